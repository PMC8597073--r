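test_that("threshold directions across sweeps match the model's comparative statics", {
  pm <- ex_params()
  sw_delta <- sweep_thresholds(pm, "delta", seq(0.1, 1.9, by = 0.1))
  expect_identical(sw_delta$verdicts$kH, "increasing")
  expect_true(sw_delta$verdicts$kL_floor_constant)

  # large LNT values make the delisting bound ill-defined and are skipped;
  # the integer delisting edge is only claimed constant for the delta and
  # mu sweeps, and indeed moves across a wide LNT range
  suppressWarnings(sw_lnt <- sweep_thresholds(pm, "LNT", seq(1.0, 6.0, by = 0.25)))
  expect_identical(sw_lnt$verdicts$kH, "decreasing")

  sw_mu <- sweep_thresholds(pm, "mu", seq(0.5, 6, by = 0.25))
  expect_identical(sw_mu$verdicts$kH, "increasing")
  expect_true(sw_mu$verdicts$kL_floor_constant)
})

test_that("invalid grid points are skipped with a warning, or fatal in strict mode", {
  pm <- ex_params()
  # delta values at or beyond LNT = 2 are invalid
  expect_warning(sw <- sweep_thresholds(pm, "delta", c(0.5, 1.0, 2.5)),
                 "skipping invalid")
  expect_equal(nrow(sw$results), 2)
  expect_error(sweep_thresholds(pm, "delta", c(0.5, 2.5), strict = TRUE),
               "invalid grid point")
  expect_error(sweep_thresholds(pm, "delta", c(0.5, 0.4)), "increasing")
})

test_that("signal quality estimation matches hand-computed proportions", {
  # single signal, 8 of 10 exposed patients matched its orientation
  rec <- data.frame(patient = 1:10, signal = "ple", orientation = "bad",
                    present = TRUE,
                    outcome = c(rep("Bad", 8), rep("Good", 2)))
  est <- estimate_signal_quality(rec)
  expect_equal(est$per_signal$quality, 0.8)
  expect_equal(est$composite, 0.8)

  # two signals weighted by exposure: (0.9*20 + 0.6*10)/30 = 0.8
  rec2 <- rbind(
    data.frame(patient = 1:20, signal = "a", orientation = "bad",
               present = TRUE,
               outcome = c(rep("Bad", 18), rep("Good", 2))),
    data.frame(patient = 21:30, signal = "b", orientation = "good",
               present = TRUE,
               outcome = c(rep("Good", 6), rep("Bad", 4))))
  est2 <- estimate_signal_quality(rec2)
  expect_equal(sort(est2$per_signal$quality), c(0.6, 0.9))
  expect_equal(est2$composite, 0.8)

  # all-correct records give a degenerate composite with a warning
  rec3 <- data.frame(patient = 1:5, signal = "x", orientation = "bad",
                     present = TRUE, outcome = "Bad")
  expect_warning(est3 <- estimate_signal_quality(rec3), "degenerates")
  expect_equal(est3$composite, 1)

  # unexposed signals are excluded with a message
  rec4 <- rbind(rec, data.frame(patient = 1:3, signal = "ghost",
                                orientation = "good", present = FALSE,
                                outcome = "Good"))
  expect_message(est4 <- estimate_signal_quality(rec4), "zero exposure")
  expect_equal(est4$composite, 0.8)
})

test_that("simulated records let the estimator recover the true quality", {
  rec <- simulate_estimation_records(0.8, n_patients = 2000, n_signals = 6,
                                     seed = 20)
  est <- estimate_signal_quality(rec)
  expect_lt(abs(est$composite - 0.8), 0.03)
  # determinism under the seed
  rec2 <- simulate_estimation_records(0.8, 2000, 6, seed = 20)
  expect_identical(rec, rec2)
  # an uninformative truth is recovered but rejected for decision use
  rec_half <- simulate_estimation_records(0.5, 2000, 4, seed = 21)
  est_half <- estimate_signal_quality(rec_half)
  expect_lt(abs(est_half$composite - 0.5), 0.05)
  expect_error(fontan_params(2, est_half$composite * 0 + 0.5, 0.1, 0.5, 10, 2),
               "theta")
})

test_that("estimator error shrinks with sample size", {
  err <- function(n, seed) {
    abs(estimate_signal_quality(
      simulate_estimation_records(0.8, n, 4, seed))$composite - 0.8)
  }
  small <- mean(vapply(1:6, function(s) err(100, s), numeric(1)))
  large <- mean(vapply(1:6, function(s) err(4000, s + 100), numeric(1)))
  expect_lt(large, small)
})
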