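test_that("worked-example thresholds reproduce the published values", {
  th <- ex_thresholds()
  # frozen from independent hand evaluation of the closed forms:
  # beta1 = (1.05 - sqrt(1.05^2 - 0.64))/2, beta2 = 0.32/2.1,
  # Psi = (1.730074*1.7 - 0.64)/(1.730074*0.5 - 0.64)
  expect_equal(th$beta1, 0.184963237281614, tolerance = 1e-12)
  expect_equal(th$beta2, 16 / 105, tolerance = 1e-12)
  expect_equal(th$psi, 10.2255514407758, tolerance = 1e-10)
  expect_equal(th$pH, 0.016965027351713, tolerance = 1e-10)
  expect_equal(th$pL, 10.45 / 18.6, tolerance = 1e-12)
  expect_equal(round(th$kH, 2), 2.93)
  expect_equal(round(th$kL, 2), 0.18)
  expect_equal(th$kH, 2.92830354097495, tolerance = 1e-10)
  expect_equal(th$kL, 0.179315488924903, tolerance = 1e-10)
  expect_identical(th$window, c(1L, 2L))
  expect_identical(c(th$kH_floor, th$kH_ceil, th$kL_floor, th$kL_ceil),
                   c(2L, 3L, 0L, 1L))
})

test_that("beta1 is the smaller quadratic root inside (0, theta)", {
  pm <- ex_params()
  b1 <- beta1(pm)
  expect_equal(b1^2 - 1.05 * b1 + 0.16, 0, tolerance = 1e-12)
  for (p in random_valid_params(25, 7)) {
    b <- beta1(p)
    expect_gt(b, 0)
    expect_lt(b, p$theta)
    expect_lt(b, 0.5)
    a <- (p$r + p$mu) / p$mu
    expect_equal(b^2 - a * b + p$theta * (1 - p$theta), 0, tolerance = 1e-10)
  }
  # vanishing signal-noise product drives the smaller root to zero
  near_det <- fontan_params(2, 1 - 1e-7, 0.1, 0.5, 10, 2)
  expect_lt(beta1(near_det), 1e-6)
})

test_that("beta2 stays below both theta and its complement", {
  expect_equal(beta2(ex_params()), 2 * 0.16 / 2.1, tolerance = 1e-12)
  for (p in random_valid_params(100, 11)) {
    b <- beta2(p)
    expect_lt(b, min(p$theta, 1 - p$theta))
    expect_gt(b, 0)
  }
  # huge discounting kills the delist-option decay ratio
  hot <- fontan_params(2, 0.8, 1e6, 0.5, 10, 2)
  expect_lt(beta2(hot), 1e-5)
})

test_that("Psi is non-negative across random draws and near one at symmetric quality", {
  for (p in random_valid_params(100, 13)) expect_gte(psi(p), 0)
  near_half <- fontan_params(2, 0.5 + 1e-9, 0.1, 0.5, 10, 2)
  expect_equal(psi(near_half), 1, tolerance = 1e-6)
})

test_that("belief bounds are probabilities with the documented monotonicity", {
  pm <- ex_params()
  # pH decreasing in the expected wait
  deltas <- seq(0.1, 1.9, by = 0.2)
  phs <- vapply(deltas, function(d)
    p_high(fontan_params(2, 0.8, 0.1, d, 10, 2)), numeric(1))
  expect_true(all(diff(phs) < 0))
  for (p in random_valid_params(100, 17)) {
    expect_gt(p_low(p), 0)
    expect_lte(p_low(p), 1)
    expect_gt(p_high(p), 0)
    expect_lte(p_high(p), 1)
  }
})

test_that("delisting bound rejects parameters without a well-defined window", {
  # tiny transplant gain: numerator of pL goes negative
  expect_error(p_low(fontan_params(0.2, 0.8, 0.05, 0.1, LT = 2.6, LNT = 2.5)),
               "not well-defined")
})

test_that("three-way decision matches the worked example and partitions the integers", {
  th <- ex_thresholds()
  expect_identical(decide(2L, th), "List")
  expect_identical(decide(3L, th), "TooWell")
  expect_identical(decide(0L, th), "TooUnwell")
  expect_identical(decide(1L, th), "List")
  expect_identical(decide(-5L, th), "TooUnwell")
  expect_identical(decide(10L, th), "TooWell")
  expect_error(decide(1.5, th), "integer")
  # every integer gets exactly one label for random parameter draws
  for (p in random_valid_params(10, 19)) {
    t2 <- listing_thresholds(p)
    ks <- seq(t2$kL_floor - 4L, t2$kH_ceil + 4L)
    labels <- decide(ks, t2)
    expect_true(all(labels %in% c("TooWell", "List", "TooUnwell")))
    # labels are monotone in k: TooUnwell, then List, then TooWell
    expect_true(all(diff(match(labels,
                               c("TooUnwell", "List", "TooWell"))) >= 0))
  }
})

test_that("floors and ceilings honour the mathematical definitions for negative thresholds", {
  # extreme discounting pushes the delisting threshold below zero
  pm <- fontan_params(mu = 0.5, theta = 0.8, r = 50, delta = 0.3,
                      LT = 9, LNT = 3)
  th <- listing_thresholds(pm)
  expect_lt(th$kL, 0)
  expect_identical(th$kL_floor, -1L)   # floor moves away from zero, not toward
  expect_identical(th$kL_ceil, 0L)
  expect_identical(th$kL_floor, as.integer(floor(th$kL)))
  expect_identical(th$kL_ceil, as.integer(ceiling(th$kL)))
})
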