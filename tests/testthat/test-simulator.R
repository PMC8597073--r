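test_that("trajectories are reproducible bit-for-bit under a fixed seed", {
  pm <- ex_params()
  th <- ex_thresholds()
  t1 <- simulate_trajectory(pm, th, horizon = 10, seed = 42)
  t2 <- simulate_trajectory(pm, th, horizon = 10, seed = 42)
  expect_identical(t1, t2)
  ev1 <- evaluate_policy(pm, th, n_reps = 30, horizon = 10, seed = 5)
  ev2 <- evaluate_policy(pm, th, n_reps = 30, horizon = 10, seed = 5)
  expect_identical(ev1$terminal_tally, ev2$terminal_tally)
  expect_identical(ev1$values, ev2$values)
})

test_that("trajectory invariants hold: unit steps, increasing times, consistent beliefs", {
  pm <- ex_params()
  th <- ex_thresholds()
  for (seed in 1:10) {
    tr <- simulate_trajectory(pm, th, horizon = 20, seed = seed)
    if (length(tr$k_path) > 1) {
      expect_true(all(abs(diff(tr$k_path)) == 1))
      expect_true(all(diff(tr$event_times) > 0))
    }
    expect_equal(tr$belief_path,
                 listed_posterior_good(tr$k_path, pm$theta))
    expect_gte(tr$discounted_life_years, 0)
    expect_lte(tr$discounted_life_years, 1 / pm$r + 1e-9)
    expect_true(tr$terminal %in% c("Transplanted", "DiedWaiting", "Delisted",
                                   "NeverListed", "HorizonEnd"))
  }
})

test_that("a vanishing arrival rate freezes the patient at the initial count", {
  pm <- fontan_params(mu = 1e-9, theta = 0.8, r = 0.1, delta = 0.5,
                      LT = 10, LNT = 2)
  th <- listing_thresholds(ex_params())  # decision rule from the example
  tr <- simulate_trajectory(pm, th, horizon = 10, seed = 3)
  expect_length(tr$event_times, 1)          # only the initial assessment
  expect_identical(tr$terminal, "NeverListed")
})

test_that("near-perfect signal quality makes the path monotone given the latent outcome", {
  # high arrival rate so many signals land before the death clock
  pm <- fontan_params(mu = 50, theta = 1 - 1e-12, r = 0.1, delta = 0.5,
                      LT = 10, LNT = 2)
  for (seed in 11:13) {
    tr <- simulate_trajectory(pm, "never", horizon = 500, seed = seed)
    steps <- diff(tr$k_path)
    expect_gt(length(steps), 20)
    if (tr$latent == "Good") expect_true(all(steps == 1))
    if (tr$latent == "Bad") expect_true(all(steps == -1))
  }
})

test_that("empirical transition frequencies match the recursion coefficients", {
  # The coefficients arise by marginalizing the latent outcome, so the
  # frequencies must be pooled across trajectories with fresh latent draws
  # (within one trajectory the latent is fixed and P(up) is theta or
  # 1 - theta). Pooling by current net count recovers the belief-weighted
  # mixture because the net count is sufficient for the latent outcome.
  pm <- ex_params()
  from <- integer(0); up <- logical(0)
  for (seed in 1:900) {
    tr <- simulate_trajectory(pm, "never", horizon = 8, seed = seed)
    k <- tr$k_path
    if (length(k) < 2) next
    from <- c(from, k[-length(k)])
    up <- c(up, diff(k) == 1)
  }
  expect_gt(length(from), 3000)
  for (k0 in -1:1) {
    sel <- from == k0
    n <- sum(sel)
    if (n < 200) next
    q <- signal_transition_probs(k0, pm$theta)
    p_hat <- mean(up[sel])
    se <- sqrt(q[["up"]] * (1 - q[["up"]]) / n)
    expect_lt(abs(p_hat - q[["up"]]), 3 * se + 1e-12)
  }
})

test_that("the threshold policy weakly dominates naive baselines", {
  pm <- ex_params()
  th <- ex_thresholds()
  n <- 400
  ev_th <- evaluate_policy(pm, th, n_reps = n, horizon = 10, seed = 77)
  ev_never <- evaluate_policy(pm, "never", n_reps = n, horizon = 10, seed = 77)
  ev_now <- evaluate_policy(pm, "immediate", n_reps = n, horizon = 10, seed = 77)
  se <- function(a, b) sqrt(a$se^2 + b$se^2)
  expect_gte(ev_th$mean, ev_never$mean - 2 * se(ev_th, ev_never))
  expect_gte(ev_th$mean, ev_now$mean - 2 * se(ev_th, ev_now))
})

test_that("down-only listed mode never raises the count while listed", {
  # start inside the listing window so every trajectory has a listed phase
  pm <- ex_params()
  th <- ex_thresholds()
  with_data <- 0
  for (seed in 1:40) {
    tr <- simulate_trajectory(pm, th, horizon = 15, seed = seed, k0 = 2L,
                              listed_mode = "down")
    expect_identical(tr$t_list, 0)
    after <- tr$event_times > tr$t_list
    if (sum(after) >= 1) {
      listed_k <- c(2L, tr$k_path[after])
      expect_true(all(diff(listed_k) == -1))
      with_data <- with_data + 1
    }
  }
  expect_gte(with_data, 3)
})

test_that("checklist fixtures have the requested composition", {
  cl <- generate_checklist_fixture(5, 5, seed = 1)
  expect_equal(cl$k, 0)
  expect_equal(cl$n, 10)
  expect_equal(generate_checklist_fixture(0, 0, seed = 1)$k, 0)
  expect_equal(generate_checklist_fixture(7, 3, seed = 1)$k, 4)
  # more signals than the vocabulary holds still yields unique labels
  big <- generate_checklist_fixture(12, 11, seed = 2)
  expect_equal(big$n, 23)
  expect_false(anyDuplicated(big$entries$symptom) > 0)
})
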