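#' Simulate one patient trajectory under a listing policy
#'
#' Generates a full patient timeline: a latent post-transplant outcome is
#' drawn once with the prior probability of one half; comorbidity-checklist
#' signals arrive as a Poisson process with rate `mu`; each signal is
#' correct (matches the latent outcome) with probability `theta` and moves
#' the net count by one under a fixed semantic convention: a Good-indicative
#' signal moves `k` up. Under this generative law the Bayes-consistent
#' belief in a Good outcome after net count `k` is
#' [listed_posterior_good()]`(k)`, and the marginal one-step transition
#' probabilities reproduce the model's recursion coefficients
#' ([signal_transition_probs()]).
#'
#' The policy is consulted at time zero and after every event. An unlisted
#' patient waits through both TooWell and TooUnwell assessments (the rule is
#' reapplied as status evolves) and is listed on entering the listing
#' window. A listed patient waits for an organ whose arrival is exponential
#' with mean `delta` (or a fixed delay); if the net count falls to the
#' delisting edge first the patient is removed from the list, which is
#' terminal. The no-transplant life expectancy acts as a global death
#' clock: a patient not transplanted by time `LNT` after first assessment
#' dies at that point, whether still unlisted, delisted, or listed without
#' an organ — this is what makes the `delta < LNT` assumption bite. At
#' transplant the outcome is Good with probability equal to the
#' listed-region belief at that instant, giving residual life `LT` from
#' the transplant, else immediate death.
#'
#' @param params A [fontan_params()] object.
#' @param policy A [listing_thresholds()] object (threshold policy), or one
#'   of `"never"` (never list) and `"immediate"` (list at time zero
#'   regardless of the net count, no delisting).
#' @param horizon Simulation horizon in years (> 0).
#' @param seed Integer seed; trajectories are bit-for-bit reproducible.
#' @param k0 Initial net signal count (default 0, the uninformative start).
#' @param listed_mode `"all"` (default): signals of both orientations keep
#'   arriving after listing; `"down"`: signals that would raise the net
#'   count are discarded in the listed region, matching the derivation's
#'   assumption that only negative signals arrive there.
#' @param wait_model `"exponential"` (default) or `"fixed"` organ wait.
#' @return An object of class `fontan_trajectory`: a list with `seed`,
#'   `latent` ("Good"/"Bad"), `event_times`, `k_path`, `belief_path`
#'   (Bayes-consistent Good-outcome belief), `decision_path`, `t_list`,
#'   `terminal` (one of Transplanted, DiedWaiting, Delisted, NeverListed,
#'   HorizonEnd), `transplant_outcome`, `death_time`, and
#'   `discounted_life_years`.
#' @export
simulate_trajectory <- function(params, policy, horizon, seed, k0 = 0L,
                                listed_mode = c("all", "down"),
                                wait_model = c("exponential", "fixed")) {
  params <- as_fontan_params(params)
  listed_mode <- match.arg(listed_mode)
  wait_model <- match.arg(wait_model)
  if (!is.numeric(horizon) || length(horizon) != 1 || !is.finite(horizon) ||
      horizon <= 0) {
    stop("horizon must be a positive number of years", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  set.seed(as.integer(seed))

  policy_type <- policy_kind(policy)
  th <- if (policy_type == "threshold") policy else NULL

  latent <- if (stats::runif(1) < params$p0) "Good" else "Bad"
  p_up <- if (latent == "Good") params$theta else 1 - params$theta

  k <- as.integer(k0)
  t_now <- 0
  listed <- FALSE
  t_list <- NA_real_
  t_organ <- Inf
  t_clock <- params$LNT   # global no-transplant death clock
  terminal <- NA_character_
  transplant_outcome <- NA_character_
  death_time <- NA_real_

  event_times <- numeric(0)
  k_path <- integer(0)
  belief_path <- numeric(0)
  decision_path <- character(0)

  consult <- function(k) {
    switch(policy_type,
           threshold = decide(k, th),
           never = "TooWell",       # never-list policy always defers
           immediate = "List")
  }

  list_now <- function(t) {
    listed <<- TRUE
    t_list <<- t
    wait <- if (wait_model == "exponential") {
      stats::rexp(1, rate = 1 / params$delta)
    } else {
      params$delta
    }
    t_organ <<- t + wait
  }

  d0 <- consult(k)
  decision_path <- c(decision_path, d0)
  k_path <- c(k_path, k)
  belief_path <- c(belief_path, listed_posterior_good(k, params$theta))
  event_times <- c(event_times, 0)
  if (d0 == "List") list_now(0)

  repeat {
    t_signal <- t_now + stats::rexp(1, rate = params$mu)
    t_next <- min(t_signal, t_organ, t_clock, horizon)

    if (listed && t_organ <= t_next) {
      g <- listed_posterior_good(k, params$theta)
      good <- stats::runif(1) < g
      terminal <- "Transplanted"
      transplant_outcome <- if (good) "Good" else "Bad"
      death_time <- t_organ + if (good) params$LT else 0
      break
    }
    if (t_clock <= t_next) {
      terminal <- if (listed) "DiedWaiting" else "NeverListed"
      death_time <- t_clock
      break
    }
    if (t_next >= horizon) {
      # simulation guard shorter than the death clock: the patient dies at
      # the clock regardless, the label records the censoring state
      terminal <- if (listed) "HorizonEnd" else "NeverListed"
      death_time <- t_clock
      break
    }

    # a signal arrives
    t_now <- t_signal
    step <- if (stats::runif(1) < p_up) 1L else -1L
    if (listed && listed_mode == "down" && step > 0L) {
      next  # up-moves suppressed in the listed region under down-only mode
    }
    k <- k + step
    event_times <- c(event_times, t_now)
    k_path <- c(k_path, k)
    belief_path <- c(belief_path, listed_posterior_good(k, params$theta))
    d <- consult(k)
    decision_path <- c(decision_path, d)
    if (!listed && d == "List") {
      list_now(t_now)
    } else if (listed && policy_type == "threshold" && d == "TooUnwell") {
      terminal <- "Delisted"
      death_time <- t_clock
      break
    }
  }

  value <- (1 - exp(-params$r * death_time)) / params$r

  structure(
    list(seed = as.integer(seed), latent = latent,
         event_times = event_times, k_path = k_path,
         belief_path = belief_path, decision_path = decision_path,
         t_list = t_list, terminal = terminal,
         transplant_outcome = transplant_outcome,
         death_time = death_time,
         discounted_life_years = value),
    class = "fontan_trajectory"
  )
}

#' @export
print.fontan_trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory (seed %d): latent %s, %d events, terminal %s, %.3f discounted life-years\n",
    x$seed, x$latent, length(x$event_times) - 1, x$terminal,
    x$discounted_life_years))
  invisible(x)
}

policy_kind <- function(policy) {
  if (inherits(policy, "fontan_thresholds")) return("threshold")
  if (is.character(policy) && length(policy) == 1 &&
      policy %in% c("never", "immediate")) {
    return(policy)
  }
  stop("policy must be a 'fontan_thresholds' object, \"never\" or \"immediate\"",
       call. = FALSE)
}

#' Monte Carlo evaluation of a listing policy
#'
#' Replicates [simulate_trajectory()] with per-replicate seeds derived from
#' the master seed, and summarizes realized discounted life-years.
#'
#' @inheritParams simulate_trajectory
#' @param n_reps Number of replicate trajectories (>= 2).
#' @param seed Master seed; replicate `i` uses a seed derived from
#'   `(seed, i)` so replicate sets are reproducible and order-independent.
#' @param ... Further arguments passed to [simulate_trajectory()].
#' @return A list with `mean`, `se` (Monte Carlo standard error),
#'   `terminal_tally` (named counts), `n_reps`, and `values`.
#' @export
evaluate_policy <- function(params, policy, n_reps, horizon, seed, ...) {
  stopifnot(n_reps >= 2)
  params <- as_fontan_params(params)
  values <- numeric(n_reps)
  terminals <- character(n_reps)
  for (i in seq_len(n_reps)) {
    tr <- simulate_trajectory(params, policy, horizon,
                              seed = replicate_seed(seed, i), ...)
    values[i] <- tr$discounted_life_years
    terminals[i] <- tr$terminal
  }
  list(mean = mean(values),
       se = stats::sd(values) / sqrt(n_reps),
       terminal_tally = table(factor(
         terminals,
         levels = c("Transplanted", "DiedWaiting", "Delisted",
                    "NeverListed", "HorizonEnd"))),
       n_reps = n_reps,
       values = values)
}

replicate_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 16807) %% 2147483647)
}

#' Generate a synthetic checklist fixture
#'
#' Builds a checklist assessment with the requested composition of
#' Good-indicative and Bad-indicative signals, drawing symptom labels from
#' a small clinical vocabulary (padded with generated labels when more are
#' requested than the vocabulary holds). Optionally serializes it.
#'
#' @param n_good,n_bad Numbers of Good- and Bad-indicative signals (>= 0).
#' @param seed Integer seed controlling label sampling.
#' @param path Optional file path; when given the checklist is written via
#'   [write_checklist()] (format chosen by extension, csv or json).
#' @return A [checklist_assessment()] object with `k = n_good - n_bad`.
#' @export
generate_checklist_fixture <- function(n_good, n_bad, seed, path = NULL) {
  stopifnot(n_good >= 0, n_bad >= 0)
  set.seed(as.integer(seed))
  vocab_good <- c("Exercise tolerance preserved", "Healthy body mass index",
                  "Support network", "Normal central venous pressure",
                  "No liver cirrhosis", "Stable oxygen saturation",
                  "Normal albumin", "Good renal perfusion")
  vocab_bad <- c("Protein losing enteropathy", "Preserved ventricular function",
                 "Multiple prior surgeries", "Severe liver cirrhosis",
                 "Elevated creatinine", "High antibodies",
                 "Massive ascites", "Peripheral edema")
  pick <- function(vocab, n, prefix) {
    if (n <= length(vocab)) sample(vocab, n) else {
      c(sample(vocab), paste0(prefix, seq_len(n - length(vocab))))
    }
  }
  goods <- pick(vocab_good, n_good, "good_signal_")
  bads <- pick(vocab_bad, n_bad, "bad_signal_")
  cl <- checklist_assessment(c(goods, bads),
                             c(rep("good", n_good), rep("bad", n_bad)))
  if (!is.null(path)) write_checklist(cl, path)
  cl
}
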