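#' Threshold sensitivity sweep over one model parameter
#'
#' Recomputes the listing thresholds from scratch across a grid of values
#' of one parameter (expected wait `delta`, no-transplant life expectancy
#' `LNT`, or decline rate `mu`), holding the others fixed, and reports
#' monotonicity verdicts. The model predicts that the upper threshold rises
#' with the expected wait and with the decline rate, falls with the
#' no-transplant life expectancy, and that the integer delisting edge is
#' insensitive to all three over clinically plausible ranges.
#'
#' @param params Baseline [fontan_params()].
#' @param name One of `"delta"`, `"LNT"`, `"mu"`.
#' @param grid Strictly increasing numeric grid for the swept parameter.
#' @param strict If `TRUE`, a grid point that fails parameter validation is
#'   an error; otherwise it is skipped with a warning.
#' @return An object of class `fontan_sweep`: list with `parameter`,
#'   `results` (data frame: value, kH, kL, kH_floor, kL_floor), and
#'   `verdicts` (directions of kH and kL, constancy of the integer edges).
#' @export
sweep_thresholds <- function(params, name = c("delta", "LNT", "mu"), grid,
                             strict = FALSE) {
  params <- as_fontan_params(params)
  name <- match.arg(name)
  if (length(grid) < 2 || any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing with at least two points",
         call. = FALSE)
  }
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    args <- list(mu = params$mu, theta = params$theta, r = params$r,
                 delta = params$delta, LT = params$LT, LNT = params$LNT)
    args[[name]] <- grid[i]
    th <- tryCatch(listing_thresholds(do.call(fontan_params, args)),
                   error = function(e) e)
    if (inherits(th, "error")) {
      if (strict) {
        stop("sweep: invalid grid point ", name, " = ", grid[i], ": ",
             conditionMessage(th), call. = FALSE)
      }
      warning("sweep: skipping invalid grid point ", name, " = ", grid[i],
              " (", conditionMessage(th), ")", call. = FALSE)
      next
    }
    rows[[i]] <- data.frame(value = grid[i], kH = th$kH, kL = th$kL,
                            kH_floor = th$kH_floor, kL_floor = th$kL_floor)
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res) || nrow(res) < 2) {
    stop("sweep: fewer than two valid grid points", call. = FALSE)
  }
  direction <- function(x) {
    d <- diff(x)
    if (all(d > 0)) "increasing" else if (all(d < 0)) "decreasing"
    else if (all(d >= 0)) "nondecreasing" else if (all(d <= 0)) "nonincreasing"
    else "nonmonotone"
  }
  structure(
    list(parameter = name, results = res,
         verdicts = list(kH = direction(res$kH), kL = direction(res$kL),
                         kH_floor_constant = length(unique(res$kH_floor)) == 1,
                         kL_floor_constant = length(unique(res$kL_floor)) == 1)),
    class = "fontan_sweep"
  )
}

#' @export
print.fontan_sweep <- function(x, ...) {
  cat(sprintf("Threshold sweep over %s (%d valid points)\n",
              x$parameter, nrow(x$results)))
  cat(sprintf("  kH %s; kL %s; floor(kL) constant: %s\n",
              x$verdicts$kH, x$verdicts$kL, x$verdicts$kL_floor_constant))
  invisible(x)
}

#' Step plot of integer threshold edges across a sweep
#'
#' @param sweep A [sweep_thresholds()] result.
#' @param file Optional png path; when given the plot is written there.
#' @return The sweep, invisibly.
#' @export
plot_sweep <- function(sweep, file = NULL) {
  stopifnot(inherits(sweep, "fontan_sweep"))
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 480)
    on.exit(grDevices::dev.off())
  }
  res <- sweep$results
  ylim <- range(res$kH_floor, res$kL_floor) + c(-0.5, 0.5)
  plot(res$value, res$kH_floor, type = "s", ylim = ylim,
       xlab = sweep$parameter, ylab = "integer threshold",
       main = sprintf("Listing edges vs %s", sweep$parameter))
  graphics::lines(res$value, res$kL_floor, type = "s", lty = 2)
  graphics::legend("topleft", legend = c("floor(kH)", "floor(kL)"),
                   lty = c(1, 2), bty = "n")
  invisible(sweep)
}

#' Estimate signal quality from historical outcome records
#'
#' For each checklist signal, quality is the proportion of patients exposed
#' to the signal (signal present at transplant) whose realized outcome
#' matched the signal's orientation — e.g. for a Bad-indicative comorbidity,
#' the share of exposed patients whose outcome was indeed Bad. The
#' per-signal proportions are combined into a composite holistic quality as
#' their exposure-weighted mean.
#'
#' @param records Data frame with columns `patient`, `signal`,
#'   `orientation` ("good"/"bad"), `present` (logical), `outcome`
#'   ("Good"/"Bad").
#' @return A list with `per_signal` (data frame: signal, orientation,
#'   n_exposed, quality) and `composite` (exposure-weighted mean quality).
#'   Signals with zero exposure are excluded with a message; a composite of
#'   1 triggers a warning because `theta = 1` degenerates the belief model.
#' @export
estimate_signal_quality <- function(records) {
  needed <- c("patient", "signal", "orientation", "present", "outcome")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    stop("records must be a data frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  records$orientation <- tolower(records$orientation)
  stopifnot(all(records$orientation %in% c("good", "bad")),
            all(records$outcome %in% c("Good", "Bad")))
  exposed <- records[records$present, , drop = FALSE]
  per <- lapply(split(exposed, exposed$signal), function(d) {
    correct <- (d$orientation == "bad" & d$outcome == "Bad") |
      (d$orientation == "good" & d$outcome == "Good")
    data.frame(signal = d$signal[1], orientation = d$orientation[1],
               n_exposed = nrow(d), quality = mean(correct))
  })
  per <- do.call(rbind, per)
  dropped <- setdiff(unique(records$signal), per$signal)
  if (length(dropped)) {
    message("estimate_signal_quality: excluding signal(s) with zero exposure: ",
            paste(dropped, collapse = ", "))
  }
  if (is.null(per) || nrow(per) == 0) {
    stop("no exposed signals to estimate from", call. = FALSE)
  }
  composite <- sum(per$quality * per$n_exposed) / sum(per$n_exposed)
  if (composite >= 1) {
    warning("composite quality is 1: theta = 1 degenerates the belief model",
            call. = FALSE)
  }
  rownames(per) <- NULL
  list(per_signal = per, composite = composite)
}

#' Simulate historical outcome records with known signal quality
#'
#' Generates per-patient comorbidity/outcome records whose per-signal
#' correctness is Bernoulli with the chosen true quality: each patient's
#' outcome is Good with probability one half, and each signal is present
#' with probability `true_theta` when the outcome matches its orientation
#' and `1 - true_theta` otherwise. Under the symmetric prior the proportion
#' of exposed patients whose outcome matches the orientation is then
#' exactly `true_theta`, so [estimate_signal_quality()] is consistent.
#'
#' @param true_theta True signal quality in (0, 1).
#' @param n_patients Number of patients.
#' @param n_signals Number of checklist signals (orientations alternate).
#' @param seed Integer seed.
#' @return A records data frame as consumed by [estimate_signal_quality()].
#' @export
simulate_estimation_records <- function(true_theta, n_patients, n_signals,
                                        seed) {
  stopifnot(true_theta > 0, true_theta < 1, n_patients >= 1, n_signals >= 1)
  set.seed(as.integer(seed))
  orientation <- rep(c("bad", "good"), length.out = n_signals)
  signal <- paste0(ifelse(orientation == "bad", "comorbidity_", "protective_"),
                   seq_len(n_signals))
  outcome <- ifelse(stats::runif(n_patients) < 0.5, "Good", "Bad")
  rows <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    match_prob <- ifelse(
      (orientation == "bad") == (outcome[i] == "Bad"),
      true_theta, 1 - true_theta)
    rows[[i]] <- data.frame(patient = i, signal = signal,
                            orientation = orientation,
                            present = stats::runif(n_signals) < match_prob,
                            outcome = outcome[i])
  }
  do.call(rbind, rows)
}
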