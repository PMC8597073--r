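#' Model parameters for the transplant listing problem
#'
#' Validates and bundles the six scalars that drive every formula in the
#' listing model, together with the fixed prior belief.
#'
#' @param mu Comorbidity arrival rate, events per year (> 0). A patient who
#'   developed two comorbidities over the last year has `mu = 2`.
#' @param theta Signal quality: the probability that a checklist signal
#'   correctly reflects the true post-transplant outcome. Must lie strictly
#'   in (0, 1) and differ from 1/2, at which the count-to-belief mapping
#'   degenerates.
#' @param r Discount rate per year (> 0) applied to future life-years.
#' @param delta Expected waiting time on the list, in years (> 0). Must be
#'   shorter than `LNT`: a patient whose no-transplant life expectancy is
#'   below the expected wait would not live to receive the organ.
#' @param LT Post-transplant life expectancy in years, given a Good outcome.
#' @param LNT Life expectancy without transplant, in years. The model
#'   assumes `0 < LNT < LT`.
#' @param p0 Prior probability of a Good outcome at first assessment.
#'   Fixed at 1/2; supplied only so the assumption is visible.
#'
#' @return An object of class `fontan_params`: a named list with the six
#'   scalars, `p0`, and the derived listing cost `C = LNT - delta` (the
#'   life-expectancy forfeited by a listed patient whose outcome is Bad).
#'
#' @examples
#' fontan_params(mu = 2, theta = 0.8, r = 0.1, delta = 0.5, LT = 10, LNT = 2)
#' @export
fontan_params <- function(mu, theta, r, delta, LT, LNT, p0 = 0.5) {
  vals <- c(mu = mu, theta = theta, r = r, delta = delta, LT = LT, LNT = LNT)
  if (!all(is.finite(vals))) {
    stop("all six model parameters must be supplied and finite", call. = FALSE)
  }
  if (mu <= 0) stop("mu must be > 0 (comorbidity arrival rate)", call. = FALSE)
  if (r <= 0) stop("r must be > 0 (discount rate)", call. = FALSE)
  if (theta <= 0 || theta >= 1) {
    stop("theta must lie strictly in (0, 1)", call. = FALSE)
  }
  if (theta == 0.5) {
    stop("theta must differ from 1/2: the net count k is undefined at theta = 1/2",
         call. = FALSE)
  }
  if (delta <= 0) stop("delta must be > 0 (expected wait on list)", call. = FALSE)
  if (LNT <= 0) stop("LNT must be > 0", call. = FALSE)
  if (delta >= LNT) {
    stop("delta must be < LNT: expected wait cannot exceed the no-transplant life expectancy",
         call. = FALSE)
  }
  if (LNT >= LT) {
    stop("LNT must be < LT: transplant must offer a substantial life-expectancy gain",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(p0, 0.5))) {
    stop("p0 is fixed at 1/2 at first assessment", call. = FALSE)
  }
  structure(
    list(mu = mu, theta = theta, r = r, delta = delta, LT = LT, LNT = LNT,
         p0 = 0.5, C = LNT - delta),
    class = "fontan_params"
  )
}

#' @export
print.fontan_params <- function(x, ...) {
  cat("Fontan listing model parameters\n")
  cat(sprintf("  mu    = %.4g comorbidities/year\n", x$mu))
  cat(sprintf("  theta = %.4g (signal quality)\n", x$theta))
  cat(sprintf("  r     = %.4g /year (discount rate)\n", x$r))
  cat(sprintf("  delta = %.4g years on list (expected)\n", x$delta))
  cat(sprintf("  LT    = %.4g years (post-transplant life expectancy)\n", x$LT))
  cat(sprintf("  LNT   = %.4g years (no-transplant life expectancy)\n", x$LNT))
  cat(sprintf("  C     = %.4g years (listing cost LNT - delta)\n", x$C))
  invisible(x)
}

#' Example parameter set used throughout the documentation
#'
#' The worked-example patient: two comorbidities per year, 80% signal
#' quality, 10% discounting, half a year expected on the list, ten years of
#' post-transplant life expectancy against two without transplant.
#'
#' @return A `fontan_params` object.
#' @export
example_params <- function() {
  fontan_params(mu = 2, theta = 0.8, r = 0.1, delta = 0.5, LT = 10, LNT = 2)
}

#' Draw random clinically plausible parameter sets
#'
#' Samples parameter sets from broad clinical ranges (decline rate 0.5-6
#' comorbidities/year, signal quality 0.55-0.95, discount rate 0.02-0.3,
#' no-transplant life expectancy 1-4 years, expected wait 10-90% of it,
#' post-transplant life expectancy 5-10 times the no-transplant one) and
#' keeps only draws for which the model is well defined (both belief
#' bounds inside (0, 1] and a non-empty listing window). Used by the
#' validation sweeps that exercise the boundary conditions and the lattice
#' oracle away from any single worked example.
#'
#' @param n Number of parameter sets.
#' @param seed Integer seed.
#' @return A list of `n` [fontan_params()] objects.
#' @export
random_valid_params <- function(n, seed) {
  set.seed(as.integer(seed))
  out <- vector("list", n)
  got <- 0
  attempts <- 0
  while (got < n) {
    attempts <- attempts + 1
    if (attempts > 1000 * n) {
      stop("random_valid_params: rejection sampling failed", call. = FALSE)
    }
    LNT <- stats::runif(1, 1, 4)
    cand <- try(fontan_params(
      mu = stats::runif(1, 0.5, 6),
      theta = stats::runif(1, 0.55, 0.95),
      r = stats::runif(1, 0.02, 0.3),
      delta = stats::runif(1, 0.1, 0.9) * LNT,
      LT = LNT * stats::runif(1, 5, 10),
      LNT = LNT), silent = TRUE)
    if (inherits(cand, "try-error")) next
    ok <- !inherits(try(listing_thresholds(cand), silent = TRUE), "try-error")
    if (ok) {
      got <- got + 1
      out[[got]] <- cand
    }
  }
  out
}

as_fontan_params <- function(params) {
  if (inherits(params, "fontan_params")) return(params)
  if (is.list(params) &&
      all(c("mu", "theta", "r", "delta", "LT", "LNT") %in% names(params))) {
    return(fontan_params(params$mu, params$theta, params$r, params$delta,
                         params$LT, params$LNT))
  }
  stop("expected a 'fontan_params' object; see fontan_params()", call. = FALSE)
}
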