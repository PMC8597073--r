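#' Posterior probability of a Good outcome from the net signal count
#'
#' The sufficient statistic for the doctor's belief is the net signal count
#' `k`: the number of Good-indicative signals in excess of Bad-indicative
#' ones (`k = n - 2b` for `b` Bad signals out of `n`). With a symmetric 1/2
#' prior the posterior probability of a Good post-transplant outcome reduces
#' to
#'
#' \deqn{p(k) = \frac{(1-\theta)^k}{\theta^k + (1-\theta)^k}}
#'
#' For signal quality above one half this is strictly decreasing in `k`:
#' in the pre-listing orientation of the model, acquiring a comorbidity
#' (which lowers the patient's net count by one) raises the belief that a
#' transplant performed now would end well.
#'
#' @param k Net signal count. Integer for observed patients; real values are
#'   accepted because the continuous thresholds live on the same scale.
#' @param theta Signal quality in (0, 1), not equal to 1/2.
#' @return Posterior probability, strictly inside (0, 1).
#' @seealso [k_from_p()] for the inverse, [listed_posterior_good()] for the
#'   listed-region orientation.
#' @examples
#' posterior_good(0, 0.8)  # prior preserved: 0.5
#' posterior_good(1, 0.8)  # 0.2
#' @export
posterior_good <- function(k, theta) {
  check_theta(theta)
  stopifnot(is.numeric(k), all(is.finite(k)))
  # compute on log scale to stay finite for large |k|
  lt <- k * log(1 - theta)
  lb <- k * log(theta)
  m <- pmax(lt, lb)
  exp(lt - m) / (exp(lt - m) + exp(lb - m))
}

#' Invert the belief back to a net signal count
#'
#' Exact inverse of [posterior_good()]:
#' \deqn{k(p) = \frac{\ln((1-p)/p)}{\ln(\theta/(1-\theta))}}
#' Used to place the closed-form belief thresholds on the observable
#' net-count scale.
#'
#' @param p Probability strictly in (0, 1).
#' @param theta Signal quality in (0, 1), not 1/2.
#' @return Real-valued net signal count.
#' @examples
#' k_from_p(0.2, 0.8)  # 1
#' @export
k_from_p <- function(p, theta) {
  check_theta(theta)
  if (any(p <= 0) || any(p >= 1)) {
    stop("p must lie strictly in (0, 1): the net count diverges at 0 and 1",
         call. = FALSE)
  }
  log((1 - p) / p) / log(theta / (1 - theta))
}

#' Brute-force Bayes posterior over the full checklist
#'
#' Direct computation of the posterior from the binomial likelihoods of `b`
#' Bad-indicative signals out of `n`, without reducing to the net count:
#' \deqn{p = \frac{\theta^b (1-\theta)^{n-b} p_0}
#'   {\theta^b (1-\theta)^{n-b} p_0 + (1-\theta)^b \theta^{n-b} (1-p_0)}}
#' With `p0 = 1/2` this equals `posterior_good(n - 2b, theta)`; the pair of
#' routes is kept deliberately so each can check the other.
#'
#' @param b Number of Bad-indicative signals (0..n).
#' @param n Total number of signals.
#' @param theta Signal quality in (0, 1).
#' @param p0 Prior probability of a Good outcome.
#' @return Posterior probability of a Good outcome.
#' @export
brute_force_posterior <- function(b, n, theta, p0 = 0.5) {
  check_theta(theta, allow_half = TRUE)
  stopifnot(n >= 0, b >= 0, b <= n, p0 > 0, p0 < 1)
  num <- theta^b * (1 - theta)^(n - b) * p0
  den <- num + (1 - theta)^b * theta^(n - b) * (1 - p0)
  num / den
}

#' Listed-region probability of a Good outcome
#'
#' Once a patient is listed the orientation of newly acquired comorbidities
#' flips: further decline signals a Bad outcome, which the model encodes by
#' interchanging `theta` and `1 - theta`. The probability of a Good outcome
#' in the listed region is therefore the complement `1 - p(k)`.
#'
#' @inheritParams posterior_good
#' @return Probability in (0, 1).
#' @export
listed_posterior_good <- function(k, theta) {
  1 - posterior_good(k, theta)
}

check_theta <- function(theta, allow_half = FALSE) {
  if (!is.numeric(theta) || length(theta) != 1 || !is.finite(theta) ||
      theta <= 0 || theta >= 1) {
    stop("theta must be a single value strictly in (0, 1)", call. = FALSE)
  }
  if (!allow_half && theta == 0.5) {
    stop("theta = 1/2 leaves the net count undefined", call. = FALSE)
  }
  invisible(theta)
}

#' Assemble a symptom checklist assessment
#'
#' A checklist assessment is a set of oriented signals observed at one
#' review: each entry is a symptom whose observed state is indicative of a
#' Good or a Bad post-transplant outcome. The net count is
#' `k = #Good - #Bad`; weighting of major comorbidities is achieved by
#' entering their associated sub-signals as separate entries rather than by
#' per-entry weights.
#'
#' @param symptom Character vector of unique symptom labels.
#' @param orientation Character vector, each element `"good"` or `"bad"`.
#' @return An object of class `fontan_checklist` with fields `entries`
#'   (data frame), `n`, `b` (number of Bad-indicative signals) and `k`.
#' @examples
#' cl <- checklist_assessment(c("PLE", "support network"), c("bad", "good"))
#' cl$k  # 0
#' @export
checklist_assessment <- function(symptom = character(), orientation = character()) {
  symptom <- as.character(symptom)
  orientation <- tolower(as.character(orientation))
  if (length(symptom) != length(orientation)) {
    stop("symptom and orientation must have equal length", call. = FALSE)
  }
  if (anyDuplicated(symptom)) {
    stop("duplicate symptom label in checklist: ",
         symptom[duplicated(symptom)][1], call. = FALSE)
  }
  bad_tok <- !orientation %in% c("good", "bad")
  if (any(bad_tok)) {
    stop("unknown orientation token '", orientation[bad_tok][1],
         "' (expected 'good' or 'bad')", call. = FALSE)
  }
  n <- length(symptom)
  b <- sum(orientation == "bad")
  structure(
    list(entries = data.frame(symptom = symptom, orientation = orientation,
                              stringsAsFactors = FALSE),
         n = n, b = b, k = n - 2L * b),
    class = "fontan_checklist"
  )
}

#' @export
print.fontan_checklist <- function(x, ...) {
  cat(sprintf("Checklist assessment: %d signals (%d good, %d bad), k = %d\n",
              x$n, x$n - x$b, x$b, x$k))
  invisible(x)
}
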