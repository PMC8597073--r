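#' Smaller root of the waiting-region characteristic quadratic
#'
#' The value of the option to list in the future decays geometrically in the
#' net count with ratio `beta1`, the smaller root of
#' \deqn{\beta^2 - \frac{r+\mu}{\mu}\beta + \theta(1-\theta) = 0.}
#' The discriminant is positive for any valid parameters because
#' `(r+mu)/mu > 1 >= 2 sqrt(theta (1-theta))`, and the smaller root
#' satisfies `0 < beta1 < theta`.
#'
#' @param params A [fontan_params()] object.
#' @return The smaller quadratic root.
#' @export
beta1 <- function(params) {
  params <- as_fontan_params(params)
  a <- (params$r + params$mu) / params$mu
  q <- params$theta * (1 - params$theta)
  (a - sqrt(a^2 - 4 * q)) / 2
}

#' Decay ratio of the delist option
#'
#' The option to remove a listed patient from the list satisfies a one-sided
#' (down-moves only) recursion whose solution decays with ratio
#' \deqn{\beta_2 = \frac{\mu\,\theta(1-\theta)}{r+\mu},}
#' the unique value consistent with the first-order recursion and with the
#' bounds `beta2 < theta` and `beta2 < 1 - theta`.
#'
#' @inheritParams beta1
#' @return The delist-option decay ratio.
#' @export
beta2 <- function(params) {
  params <- as_fontan_params(params)
  params$mu * params$theta * (1 - params$theta) / (params$r + params$mu)
}

#' Threshold ratio entering the upper belief bound
#'
#' The upper belief bound is controlled by the ratio
#' \deqn{\Psi = \frac{(r+\mu(1-\beta_1))(r+\mu\theta) - \mu^2\theta(1-\theta)}
#'   {(r+\mu(1-\beta_1))(r+\mu(1-\theta)) - \mu^2\theta(1-\theta)}}
#' which is non-negative for valid parameters (asserted at run time).
#'
#' @inheritParams beta1
#' @return The ratio `Psi` (non-negative).
#' @export
psi <- function(params) {
  params <- as_fontan_params(params)
  b1 <- beta1(params)
  common <- params$r + params$mu * (1 - b1)
  cross <- params$mu^2 * params$theta * (1 - params$theta)
  num <- common * (params$r + params$mu * params$theta) - cross
  den <- common * (params$r + params$mu * (1 - params$theta)) - cross
  if (!is.finite(den) || den == 0) {
    stop("psi: zero denominator at mu=", params$mu, ", theta=", params$theta,
         ", r=", params$r, call. = FALSE)
  }
  out <- num / den
  if (out < 0) {
    stop("psi: negative ratio (", format(out),
         "); parameters violate the model's well-definedness assumptions",
         call. = FALSE)
  }
  out
}

#' Upper belief threshold (listing bound)
#'
#' Belief level separating "too well for now" from "list": a patient whose
#' belief in a Good outcome exceeds `pH` on the pre-listing orientation is
#' still too well to be listed.
#' \deqn{p_H = \left[\Psi\left(\frac{L_T}{L_{NT}-\delta}-1\right)+1\right]^{-1}}
#'
#' @inheritParams beta1
#' @return Probability in (0, 1].
#' @export
p_high <- function(params) {
  params <- as_fontan_params(params)
  bracket <- psi(params) * (params$LT / (params$LNT - params$delta) - 1) + 1
  out <- 1 / bracket
  if (!is.finite(out) || out <= 0 || out > 1) {
    stop("p_high is not a probability (", format(out),
         "): model not well-defined for these parameters", call. = FALSE)
  }
  out
}

#' Lower belief threshold (delisting bound)
#'
#' Belief level at which a listed patient has declined far enough to be
#' removed from the list:
#' \deqn{p_L = \frac{(r+\mu)(\delta+L_T) - (2r+\mu(2+\theta))L_{NT}}
#'   {(r+\mu)L_T + \mu(1-2\theta)L_{NT}}}
#' Stated on the listed-region orientation, where the probability of a Good
#' outcome is the complement `1 - p(k)`.
#'
#' @inheritParams beta1
#' @return Probability in (0, 1].
#' @export
p_low <- function(params) {
  params <- as_fontan_params(params)
  num <- (params$r + params$mu) * (params$delta + params$LT) -
    (2 * params$r + params$mu * (2 + params$theta)) * params$LNT
  den <- (params$r + params$mu) * params$LT +
    params$mu * (1 - 2 * params$theta) * params$LNT
  out <- num / den
  if (!is.finite(out) || out <= 0 || out > 1) {
    stop("p_low = ", format(out),
         " is outside (0, 1]: the delisting bound is not well-defined for ",
         "these parameters (requires LT >> LNT > delta)", call. = FALSE)
  }
  out
}

#' Continuous upper listing threshold on the net-count scale
#'
#' Maps the upper belief bound through the count-to-belief inverse:
#' `kH = ln((1 - pH)/pH) / ln(theta/(1 - theta))`. Patients with net count
#' at or above the ceiling of `kH` are too well to list.
#'
#' @inheritParams beta1
#' @return Real-valued threshold `kH`.
#' @export
k_high <- function(params) {
  params <- as_fontan_params(params)
  k_from_p(p_high(params), params$theta)
}

#' Continuous lower (delisting) threshold on the net-count scale
#'
#' The lower bound lives on the listed-region orientation, so the ratio in
#' the count mapping is inverted relative to [k_from_p()]:
#' `kL = ln(pL/(1 - pL)) / ln(theta/(1 - theta))`.
#'
#' @inheritParams beta1
#' @return Real-valued threshold `kL`.
#' @export
k_low <- function(params) {
  params <- as_fontan_params(params)
  pl <- p_low(params)
  log(pl / (1 - pl)) / log(params$theta / (1 - params$theta))
}

#' Compute the full set of listing thresholds
#'
#' Runs the closed-form pipeline `beta1 -> Psi -> pH -> kH` and
#' `pL -> kL`, attaches integer floors and ceilings, and checks the
#' invariants that make the three-region rule meaningful (`kL < kH`, both
#' belief bounds inside (0, 1]).
#'
#' @inheritParams beta1
#' @return An object of class `fontan_thresholds` with fields `beta1`,
#'   `beta2`, `psi`, `pH`, `pL`, `kH`, `kL`, the integer forms `kH_floor`,
#'   `kH_ceil`, `kL_floor`, `kL_ceil`, the listing `window`
#'   (`c(ceiling(kL), floor(kH))`), and the `params` used.
#' @examples
#' th <- listing_thresholds(example_params())
#' round(th$kH, 2)  # 2.93
#' round(th$kL, 2)  # 0.18
#' th$window        # c(1, 2)
#' @export
listing_thresholds <- function(params) {
  params <- as_fontan_params(params)
  b1 <- beta1(params)
  stopifnot(b1 > 0, b1 < params$theta)
  b2 <- beta2(params)
  stopifnot(b2 < params$theta, b2 < 1 - params$theta)
  ps <- psi(params)
  pH <- p_high(params)
  pL <- p_low(params)
  kH <- k_high(params)
  kL <- k_low(params)
  if (kL >= kH) {
    stop("no listing window exists for these parameters: kL = ",
         format(kL), " >= kH = ", format(kH), call. = FALSE)
  }
  structure(
    list(beta1 = b1, beta2 = b2, psi = ps, pH = pH, pL = pL,
         kH = kH, kL = kL,
         kH_floor = as.integer(floor(kH)), kH_ceil = as.integer(ceiling(kH)),
         kL_floor = as.integer(floor(kL)), kL_ceil = as.integer(ceiling(kL)),
         window = c(as.integer(ceiling(kL)), as.integer(floor(kH))),
         params = params),
    class = "fontan_thresholds"
  )
}

#' @export
print.fontan_thresholds <- function(x, ...) {
  cat("Listing thresholds\n")
  cat(sprintf("  beta1 = %.4f  beta2 = %.4f  Psi = %.4f\n",
              x$beta1, x$beta2, x$psi))
  cat(sprintf("  pH = %.4f  pL = %.4f\n", x$pH, x$pL))
  cat(sprintf("  kH = %.2f (floor %d, ceil %d)\n", x$kH, x$kH_floor, x$kH_ceil))
  cat(sprintf("  kL = %.2f (floor %d, ceil %d)\n", x$kL, x$kL_floor, x$kL_ceil))
  cat(sprintf("  list while k in [%d, %d]; too well at k >= %d; too unwell at k <= %d\n",
              x$window[1], x$window[2], x$kH_ceil, x$kL_floor))
  invisible(x)
}

#' Three-way listing decision for an observed net count
#'
#' Applies the decision rule: too well when `k >= ceiling(kH)`, list when
#' `ceiling(kL) <= k <= floor(kH)`, too unwell when `k <= floor(kL)`.
#' When a threshold is an exact integer the region definitions take
#' precedence over the ceiling clause: `k = kH` lists, `k = kL` is too
#' unwell.
#'
#' @param k Integer net signal count (or vector thereof).
#' @param thresholds A [listing_thresholds()] object (or a `fontan_params`
#'   object, in which case thresholds are computed).
#' @return Character vector with levels `"TooWell"`, `"List"`,
#'   `"TooUnwell"`.
#' @examples
#' th <- listing_thresholds(example_params())
#' decide(c(0, 2, 3), th)  # TooUnwell, List, TooWell
#' @export
decide <- function(k, thresholds) {
  if (inherits(thresholds, "fontan_params")) {
    thresholds <- listing_thresholds(thresholds)
  }
  stopifnot(inherits(thresholds, "fontan_thresholds"))
  if (any(k != round(k))) {
    stop("decide() expects integer net counts; thresholds are real-valued ",
         "but patients are scored on whole signals", call. = FALSE)
  }
  k <- as.integer(round(k))
  kH <- thresholds$kH
  kL <- thresholds$kL
  out <- character(length(k))
  for (i in seq_along(k)) {
    out[i] <- if (k[i] == kH) {
      "List"                       # exact upper threshold: region 1 includes kH
    } else if (k[i] == kL) {
      "TooUnwell"                  # exact lower threshold: region 6 includes kL
    } else if (k[i] >= ceiling(kH)) {
      "TooWell"
    } else if (k[i] <= floor(kL)) {
      "TooUnwell"
    } else {
      "List"
    }
  }
  out
}
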