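#' Regional value functions and option constants
#'
#' The listing model divides the net-count line into six regions and assigns
#' each an expected life-years value: immediate listing (`vr1`), watchful
#' waiting far above the listing bound (`vr2`), one signal above the bound
#' (`vr3`), listed with a live delist option (`vr4` = `vr1` + `vo4`), listed
#' one signal above the delist bound (`vr5` = `vr1` + `vo5`), and delisted
#' (`vr6` = `LNT`). The two option constants `A` and `B` are pinned by
#' value-matching conditions at the thresholds; see [solve_constants()].
#'
#' @name value_functions
NULL

# transition coefficients of the one-step signal recursion:
# q_down multiplies the k-1 branch, q_up the k+1 branch; they are the
# probabilities of a Good-indicative resp. Bad-indicative signal at belief p
# in the pre-listing orientation, and sum to one for any p, theta.
q_down <- function(p, theta) 2 * p * theta + 1 - theta - p
q_up   <- function(p, theta) p + theta - 2 * theta * p

denom_k <- function(k, theta) theta^k + (1 - theta)^k

#' One-step signal transition probabilities at a given net count
#'
#' Probabilities that the next signal moves the net count down (a
#' Good-indicative signal in the pre-listing orientation, i.e. a new
#' comorbidity) or up, evaluated at the current belief `p(k)`.
#'
#' @param k Net signal count.
#' @param theta Signal quality.
#' @return Named vector `c(down = ..., up = ...)` summing to one.
#' @export
signal_transition_probs <- function(k, theta) {
  p <- posterior_good(k, theta)
  c(down = q_down(p, theta), up = q_up(p, theta))
}

#' Value of listing immediately
#'
#' Expected total life expectancy from listing now with expected wait
#' `delta`: `(1 - p(k)) * LT + (delta - LNT)`.
#'
#' @param k Net signal count (real or integer).
#' @param params A [fontan_params()] object.
#' @return Expected life-years.
#' @export
vr1 <- function(k, params) {
  params <- as_fontan_params(params)
  (1 - posterior_good(k, params$theta)) * params$LT +
    (params$delta - params$LNT)
}

#' Value of watchful waiting far from the listing bound
#'
#' `vr2(k) = A * beta1^k / (theta^k + (1-theta)^k)`; tends to zero as the
#' waiting region recedes from the listing bound since `beta1 < theta`.
#'
#' @param k Net signal count.
#' @param vm A value model from [solve_constants()].
#' @return Expected life-years of holding the listing option.
#' @export
vr2 <- function(k, vm) {
  stopifnot(inherits(vm, "fontan_value_model"))
  th <- vm$params$theta
  vm$A * vm$thresholds$beta1^k / denom_k(k, th)
}

#' Value of waiting one signal above the listing bound
#'
#' The one-step recursion with the immediate-listing value on the down
#' branch and the waiting value on the up branch:
#' `vr3(k) = mu/(r+mu) * (q_down(p(k)) * vr1(k-1) + q_up(p(k)) * vr2(k+1))`.
#'
#' @inheritParams vr2
#' @return Expected life-years.
#' @export
vr3 <- function(k, vm) {
  stopifnot(inherits(vm, "fontan_value_model"))
  pm <- vm$params
  p <- posterior_good(k, pm$theta)
  pm$mu / (pm$r + pm$mu) *
    (q_down(p, pm$theta) * vr1(k - 1, pm) + q_up(p, pm$theta) * vr2(k + 1, vm))
}

#' Delist option value in the interior of the listed region
#'
#' `vo4(k) = B * beta2^k / (theta^k + (1-theta)^k)`; grows without bound as
#' comorbidities accumulate (`k` decreasing), reflecting that the option to
#' delist is most valuable for the sickest listed patients.
#'
#' @inheritParams vr2
#' @return Option value in life-years.
#' @export
vo4 <- function(k, vm) {
  stopifnot(inherits(vm, "fontan_value_model"))
  th <- vm$params$theta
  vm$B * vm$thresholds$beta2^k / denom_k(k, th)
}

#' Total value of being listed in the interior region
#'
#' `vr4 = vr1 + vo4`: the capitalized value of the coming transplant plus
#' the live option to delist should the patient decline sharply.
#'
#' @inheritParams vr2
#' @return Expected life-years.
#' @export
vr4 <- function(k, vm) {
  vr1(k, vm$params) + vo4(k, vm)
}

#' Delist option value one signal above the delisting bound
#'
#' One more comorbidity triggers removal, so the option term capitalizes
#' the no-transplant life expectancy directly:
#' `vo5(k) = mu/(r+mu) * q_up(p(k)) * LNT`.
#'
#' @param k Net signal count.
#' @param params A [fontan_params()] object.
#' @return Option value in life-years; never exceeds `mu/(r+mu) * LNT`.
#' @export
vo5 <- function(k, params) {
  params <- as_fontan_params(params)
  p <- posterior_good(k, params$theta)
  params$mu / (params$r + params$mu) * q_up(p, params$theta) * params$LNT
}

#' Total value of being listed one signal above the delisting bound
#'
#' `vr5 = vr1 + vo5`.
#'
#' @inheritParams vo5
#' @return Expected life-years.
#' @export
vr5 <- function(k, params) {
  vr1(k, params) + vo5(k, params)
}

#' Value of the delisted (too unwell) state
#'
#' The patient keeps the no-transplant life expectancy: a constant `LNT`,
#' independent of the net count.
#'
#' @param params A [fontan_params()] object.
#' @return `LNT`, in life-years.
#' @export
vr6 <- function(params) {
  as_fontan_params(params)$LNT
}

#' Solve the option constants A and B
#'
#' `A` scales the waiting-option value [vr2()] and `B` the delist-option
#' value [vo4()]. Each is pinned by one value-matching condition at its
#' threshold; the remaining condition of each pair then holds automatically
#' at the closed-form belief bounds and is exposed as a residual by
#' [boundary_residuals()].
#'
#' The model's belief interchange for the listed region (`theta` and
#' `1 - theta` swapped, so the Good-outcome probability is the complement)
#' is equivalent to negating the net-count argument: `p(-k) = 1 - p(k)`.
#' The value-matching algebra behind the closed-form thresholds operates on
#' the interchanged scale, so the conditions are imposed at the evaluation
#' points `-kH` and `-kL`; see the methods vignette for the full account.
#'
#' @param params A [fontan_params()] object.
#' @param thresholds Optional precomputed [listing_thresholds()].
#' @return An object of class `fontan_value_model` with fields `A`, `B`,
#'   `params`, `thresholds`.
#' @export
solve_constants <- function(params, thresholds = NULL) {
  params <- as_fontan_params(params)
  if (is.null(thresholds)) thresholds <- listing_thresholds(params)
  th <- params$theta
  disc <- params$mu / (params$r + params$mu)
  b1 <- thresholds$beta1
  b2 <- thresholds$beta2

  # A from the waiting-side matching condition one step above the (interchanged)
  # upper threshold: vr2 = vr3 there, linear in A.
  xH <- -thresholds$kH
  x1 <- xH + 1
  p1 <- posterior_good(x1, th)
  lhs_coef <- b1^x1 / denom_k(x1, th)
  rhs_coef <- disc * q_up(p1, th) * b1^(xH + 2) / denom_k(xH + 2, th)
  rhs_const <- disc * q_down(p1, th) * vr1(xH, params)
  if (abs(lhs_coef - rhs_coef) < 1e-300) {
    stop("solve_constants: singular linear solve for A", call. = FALSE)
  }
  A <- rhs_const / (lhs_coef - rhs_coef)

  # B from the listed-side matching condition one comorbidity above the
  # (interchanged) delisting threshold: vo4 = vo5 there, linear in B.
  xL <- -(thresholds$kL + 1)
  vo5_at <- vo5(xL, params)
  B <- vo5_at * denom_k(xL, th) / b2^xL

  structure(
    list(A = A, B = B, params = params, thresholds = thresholds),
    class = "fontan_value_model"
  )
}

#' @export
print.fontan_value_model <- function(x, ...) {
  cat(sprintf("Value model: A = %.6g, B = %.6g (kH = %.4f, kL = %.4f)\n",
              x$A, x$B, x$thresholds$kH, x$thresholds$kL))
  invisible(x)
}

#' Boundary-condition residuals at the closed-form thresholds
#'
#' The four value-matching conditions that pin the thresholds and the
#' option constants, evaluated at the closed-form `kH` and `kL`:
#' upper value matching (`vr1 = vr3` at the threshold), upper option
#' matching (`vr2 = vr3` one step above, zero by construction of `A`),
#' lower value matching (the listed value nets to `LNT` at the delisting
#' threshold), and lower option matching (`vo4 = vo5` one step above, zero
#' by construction of `B`). All four vanish to numerical precision for any
#' valid parameter set, verifying that the closed-form belief bounds solve
#' their defining systems. Conditions are evaluated at the interchanged
#' points (see [solve_constants()]); on the lower side the delist-option
#' premium enters the indifference against `LNT` with negative sign (the
#' value of remaining listed equals the delist payoff plus the foregone
#' option premium).
#'
#' @param vm A value model from [solve_constants()].
#' @return Named numeric vector of four signed residuals:
#'   `upper_value_match`, `upper_option_match`, `lower_value_match`,
#'   `lower_option_match`.
#' @export
boundary_residuals <- function(vm) {
  stopifnot(inherits(vm, "fontan_value_model"))
  params <- vm$params
  trs <- vm$thresholds
  xH <- -trs$kH
  xL <- -trs$kL
  res_upper_vm <- vr1(xH, params) - vr3(xH, vm)
  res_upper_om <- vr2(xH + 1, vm) - vr3(xH + 1, vm)
  res_lower_vm <- (vr1(xL, params) - vo5(xL, params)) - params$LNT
  res_lower_om <- vo4(xL - 1, vm) - vo5(xL - 1, params)
  c(upper_value_match = res_upper_vm,
    upper_option_match = res_upper_om,
    lower_value_match = res_lower_vm,
    lower_option_match = res_lower_om)
}
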