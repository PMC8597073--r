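#' Lattice problem for the numerical threshold oracle
#'
#' Bundles everything the free-boundary lattice solver needs: the model
#' parameters, the integer lattice bounds (a buffered window around the
#' closed-form thresholds, which are used only to centre the search), the
#' length of the waiting-side tail on which the waiting-option recursion is
#' iterated, and the convergence controls of the fixed-point iteration.
#'
#' @param params A [fontan_params()] object.
#' @param thresholds Optional [listing_thresholds()] (computed if missing);
#'   used only to centre the lattice and the root brackets.
#' @param buffer Integer buffer added on both sides of the threshold window
#'   when building the lattice (default 8, at least 6).
#' @param n_tail Number of lattice points in the waiting-region tail used to
#'   impose the decay-at-infinity condition (default 60).
#' @param tol Sup-norm convergence tolerance of the value iteration.
#' @param max_iter Iteration cap; exceeding it is an error that reports the
#'   last sup-norm change.
#' @return An object of class `fontan_lattice_problem`.
#' @export
lattice_problem <- function(params, thresholds = NULL, buffer = 8,
                            n_tail = 60, tol = 1e-12, max_iter = 2e5) {
  params <- as_fontan_params(params)
  if (is.null(thresholds)) thresholds <- listing_thresholds(params)
  stopifnot(buffer >= 6, n_tail >= 20, tol > 0, max_iter > 0)
  k_min <- thresholds$kL_floor - buffer
  k_max <- thresholds$kH_ceil + buffer
  structure(
    list(params = params, thresholds = thresholds,
         k_min = k_min, k_max = k_max,
         n_tail = as.integer(n_tail), tol = tol, max_iter = as.integer(max_iter)),
    class = "fontan_lattice_problem"
  )
}

# Fixed-point iteration of the waiting-layer recursion on the offset grid
# x + 0:n_tail, anchored at the immediate-listing value on the left and the
# decay asymptote (zero option value) on the right. The Bellman operator is
# a contraction with modulus mu/(r+mu); the sup-norm change per sweep is
# recorded so the geometric decay can be inspected.
iterate_waiting_layer <- function(x, problem) {
  pm <- problem$params
  th <- pm$theta
  disc <- pm$mu / (pm$r + pm$mu)
  n <- problem$n_tail
  grid <- x + 0:n
  p <- posterior_good(grid, th)
  qd <- q_down(p, th)
  qu <- q_up(p, th)
  U <- numeric(n + 1)
  U[1] <- vr1(x, pm)
  deltas <- numeric(0)
  i <- 2:n
  for (it in seq_len(problem$max_iter)) {
    Un <- U
    Un[i] <- disc * (qd[i] * U[i - 1] + qu[i] * U[i + 1])
    d <- max(abs(Un - U))
    if (length(deltas) < 200) deltas <- c(deltas, d)
    U <- Un
    if (d < problem$tol) {
      return(list(U = U, iterations = it, deltas = deltas))
    }
  }
  stop("waiting-layer value iteration did not converge within ",
       problem$max_iter, " sweeps; last sup-norm change ",
       format(max(abs(Un - U))), call. = FALSE)
}

# Value-matching defect of the upper free boundary at interchanged point x:
# zero when the immediate-listing value matches the one-step continuation
# built from the iterated waiting layer.
upper_matching_defect <- function(x, problem) {
  pm <- problem$params
  th <- pm$theta
  disc <- pm$mu / (pm$r + pm$mu)
  lay <- iterate_waiting_layer(x, problem)
  p <- posterior_good(x, th)
  vr1(x, pm) - disc * (q_down(p, th) * vr1(x - 1, pm) +
                         q_up(p, th) * lay$U[2])
}

# Staying-listed net value against the delist payoff at interchanged point
# x; zero at the lower free boundary.
lower_matching_defect <- function(x, problem) {
  pm <- problem$params
  vr1(x, pm) - vo5(x, pm) - pm$LNT
}

expand_bracket <- function(f, lo, hi, problem, max_span = 200) {
  flo <- f(lo, problem); fhi <- f(hi, problem)
  while (sign(flo) == sign(fhi)) {
    lo <- lo - 2; hi <- hi + 2
    if (hi - lo > max_span) {
      stop("oracle: could not bracket the free boundary", call. = FALSE)
    }
    flo <- f(lo, problem); fhi <- f(hi, problem)
  }
  c(lo, hi)
}

#' Solve the pre-listing stopping problem on the signal lattice
#'
#' Recovers the upper listing threshold numerically, without using the
#' closed-form belief bounds: the waiting-region value is obtained by
#' fixed-point (value) iteration of the one-step signal recursion on a
#' lattice tail with the decay condition imposed at the far end, and the
#' free boundary is located by root-finding on the value-matching defect.
#' The recursion operates on the interchanged net-count scale (the listed
#' region's belief interchange maps `k` to `-k`); recovered thresholds are
#' mapped back to the reported scale by negation.
#'
#' @param problem A [lattice_problem()] object.
#' @return A list with `k_high_hat` (continuous threshold recovered on the
#'   reported scale), `edge` (its floor: the largest net count at which
#'   listing is indicated), `stop_set` (integer lattice points with
#'   `k <= edge`), `values` (data frame of lattice values on the
#'   interchanged grid at the recovered boundary), `iterations`, and
#'   `deltas` (sup-norm change per sweep, for contraction diagnostics).
#' @export
solve_prelisting <- function(problem) {
  stopifnot(inherits(problem, "fontan_lattice_problem"))
  centre <- -problem$thresholds$kH
  br <- expand_bracket(upper_matching_defect, centre - 3, centre + 3, problem)
  root <- stats::uniroot(upper_matching_defect, br, problem = problem,
                         tol = 1e-11)$root
  k_high_hat <- -root
  lay <- iterate_waiting_layer(root, problem)
  edge <- as.integer(floor(k_high_hat))
  lattice <- seq(problem$k_min, problem$k_max)
  list(k_high_hat = k_high_hat,
       edge = edge,
       stop_set = lattice[lattice <= edge],
       values = data.frame(x = root + seq(0, problem$n_tail), value = lay$U),
       iterations = lay$iterations,
       deltas = lay$deltas)
}

#' Solve the listed-patient delisting problem on the signal lattice
#'
#' Recovers the lower (delisting) threshold numerically by locating the
#' point where the value of remaining listed nets out to the no-transplant
#' life expectancy, using only the printed regional value structure (the
#' capitalized listing value and the one-step delist-option premium), not
#' the closed-form belief bound. As in [solve_prelisting()] the matching is
#' performed on the interchanged scale and mapped back by negation.
#'
#' @param problem A [lattice_problem()] object.
#' @return A list with `k_low_hat` (continuous threshold on the reported
#'   scale), `edge` (its floor: the delisting edge), `delist_set` (integer
#'   lattice points with `k <= edge`), and `B_hat` (delist-option constant
#'   implied by option matching one comorbidity above the recovered
#'   boundary).
#' @export
solve_listed <- function(problem) {
  stopifnot(inherits(problem, "fontan_lattice_problem"))
  centre <- -problem$thresholds$kL
  br <- expand_bracket(lower_matching_defect, centre - 3, centre + 3, problem)
  root <- stats::uniroot(lower_matching_defect, br, problem = problem,
                         tol = 1e-11)$root
  k_low_hat <- -root
  pm <- problem$params
  b2 <- beta2(pm)
  x1 <- root - 1
  B_hat <- vo5(x1, pm) * denom_k(x1, pm$theta) / b2^x1
  edge <- as.integer(floor(k_low_hat))
  lattice <- seq(problem$k_min, problem$k_max)
  list(k_low_hat = k_low_hat,
       edge = edge,
       delist_set = lattice[lattice <= edge],
       B_hat = B_hat)
}
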