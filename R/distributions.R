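#' Defective per-step choice/response-time distribution
#'
#' The joint outcome of a two-choice sequential-sampling model on a grid of
#' sampling steps: `p_upper[n]` is the probability that the process is
#' absorbed at the upper boundary (decision "A") at step `n`, and `p_lower[n]`
#' the same for the lower boundary (decision "B"). Both are *defective*
#' distributions: each sums to the probability of its decision, and the two
#' together sum to at most 1 (mass missing to 1 is probability of no decision
#' within the horizon).
#'
#' @param p_upper,p_lower Non-negative numeric vectors of equal length.
#' @param step Step duration in seconds.
#' @return A tibble of class `fpt_dist` with columns `n`, `time`, `p_upper`,
#'   `p_lower` and attribute `step`.
#' @export
fpt_dist <- function(p_upper, p_lower, step) {
  stopifnot(is.numeric(p_upper), is.numeric(p_lower),
            length(p_upper) == length(p_lower))
  if (any(p_upper < 0) || any(p_lower < 0)) {
    stop("per-step probabilities must be non-negative", call. = FALSE)
  }
  tot <- sum(p_upper) + sum(p_lower)
  # small overshoot of 1 is tolerated: solver quadrature is O(step^2) accurate
  if (tot > 1 + 1e-2) {
    stop(sprintf("total probability mass %.6f exceeds 1", tot), call. = FALSE)
  }
  n <- seq_along(p_upper)
  out <- tibble::tibble(n = n, time = n * step,
                        p_upper = p_upper, p_lower = p_lower)
  attr(out, "step") <- step
  class(out) <- c("fpt_dist", class(out))
  out
}

#' Summaries of a defective choice/RT distribution
#'
#' `total_mass()` is the probability of any decision within the horizon;
#' `choice_prob()` is the probability of the upper-boundary decision,
#' normalized by the total decided mass.
#'
#' @param dist An `fpt_dist`.
#' @return A single number.
#' @export
total_mass <- function(dist) sum(dist$p_upper) + sum(dist$p_lower)

#' @rdname total_mass
#' @export
choice_prob <- function(dist) sum(dist$p_upper) / total_mass(dist)

#' Renormalize a truncated defective distribution to total mass 1
#'
#' Inversion equates per-step densities, which requires the target and the
#' model to carry commensurate mass; truncated tails are therefore scaled up
#' before inversion and the truncation recorded.
#'
#' @param dist An `fpt_dist`.
#' @return The rescaled `fpt_dist`, with attribute `truncated_mass` holding
#'   the mass that was missing to 1.
#' @export
renormalize <- function(dist, ...) {
  tot <- total_mass(dist)
  if (tot <= 0) stop("cannot renormalize a distribution with zero mass", call. = FALSE)
  out <- fpt_dist(dist$p_upper / tot, dist$p_lower / tot, attr(dist, "step"))
  attr(out, "truncated_mass") <- max(0, 1 - tot)
  out
}

#' Total-variation distance between two defective choice/RT distributions
#'
#' Computed over the completed outcome space: per-step absorption at either
#' boundary plus the "no decision within horizon" atom. That is
#' `0.5 * (sum_n |dP_A,n| + sum_n |dP_B,n| + |d residual mass|)`.
#'
#' @param a,b `fpt_dist` objects on the same step grid (equal `step` and
#'   length).
#' @return A number in \[0, 1\].
#' @examples
#' d <- fpt_dist(c(0.5, 0.2), c(0.2, 0.1), 0.01)
#' dist_tv(d, d)  # 0
#' @export
dist_tv <- function(a, b) {
  if (!isTRUE(all.equal(attr(a, "step"), attr(b, "step"))) || nrow(a) != nrow(b)) {
    stop("distributions must share the same step size and horizon", call. = FALSE)
  }
  resid_a <- 1 - total_mass(a)
  resid_b <- 1 - total_mass(b)
  0.5 * (sum(abs(a$p_upper - b$p_upper)) +
           sum(abs(a$p_lower - b$p_lower)) +
           abs(resid_a - resid_b))
}

#' Kolmogorov-Smirnov distance between the upper-boundary RT distributions
#'
#' Compares the cumulative defective upper-boundary mass of two distributions
#' on a common grid (maximum absolute difference of the cumulative curves).
#' For distributions carrying raw per-second densities (solver or analytic
#' results) the cumulative curve is computed by trapezoid integration of the
#' density, so that it is directly comparable with empirical bin counts,
#' which are exact interval integrals; for empirical distributions it is the
#' running sum of bin masses.
#'
#' @param a,b `fpt_dist` objects on the same grid.
#' @return The sup-norm distance between the two cumulative curves.
#' @export
dist_ks_upper <- function(a, b) {
  if (nrow(a) != nrow(b)) stop("distributions must share the same horizon", call. = FALSE)
  max(abs(cum_upper(a) - cum_upper(b)))
}

cum_upper <- function(dist) {
  g <- attr(dist, "g")
  if (!is.null(g)) {
    step <- attr(dist, "step")
    gu <- pmax(g$g_upper, 0)
    step * (cumsum(gu) - gu / 2)  # trapezoid with g(0) = 0
  } else {
    cumsum(dist$p_upper)
  }
}

pad_dist <- function(dist, n_steps) {
  if (nrow(dist) >= n_steps) return(dist)
  extra <- n_steps - nrow(dist)
  fpt_dist(c(dist$p_upper, rep(0, extra)), c(dist$p_lower, rep(0, extra)),
           attr(dist, "step"))
}
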