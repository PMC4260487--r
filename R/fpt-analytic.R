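#' Closed-form first-passage-time distributions for constant boundaries
#'
#' Independent oracle for the forward solver: the classical infinite-series
#' solution for a drifted Wiener process between two constant absorbing
#' barriers at `+a` and `-a`, started at 0. With barrier separation
#' `b = 2a`, start `z = a` above the lower barrier, drift `v` and variance
#' `s2`, the defective density of absorption at the *lower* barrier is
#' \deqn{g^-(t) = \frac{\pi s^2}{b^2} e^{-vz/s^2 - v^2 t/(2 s^2)}
#'   \sum_{k \ge 1} k \sin(k\pi z/b) e^{-k^2 \pi^2 s^2 t / (2 b^2)},}
#' and the upper-barrier density follows by reflection (`v -> -v`). The
#' series is truncated when terms fall below 1e-12. Per-step masses are
#' `g(n*step) * step`, matching the solver's convention.
#'
#' @param a Boundary half-width (> 0).
#' @param ev An [evidence()] object.
#' @param n_steps Horizon in steps.
#' @return An [fpt_dist()] with attribute `g` (exact per-second densities)
#'   and attribute `p_upper_exact`, the closed-form absorption probability
#'   at the upper barrier (not truncated to the horizon).
#' @examples
#' d <- analytic_fpt_constant(1, evidence(0.05, 0.1, 0.01), 1500)
#' attr(d, "p_upper_exact")
#' @export
analytic_fpt_constant <- function(a, ev, n_steps) {
  ev <- as_evidence(ev)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
    stop("`a` must be a single positive number", call. = FALSE)
  }
  step <- ev$step
  tt <- step * seq_len(n_steps)
  b <- 2 * a
  z <- a
  g_lo <- series_two_barrier(tt, v = ev$xi, s2 = ev$s2, b = b, z = z)
  g_up <- series_two_barrier(tt, v = -ev$xi, s2 = ev$s2, b = b, z = b - z)
  p_up <- pmax(g_up * step, 0)
  p_lo <- pmax(g_lo * step, 0)
  out <- fpt_dist(p_up, p_lo, step)
  attr(out, "g") <- list(g_upper = g_up, g_lower = g_lo)
  attr(out, "p_upper_exact") <- absorb_prob_upper(a, ev)
  out
}

# defective density of lower-barrier absorption: barriers at 0 and b, start z
series_two_barrier <- function(tt, v, s2, b, z, tol = 1e-12, k_max = 10000L) {
  # choose enough terms for the smallest time requested
  t_min <- min(tt)
  decay <- pi^2 * s2 * t_min / (2 * b^2)
  k_need <- ceiling(sqrt(max(1, -log(tol) / decay))) + 5L
  k_need <- min(k_need, k_max)
  k <- seq_len(k_need)
  pre <- (pi * s2 / b^2) * exp(-v * z / s2 - v^2 * tt / (2 * s2))
  # terms: rows k, cols t
  mat <- (k * sin(k * pi * z / b)) * exp(-outer(k^2, tt) * (pi^2 * s2 / (2 * b^2)))
  pre * colSums(mat)
}

#' Absorption probability at the upper barrier (constant boundaries)
#'
#' Closed form for drifted Brownian motion between barriers at `+a` and `-a`
#' started at 0: `(1 - exp(-2 v a / s2)) / (1 - exp(-4 v a / s2))`, with the
#' zero-drift limit 1/2.
#'
#' @inheritParams analytic_fpt_constant
#' @return A probability.
#' @export
absorb_prob_upper <- function(a, ev) {
  ev <- as_evidence(ev)
  v <- ev$xi
  if (abs(v) * a / ev$s2 < 1e-12) return(0.5)
  expm1(-2 * v * a / ev$s2) / expm1(-4 * v * a / ev$s2)
}
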