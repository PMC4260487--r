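#' Free transition density and CDF of the Wiener evidence process
#'
#' Density (and distribution function) of the unbounded evidence tally at
#' `(x, t)` given that it was at `(y, tau)`, for a Wiener process with drift
#' `xi = mu/step` and infinitesimal variance `s2 = sigma^2/step`:
#' a Gaussian with mean `y + xi * (t - tau)` and variance `s2 * (t - tau)`.
#'
#' @param x Evidence level at the later time (vectorized).
#' @param t Later time in seconds.
#' @param y Evidence level at the earlier time (vectorized).
#' @param tau Earlier time in seconds; every `t` must exceed its `tau`.
#' @param ev An [evidence()] object.
#' @return Density values (`transition_density`) or lower-tail probabilities
#'   (`transition_cdf`).
#' @examples
#' ev <- evidence(0, 1, 1)
#' transition_density(0, 1, 0, 0, ev)  # dnorm(0) = 0.3989...
#' @export
transition_density <- function(x, t, y, tau, ev) {
  ev <- as_evidence(ev)
  dt <- t - tau
  if (any(dt <= 0)) stop("`t` must be strictly greater than `tau`", call. = FALSE)
  stats::dnorm(x, mean = y + ev$xi * dt, sd = sqrt(ev$s2 * dt))
}

#' @rdname transition_density
#' @export
transition_cdf <- function(x, t, y, tau, ev) {
  ev <- as_evidence(ev)
  dt <- t - tau
  if (any(dt <= 0)) stop("`t` must be strictly greater than `tau`", call. = FALSE)
  stats::pnorm(x, mean = y + ev$xi * dt, sd = sqrt(ev$s2 * dt))
}

#' Singularity-removed Volterra kernel
#'
#' The kernel of the transformed (second-kind) renewal equations,
#' `Psi(a(t), t | y, tau) = f(a(t), t | y, tau) / 2 * (a'(t) - (a(t) - y) / (t - tau))`.
#' Unlike the raw transition density, Psi stays bounded as `tau -> t` along a
#' smooth boundary (the bracket vanishes at the same rate the density blows
#' up), which is what makes stepwise quadrature of the system stable. For the
#' constant-drift Wiener process the drift terms of the general kernel cancel
#' exactly, so no drift correction appears in the bracket.
#'
#' @param a_val Boundary level `a(t)` (vectorized).
#' @param a_deriv Boundary derivative `a'(t)` (evidence per second).
#' @param t Later time in seconds.
#' @param y Evidence level at the earlier time (vectorized).
#' @param tau Earlier time; every `t` must exceed its `tau`.
#' @param ev An [evidence()] object.
#' @return Kernel values.
#' @export
psi_kernel <- function(a_val, a_deriv, t, y, tau, ev) {
  dt <- t - tau
  if (any(dt <= 0)) stop("`t` must be strictly greater than `tau`", call. = FALSE)
  transition_density(a_val, t, y, tau, ev) / 2 * (a_deriv - (a_val - y) / dt)
}

#' First-passage-time distributions through time-varying boundaries
#'
#' Maps a Gaussian evidence distribution and a pair of (possibly
#' time-varying) absorbing boundaries to the model's defective choice/RT
#' distributions, by stepping the coupled second-kind Volterra integral
#' equations for the first-passage densities `g_A` (upper) and `g_B` (lower)
#' with the singularity-removed kernel [psi_kernel()] and the composite
#' trapezoidal rule on the sampling grid. The diagonal (`tau = t`) kernel
#' value is its analytic limit, 0, for boundaries of bounded curvature, which
#' makes the stepping explicit. Returned per-step probabilities are
#' `P_X,n = g_X(n * step) * step`.
#'
#' @param bounds A [boundary_pair()] sharing its `step` with `ev`.
#' @param ev An [evidence()] object.
#' @param state A [diffusion_state()]; the start must lie strictly between
#'   the boundaries.
#' @param n_steps Horizon in steps; defaults to the full boundary table. If
#'   the boundaries touch before the horizon, the result is truncated there
#'   with a warning.
#' @return An [fpt_dist()], with attribute `g` holding the raw per-second
#'   first-passage densities (`g_upper`, `g_lower`).
#' @examples
#' ev <- evidence(0, 0.1, 0.01)
#' b <- boundary_constant(0.3, 400, 0.01)
#' d <- solve_fpt(b, ev)
#' choice_prob(d)  # 0.5 by symmetry
#' @export
solve_fpt <- function(bounds, ev, state = diffusion_state(), n_steps = nrow(bounds)) {
  ev <- as_evidence(ev)
  step <- boundary_step(bounds)
  if (!isTRUE(all.equal(step, ev$step))) {
    stop("`bounds` and `ev` must share the same step duration", call. = FALSE)
  }
  if (!(state$x0 < attr(bounds, "start_upper") && state$x0 > attr(bounds, "start_lower"))) {
    stop("initial state must lie strictly between the starting boundaries", call. = FALSE)
  }
  n_steps <- min(n_steps, nrow(bounds))
  open <- boundary_open_until(bounds)
  if (open < n_steps) {
    warning(sprintf("boundaries touch at step %d; truncating horizon", open + 1L),
            call. = FALSE)
    n_steps <- open
  }
  bd <- boundary_deriv(bounds)
  gg <- volterra_g(bd$upper[seq_len(n_steps)], bd$lower[seq_len(n_steps)],
                   bd$d_upper[seq_len(n_steps)], bd$d_lower[seq_len(n_steps)],
                   step, ev, state$x0, state$t0)
  if (any(!is.finite(gg$g_upper)) || any(!is.finite(gg$g_lower))) {
    stop("non-finite kernel values in the Volterra recursion", call. = FALSE)
  }
  # raw quadrature masses are kept: the trapezoid rule can overshoot total
  # mass by O(step^2), and rescaling would bias round-trip inversion
  p_up <- pmax(gg$g_upper * step, 0)
  p_lo <- pmax(gg$g_lower * step, 0)
  out <- fpt_dist(p_up, p_lo, step)
  if (open < nrow(bounds)) {
    # collapsed boundaries force absorption: remaining mass is assigned at the
    # touch step to the boundary nearest the expected surviving position
    remaining <- 1 - total_mass(out)
    if (remaining > 0 && n_steps >= 1L) {
      pos <- state$x0 + ev$xi * (n_steps * step)
      d_up <- abs(bounds$upper[[n_steps]] - pos)
      d_lo <- abs(bounds$lower[[n_steps]] - pos)
      w_up <- if (d_up < d_lo) 1 else if (d_up > d_lo) 0 else 0.5
      out$p_upper[[n_steps]] <- out$p_upper[[n_steps]] + w_up * remaining
      out$p_lower[[n_steps]] <- out$p_lower[[n_steps]] + (1 - w_up) * remaining
    }
  }
  attr(out, "g") <- gg
  out
}

# Core trapezoidal stepping of the coupled second-kind Volterra system.
# Endpoint quadrature weights carry zero contributions (g(t0) = 0; the
# diagonal kernel limit is 0), so each g(n) is explicit in g(1..n-1).
# `g1_init`/`g2_init` allow extending a committed solution from step `from`.
volterra_g <- function(up, lo, dup, dlo, step, ev, x0 = 0, t0 = 0,
                       g1_init = NULL, g2_init = NULL, from = 1L) {
  n_steps <- length(up)
  tt <- t0 + step * seq_len(n_steps)
  g1 <- numeric(n_steps)
  g2 <- numeric(n_steps)
  if (from > 1L) {
    k <- seq_len(from - 1L)
    g1[k] <- g1_init[k]
    g2[k] <- g2_init[k]
  }
  for (n in seq.int(from, n_steps)) {
    p1_start <- psi_kernel(up[[n]], dup[[n]], tt[[n]], x0, t0, ev)
    p2_start <- psi_kernel(lo[[n]], dlo[[n]], tt[[n]], x0, t0, ev)
    if (n == 1L) {
      g1[[1L]] <- -2 * p1_start
      g2[[1L]] <- 2 * p2_start
    } else {
      k <- seq_len(n - 1L)
      psi1_u <- psi_kernel(up[[n]], dup[[n]], tt[[n]], up[k], tt[k], ev)
      psi1_l <- psi_kernel(up[[n]], dup[[n]], tt[[n]], lo[k], tt[k], ev)
      psi2_u <- psi_kernel(lo[[n]], dlo[[n]], tt[[n]], up[k], tt[k], ev)
      psi2_l <- psi_kernel(lo[[n]], dlo[[n]], tt[[n]], lo[k], tt[k], ev)
      g1[[n]] <- -2 * p1_start + 2 * step * sum(g1[k] * psi1_u + g2[k] * psi1_l)
      g2[[n]] <- 2 * p2_start - 2 * step * sum(g1[k] * psi2_u + g2[k] * psi2_l)
    }
  }
  list(g_upper = g1, g_lower = g2)
}

#' Residual of the first-kind renewal relation
#'
#' Diagnostic: the solved first-passage densities must satisfy the original
#' first-kind Volterra relation linking the free transition density at the
#' boundary to the convolution of `g_A`, `g_B` with the free density. The
#' integrand has an integrable square-root singularity at the upper limit, so
#' it is evaluated by product integration: the smooth factor
#' `h(tau) = g(tau) f(a(t), t | a(tau), tau) sqrt(t - tau)` is interpolated
#' linearly on each cell and the `1/sqrt(t - tau)` weight integrated exactly.
#'
#' @param bounds,ev,state As in [solve_fpt()].
#' @param dist The [solve_fpt()] result for those inputs.
#' @return The maximum absolute residual over grid times (upper equation),
#'   normalized by the largest free boundary density, so that it measures
#'   quadrature error where mass actually flows.
#' @export
first_kind_residual <- function(bounds, ev, dist, state = diffusion_state()) {
  ev <- as_evidence(ev)
  step <- attr(dist, "step")
  g <- attr(dist, "g")
  n_steps <- nrow(dist)
  tt <- state$t0 + step * seq_len(n_steps)
  up <- bounds$upper[seq_len(n_steps)]
  lo <- bounds$lower[seq_len(n_steps)]
  bd <- boundary_deriv(bounds)
  worst <- 0
  lhs_max <- max(transition_density(up, tt, state$x0, state$t0, ev))
  for (n in 2:n_steps) {
    lhs <- transition_density(up[[n]], tt[[n]], state$x0, state$t0, ev)
    if (lhs < 1e-10) next
    k <- seq_len(n - 1L)
    dt_k <- tt[[n]] - tt[k]
    # smooth parts h(tau_k) for the upper/upper and lower/upper convolutions
    h_self <- g$g_upper[k] * transition_density(up[[n]], tt[[n]], up[k], tt[k], ev) * sqrt(dt_k)
    # endpoint limit of the self term
    h_end <- g$g_upper[[n]] *
      exp(-(bd$d_upper[[n]] - ev$xi)^2 * 0 / (2 * ev$s2)) / sqrt(2 * pi * ev$s2)
    h <- c(0, h_self, h_end)  # grid tau = t0, t1, ..., tn
    dd <- tt[[n]] - c(state$t0, tt[seq_len(n)])  # t - tau on that grid
    rhs <- prod_sqrt_integral(h, dd)
    # cross term (lower boundary history) is smooth at the endpoint: trapezoid
    cross <- g$g_lower[k] * transition_density(up[[n]], tt[[n]], lo[k], tt[k], ev)
    rhs <- rhs + step * sum(cross)
    worst <- max(worst, abs(rhs - lhs) / lhs_max)
  }
  worst
}

# integral of h(tau) / sqrt(t - tau) with h piecewise linear on the grid;
# `h` at nodes, `dd` = t - tau at nodes (decreasing to 0)
prod_sqrt_integral <- function(h, dd) {
  m <- length(h) - 1L
  k <- seq_len(m)
  d0 <- dd[k]
  d1 <- dd[k + 1L]
  w_int <- 2 * (sqrt(d0) - sqrt(d1))                # integral of weight
  w_mom <- d0 * w_int - (2 / 3) * (d0^1.5 - d1^1.5) # integral of (tau - tau_k) * weight
  lam <- d0 - d1
  sum(h[k] * w_int + (h[k + 1L] - h[k]) * w_mom / lam)
}
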