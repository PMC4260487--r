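#' Discretized pair of decision boundaries
#'
#' A boundary pair stores the upper and lower absorbing boundaries of a
#' two-choice diffusion model on the sampling grid `t_n = n * step`,
#' `n = 1, ..., N`, together with the starting values at `t = 0`. The
#' backward finite-difference derivative `a'(n) = (a(n) - a(n-1)) / step`
#' used by the Volterra kernel is well defined for every `n >= 1` because the
#' starting values are stored.
#'
#' @param upper,lower Numeric vectors of equal length: boundary levels at
#'   steps 1..N. `upper` must stay strictly above `lower` wherever the
#'   process can still be live.
#' @param step Sampling-step duration in seconds.
#' @param start_upper,start_lower Boundary values at time 0. Defaults are the
#'   first elements of `upper`/`lower`. `start_upper > 0 > start_lower` is
#'   required so an unbiased start at 0 is interior.
#'
#' @return A tibble of class `boundary_tbl` with columns `n`, `time`,
#'   `upper`, `lower`, and attributes `step`, `start_upper`, `start_lower`.
#' @examples
#' b <- boundary_pair(rep(1, 100), rep(-1, 100), step = 0.01)
#' head(boundary_deriv(b)$d_upper)
#' @export
boundary_pair <- function(upper, lower, step,
                          start_upper = upper[[1]], start_lower = lower[[1]]) {
  stopifnot(is.numeric(upper), is.numeric(lower), length(upper) == length(lower),
            length(upper) >= 1L, all(is.finite(upper)), all(is.finite(lower)))
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop("`step` must be a single positive number (seconds)", call. = FALSE)
  }
  if (!(start_upper > 0 && start_lower < 0)) {
    stop("starting values must satisfy start_upper > 0 > start_lower", call. = FALSE)
  }
  n <- seq_along(upper)
  out <- tibble::tibble(n = n, time = n * step, upper = upper, lower = lower)
  attr(out, "step") <- step
  attr(out, "start_upper") <- start_upper
  attr(out, "start_lower") <- start_lower
  class(out) <- c("boundary_tbl", class(out))
  out
}

#' Constant boundaries at +a and -a
#'
#' @param a Boundary half-width (> 0).
#' @param n_steps Number of sampling steps.
#' @param step Step duration in seconds.
#' @return A `boundary_tbl`.
#' @export
boundary_constant <- function(a, n_steps, step) {
  stopifnot(a > 0, n_steps >= 1)
  boundary_pair(rep(a, n_steps), rep(-a, n_steps), step,
                start_upper = a, start_lower = -a)
}

#' Boundaries from functions of time
#'
#' Evaluates `f_upper(t)` and `f_lower(t)` on the grid `t = step, ..., N*step`
#' (and at `t = 0` for the starting values).
#'
#' @param f_upper,f_lower Vectorized functions of time in seconds.
#' @param n_steps Number of sampling steps.
#' @param step Step duration in seconds.
#' @return A `boundary_tbl`.
#' @examples
#' boundary_from_fun(function(t) exp(-t), function(t) -exp(-t), 100, 0.01)
#' @export
boundary_from_fun <- function(f_upper, f_lower, n_steps, step) {
  tt <- step * seq_len(n_steps)
  boundary_pair(f_upper(tt), f_lower(tt), step,
                start_upper = f_upper(0), start_lower = f_lower(0))
}

#' Backward-difference boundary derivatives
#'
#' @param bounds A `boundary_tbl`.
#' @return The input tibble with columns `d_upper`, `d_lower` appended:
#'   `a'(n) = (a(n) - a(n-1)) / step`, using the stored starting values for
#'   `n = 1`.
#' @export
boundary_deriv <- function(bounds) {
  step <- attr(bounds, "step")
  up <- bounds$upper
  lo <- bounds$lower
  bounds$d_upper <- c(up[[1]] - attr(bounds, "start_upper"), diff(up)) / step
  bounds$d_lower <- c(lo[[1]] - attr(bounds, "start_lower"), diff(lo)) / step
  bounds
}

boundary_step <- function(bounds) attr(bounds, "step")

#' Last step at which the boundaries are still separated
#'
#' @param bounds A `boundary_tbl`.
#' @return The largest `n` such that `upper(k) > lower(k)` for all `k <= n`
#'   (0 if they touch immediately).
#' @export
boundary_open_until <- function(bounds) {
  bad <- which(bounds$upper <= bounds$lower)
  if (length(bad) == 0L) nrow(bounds) else min(bad) - 1L
}
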