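#' Gaussian evidence distribution for a sequential-sampling model
#'
#' Evidence samples are drawn from a Gaussian with mean `mu` and standard
#' deviation `sigma`, one sample every `step` seconds. In the diffusion limit
#' this corresponds to a Wiener process with drift `xi = mu / step` and
#' infinitesimal variance `s2 = sigma^2 / step`.
#'
#' @param mu Mean evidence per sample (unitless evidence).
#' @param sigma Standard deviation of evidence per sample; must be positive.
#' @param step Sampling-step duration in seconds; must be positive.
#'
#' @return An object of class `evidence_dist`: a list with fields `mu`,
#'   `sigma`, `step`, and the derived `xi` (drift rate, evidence per second)
#'   and `s2` (diffusion coefficient squared, evidence^2 per second).
#' @examples
#' ev <- evidence(mu = 0.05, sigma = 0.1, step = 0.01)
#' ev$xi   # 5: drift per second
#' ev$s2   # 1: infinitesimal variance per second
#' @export
evidence <- function(mu, sigma, step) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0) {
    stop("`step` must be a single positive number (seconds)", call. = FALSE)
  }
  out <- list(mu = mu, sigma = sigma, step = step,
              xi = mu / step, s2 = sigma^2 / step)
  if (!all(vapply(out, is.finite, logical(1)))) {
    stop("derived drift/diffusion coefficients are not finite", call. = FALSE)
  }
  class(out) <- "evidence_dist"
  out
}

#' @export
print.evidence_dist <- function(x, ...) {
  cat(sprintf(
    "<evidence_dist> mu = %g, sigma = %g per sample; step = %g s (xi = %g /s, s^2 = %g /s)\n",
    x$mu, x$sigma, x$step, x$xi, x$s2))
  invisible(x)
}

#' Initial state of the diffusion process
#'
#' @param x0 Initial evidence tally; must lie strictly between the boundaries
#'   at the starting time.
#' @param t0 Initial time in seconds.
#' @return A list of class `diffusion_state`.
#' @export
diffusion_state <- function(x0 = 0, t0 = 0) {
  stopifnot(is.numeric(x0), length(x0) == 1L, is.finite(x0),
            is.numeric(t0), length(t0) == 1L, is.finite(t0))
  structure(list(x0 = x0, t0 = t0), class = "diffusion_state")
}

as_evidence <- function(ev) {
  if (inherits(ev, "evidence_dist")) return(ev)
  stop("`ev` must be an `evidence_dist` created by `evidence()`", call. = FALSE)
}
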