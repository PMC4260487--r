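#' Equate a diffusion model to a Gaussian accumulator model
#'
#' Finds the time-varying boundaries that make a Wiener diffusion process
#' with the same per-sample Gaussian evidence distribution reproduce the
#' choice probabilities and response-time distributions of an accumulator
#' (race) model with constant thresholds: computes the accumulator's
#' defective distributions by state-space recursion, then inverts them
#' (point-wise phase plus piecewise-linear corrective refinement).
#'
#' @param spec An [acc_spec()].
#' @param cfg An [inversion_config()]; its `step` must match `spec$step`.
#' @param horizon Steps for the accumulator recursion; default covers the
#'   race until residual mass is negligible.
#' @param symmetric Use the symmetry-constrained inversion.
#' @param refine Apply [piecewise_refine()] (default TRUE).
#' @return An `fpt_inversion` whose `target` is the accumulator distribution;
#'   the achieved-vs-target distance is in `$tv`.
#' @examples
#' \donttest{
#' eq <- equate_models(acc_spec(0.01, 0.1), inversion_config())
#' eq$tv
#' }
#' @export
equate_models <- function(spec, cfg = inversion_config(step = spec$step),
                          horizon = NULL, symmetric = FALSE, refine = TRUE) {
  stopifnot(inherits(spec, "acc_spec"))
  if (!isTRUE(all.equal(spec$step, cfg$step))) {
    stop("`spec` and `cfg` must share the same step duration", call. = FALSE)
  }
  if (is.null(horizon)) horizon <- default_acc_horizon(spec)
  target <- accumulator_fpt(spec, horizon)
  ev <- evidence(spec$mu, spec$sigma, spec$step)
  fit <- if (symmetric) invert_symmetric(target, ev, cfg)
         else invert_boundaries(target, ev, cfg)
  if (refine) fit <- piecewise_refine(fit)
  fit
}

# enough steps for the race to finish: the slowest tally needs about
# K / E[positive part] samples; use a generous multiple, then extend if the
# residual mass is still visible
default_acc_horizon <- function(spec) {
  gain <- stats::dnorm(spec$mu / spec$sigma) * spec$sigma +
    spec$mu * stats::pnorm(spec$mu / spec$sigma)  # E[max(x, 0)]
  h <- ceiling(12 * spec$threshold / max(gain, 1e-6))
  max(h, 100L)
}
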