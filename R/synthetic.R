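#' Synthetic RT datasets
#'
#' Generators for the kinds of data the empirical pipeline consumes. They
#' emulate individual-subject 2AFC data for non-evidential stimuli: a choice
#' probability, right-skewed response-time distributions per alternative
#' (shifted Weibull), and a common non-decision shift. Defaults mimic an
#' accuracy-instruction condition: around 1000 usable trials per alternative,
#' decision times of a few hundred milliseconds on top of a ~0.3 s
#' non-decision time.
#'
#' `simulate_weibull_rts()` draws directly from shifted Weibull laws;
#' `simulate_diffusion_rts()` draws from a zero-drift (or any) diffusion with
#' known time-varying boundaries, which is the ground-truth generator for
#' end-to-end recovery checks.
#'
#' @param n_trials Number of trials.
#' @param p_choice Probability of alternative "A".
#' @param shape_a,scale_a,shape_b,scale_b Weibull parameters (shape unitless,
#'   scale seconds) of the decision-time distributions per alternative.
#' @param shift Non-decision shift in seconds added to every trial.
#' @param seed Integer seed.
#' @param subject,condition Labels attached to the records.
#' @return A tibble with columns `subject`, `condition`, `choice`, `rt`.
#' @examples
#' d <- simulate_weibull_rts(200, seed = 1)
#' table(d$choice)
#' @export
simulate_weibull_rts <- function(n_trials = 2000, p_choice = 0.5,
                                 shape_a = 1.8, scale_a = 0.35,
                                 shape_b = shape_a, scale_b = scale_a,
                                 shift = 0.3, seed = 1,
                                 subject = "S1", condition = "accuracy") {
  stopifnot(n_trials > 0, p_choice >= 0, p_choice <= 1,
            shape_a > 0, scale_a > 0, shape_b > 0, scale_b > 0, shift >= 0)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  is_a <- stats::runif(n_trials) < p_choice
  rt <- ifelse(is_a,
               stats::rweibull(n_trials, shape_a, scale_a),
               stats::rweibull(n_trials, shape_b, scale_b)) + shift
  tibble::tibble(subject = subject, condition = condition,
                 choice = ifelse(is_a, "A", "B"), rt = rt)
}

#' @rdname simulate_weibull_rts
#' @param bounds,ev Boundary table and evidence distribution of the
#'   generating diffusion (see [boundary_pair()], [evidence()]).
#' @export
simulate_diffusion_rts <- function(bounds, ev, n_trials = 2000, shift = 0.3,
                                   seed = 1, subject = "S1",
                                   condition = "accuracy") {
  trials <- simulate_path_trials(bounds, ev, n_trials, seed)
  tibble::tibble(subject = subject, condition = condition,
                 choice = trials$choice, rt = trials$time + shift)
}
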