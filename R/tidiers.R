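#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a boundary inversion
#'
#' @param x An `fpt_inversion`.
#' @param ... Unused.
#' @return A tibble with one row per step: recovered boundaries, target and
#'   achieved per-step probabilities, per-step residuals, and `phase`
#'   ("pointwise" up to the critical step, "refined" beyond).
#' @method tidy fpt_inversion
#' @export
tidy.fpt_inversion <- function(x, ...) {
  tibble::tibble(
    n = x$bounds$n,
    time = x$bounds$time,
    upper = x$bounds$upper,
    lower = x$bounds$lower,
    p_upper_target = x$target$p_upper,
    p_lower_target = x$target$p_lower,
    p_upper_achieved = x$achieved$p_upper,
    p_lower_achieved = x$achieved$p_lower,
    phase = ifelse(x$bounds$n <= x$main_until, "pointwise", "refined")
  )
}

#' @rdname tidy.fpt_inversion
#' @return For `glance()`: a one-row tibble with the achieved-vs-target
#'   total-variation distance, the summed per-step deviation, choice
#'   probabilities, the critical step and convergence flags.
#' @method glance fpt_inversion
#' @export
glance.fpt_inversion <- function(x, ...) {
  tibble::tibble(
    tv = x$tv,
    objective = x$objective,
    p_upper_target = choice_prob(x$target),
    p_upper_achieved = choice_prob(x$achieved),
    main_until = x$main_until,
    n_steps = nrow(x$bounds),
    symmetric = x$symmetric,
    refined = x$refined,
    converged = x$converged
  )
}

#' Tidy and glance methods for Weibull RT fits
#'
#' @param x A `weibull_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`term`, `estimate`); `glance()`:
#'   one-row fit summary.
#' @method tidy weibull_fit
#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble::tibble(term = c("shape", "scale", "shift", "choice_prob"),
                 estimate = c(x$shape, x$scale, x$shift, x$choice_prob))
}

#' @rdname tidy.weibull_fit
#' @method glance weibull_fit
#' @export
glance.weibull_fit <- function(x, ...) {
  tibble::tibble(choice = x$choice, shape = x$shape, scale = x$scale,
                 shift = x$shift, choice_prob = x$choice_prob,
                 n = x$n, loglik = x$loglik)
}

#' @rdname tidy.fpt_inversion
#' @method tidy fpt_empirical
#' @export
tidy.fpt_empirical <- function(x, ...) tidy(x$fit)

#' @rdname tidy.fpt_inversion
#' @method glance fpt_empirical
#' @export
glance.fpt_empirical <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$fit),
    tibble::tibble(shift = x$shift,
                   start_upper = attr(x$fit$bounds, "start_upper"),
                   start_lower = attr(x$fit$bounds, "start_lower"),
                   gof_p_A = x$gof$p_value[x$gof$choice == "A"],
                   gof_p_B = x$gof$p_value[x$gof$choice == "B"]))
}
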