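#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a defective choice/RT distribution
#'
#' Per-step probabilities for the two alternatives, weighted by their choice
#' probabilities (the two panels integrate to p and 1 - p).
#'
#' @param object An [fpt_dist()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fpt_dist
#' @export
autoplot.fpt_dist <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("p_upper", "p_lower"),
                              names_to = "boundary", values_to = "p")
  long$boundary <- factor(long$boundary, c("p_upper", "p_lower"),
                          c("A (upper)", "B (lower)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$p)) +
    ggplot2::geom_col(width = attr(object, "step"), fill = "grey55") +
    ggplot2::facet_wrap(ggplot2::vars(.data$boundary), ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "per-step probability") +
    ggplot2::theme_minimal()
}

#' Plot a boundary pair
#'
#' @param object A [boundary_pair()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot boundary_tbl
#' @export
autoplot.boundary_tbl <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("upper", "lower"),
                              names_to = "boundary", values_to = "level")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$level,
                                     group = .data$boundary)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "evidence level") +
    ggplot2::theme_minimal()
}

#' Boundary and RT-distribution panels for an inversion result
#'
#' One combined figure: recovered boundaries on the left (the point-wise
#' phase solid, the piecewise-refined phase broken), and on the right the
#' per-alternative response-time distributions, target as a line over the
#' achieved histogram, annotated with the achieved choice probabilities.
#'
#' @param object An `fpt_inversion` (or `fpt_empirical`).
#' @param ... Unused.
#' @return A patchwork object.
#' @method autoplot fpt_inversion
#' @export
autoplot.fpt_inversion <- function(object, ...) {
  td <- tidy(object)
  step <- attr(object$target, "step")
  bl <- tidyr::pivot_longer(td, c("upper", "lower"),
                            names_to = "boundary", values_to = "level")
  p_bounds <- ggplot2::ggplot(bl, ggplot2::aes(x = .data$time, y = .data$level,
                                               group = .data$boundary,
                                               linetype = .data$phase)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(pointwise = "solid", refined = "31"),
                                   guide = "none") +
    ggplot2::labs(x = "time (s)", y = "evidence level", title = "boundaries") +
    ggplot2::theme_minimal()
  p_up <- sum(td$p_upper_achieved)
  p_lo <- sum(td$p_lower_achieved)
  rt_panel <- function(ach, tgt, lab, p_ann) {
    df <- tibble::tibble(time = td$time, achieved = ach, target = tgt)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
      ggplot2::geom_col(ggplot2::aes(y = .data$achieved), width = step,
                        fill = "grey70") +
      ggplot2::geom_line(ggplot2::aes(y = .data$target)) +
      ggplot2::annotate("text", x = Inf, y = Inf, hjust = 1.1, vjust = 1.5,
                        label = sprintf("p = %.3f", p_ann)) +
      ggplot2::labs(x = "time (s)", y = NULL, title = lab) +
      ggplot2::theme_minimal()
  }
  p_a <- rt_panel(td$p_upper_achieved, td$p_upper_target, "decision A", p_up)
  p_b <- rt_panel(td$p_lower_achieved, td$p_lower_target, "decision B", p_lo)
  patchwork::wrap_plots(p_bounds, patchwork::wrap_plots(p_a, p_b, ncol = 1),
                        nrow = 1, widths = c(2, 1))
}

#' @rdname autoplot.fpt_inversion
#' @method autoplot fpt_empirical
#' @export
autoplot.fpt_empirical <- function(object, ...) autoplot(object$fit)
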