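#' Shift response times by the minimum observed value
#'
#' The empirical stand-in for non-decision (encoding and response) time: the
#' smallest response time observed in the condition, minus a 1 ms guard so
#' every shifted response time stays strictly positive (a zero first-passage
#' time is impossible under the model).
#'
#' @param data A tibble with at least columns `rt` (seconds, > 0) and
#'   `choice` ("A"/"B"), as produced by [simulate_weibull_rts()] or
#'   [read_rt_data()].
#' @param guard Guard offset in seconds (default 0.001).
#' @return The tibble with `rt` shifted, in the original row order, carrying
#'   the shift in attribute `rt_shift`.
#' @examples
#' d <- tibble::tibble(rt = c(0.4, 0.5, 0.9), choice = c("A", "B", "A"))
#' shift_rts(d)$rt  # 0.001 0.101 0.501
#' @export
shift_rts <- function(data, guard = 0.001) {
  check_rt_data(data)
  shift <- min(data$rt) - guard
  shift <- max(shift, 0)
  out <- data
  out$rt <- data$rt - shift
  attr(out, "rt_shift") <- shift
  out
}

check_rt_data <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0L) {
    stop("`data` must be a non-empty data frame of RT records", call. = FALSE)
  }
  if (!all(c("rt", "choice") %in% names(data))) {
    stop("`data` needs columns `rt` and `choice`", call. = FALSE)
  }
  if (any(!is.finite(data$rt)) || any(data$rt <= 0)) {
    stop("all response times must be positive and finite", call. = FALSE)
  }
  if (!all(data$choice %in% c("A", "B"))) {
    stop('`choice` must be "A" or "B"', call. = FALSE)
  }
  invisible(data)
}

#' Maximum-likelihood Weibull fit to one alternative's response times
#'
#' Fits a two-parameter Weibull distribution to the (already shifted)
#' response times of the chosen alternative by maximum likelihood, and
#' records that alternative's choice probability as its share of the
#' records. Smoothing the empirical distributions this way is what makes the
#' boundary inversion stable: raw binned data carry multi-modalities that the
#' point-wise recursion amplifies.
#'
#' @param data A shifted RT tibble (see [shift_rts()]).
#' @param choice Which alternative to fit: "A" or "B".
#' @return An object of class `weibull_fit`: list with `shape`, `scale`,
#'   `shift` (carried from the data attribute, 0 if absent), `choice_prob`,
#'   `choice`, `n`, `loglik`, `convergence`.
#' @export
fit_weibull <- function(data, choice = c("A", "B")) {
  choice <- match.arg(choice)
  check_rt_data(data)
  x <- data$rt[data$choice == choice]
  if (length(x) < 10L) {
    stop(sprintf('fewer than 10 records for choice "%s"', choice), call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("degenerate response times (all equal); cannot fit a Weibull", call. = FALSE)
  }
  fd <- fitdistrplus::fitdist(x, "weibull")
  if (any(!is.finite(fd$estimate))) {
    stop("Weibull fit did not converge; estimates are not finite", call. = FALSE)
  }
  structure(list(shape = unname(fd$estimate[["shape"]]),
                 scale = unname(fd$estimate[["scale"]]),
                 shift = attr(data, "rt_shift") %||% 0,
                 choice_prob = mean(data$choice == choice),
                 choice = choice, n = length(x),
                 loglik = fd$loglik,
                 convergence = fd$convergence %||% 0L),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<weibull_fit> choice %s: shape %.4g, scale %.4g s (shift %.3f s), p = %.3f, n = %d\n",
    x$choice, x$shape, x$scale, x$shift, x$choice_prob, x$n))
  invisible(x)
}

#' Discretize fitted Weibull RT distributions into inversion targets
#'
#' Builds the defective per-step probabilities from two fitted Weibull
#' distributions, one per alternative, weighting each by its choice
#' probability: `P_X,n = p_X * (F_X(n * step) - F_X((n-1) * step))`.
#'
#' @param fit_A,fit_B [fit_weibull()] results for alternatives A and B.
#' @param step Step duration in seconds (the sampling interval of the
#'   planned inversion).
#' @param horizon Number of steps. If more than 1% of the mass lies beyond
#'   the horizon a warning is issued.
#' @return An [fpt_dist()].
#' @export
build_targets <- function(fit_A, fit_B, step, horizon) {
  stopifnot(inherits(fit_A, "weibull_fit"), inherits(fit_B, "weibull_fit"))
  tt <- step * (0:horizon)
  cdf_a <- stats::pweibull(tt, fit_A$shape, fit_A$scale)
  cdf_b <- stats::pweibull(tt, fit_B$shape, fit_B$scale)
  p_up <- fit_A$choice_prob * diff(cdf_a)
  p_lo <- fit_B$choice_prob * diff(cdf_b)
  out <- fpt_dist(p_up, p_lo, step)
  if (1 - total_mass(out) > 0.01) {
    warning(sprintf("horizon leaves %.3f of the mass undiscretized",
                    1 - total_mass(out)), call. = FALSE)
  }
  out
}

#' Decile chi-square goodness of fit for a Weibull RT fit
#'
#' Pearson's chi-square with the fitted distribution's deciles as bin edges
#' (expected count n/10 per bin) and degrees of freedom 10 - 1 - 2 = 7,
#' discounting the two estimated Weibull parameters.
#'
#' @param data Shifted RT tibble.
#' @param fit The [fit_weibull()] result whose alternative is tested.
#' @return A one-row tibble: `statistic`, `dof`, `p_value`.
#' @examples
#' chisq_pvalue(7.14, 7)  # 0.41 to two decimals
#' @export
chi_square_gof <- function(data, fit) {
  stopifnot(inherits(fit, "weibull_fit"))
  check_rt_data(data)
  x <- data$rt[data$choice == fit$choice]
  if (length(x) < 10L) {
    stop("fewer than 10 records for the fitted alternative", call. = FALSE)
  }
  edges <- c(0, stats::qweibull(seq(0.1, 0.9, by = 0.1), fit$shape, fit$scale), Inf)
  obs <- as.vector(table(cut(x, edges, right = TRUE)))
  expected <- length(x) / 10
  statistic <- sum((obs - expected)^2 / expected)
  dof <- 7L
  tibble::tibble(statistic = statistic, dof = dof,
                 p_value = chisq_pvalue(statistic, dof))
}

#' @rdname chi_square_gof
#' @param statistic Chi-square statistic.
#' @param dof Degrees of freedom.
#' @export
chisq_pvalue <- function(statistic, dof) {
  stats::pchisq(statistic, df = dof, lower.tail = FALSE)
}
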