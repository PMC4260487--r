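#' Specification of the Gaussian accumulator (race) model
#'
#' The accumulator model keeps two separate non-decreasing tallies. Each
#' sample `x ~ N(mu, sigma)` adds `x` to tally A when positive and `|x|` to
#' tally B when negative; the first tally to reach the symmetric criterion
#' `threshold` wins the race. Only the ratio `threshold / sigma` matters for
#' the shape of the predictions (the process scales with `sigma`), so the
#' default `threshold = 1` pairs naturally with diffusion starting boundaries
#' at +/-1.
#'
#' @param mu,sigma Per-sample Gaussian evidence mean and SD (`sigma > 0`).
#' @param threshold Criterion level K shared by both tallies (> 0).
#' @param step Sampling-step duration in seconds.
#' @param state_cells Number of grid cells per tally axis for the discrete
#'   state-space recursion (>= 50). Cells must be no wider than `sigma / 2`
#'   so the discretized increment distribution is resolved.
#' @return An object of class `acc_spec`.
#' @export
acc_spec <- function(mu, sigma, threshold = 1, step = 0.01, state_cells = 200L) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            sigma > 0, threshold > 0, step > 0)
  state_cells <- as.integer(state_cells)
  if (state_cells < 50L) stop("`state_cells` must be at least 50", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, threshold = threshold,
                 step = step, state_cells = state_cells),
            class = "acc_spec")
}

#' Choice/RT distributions of the accumulator model by state-space recursion
#'
#' Propagates the joint sub-threshold probability mass of the two tallies
#' over a 2-D grid. Increments are discretized by cell-averaged
#' probabilities (CDF differences), which conserves mass exactly; the mass
#' pushed past the criterion on either axis at step `n` is accumulated into
#' the defective per-step probabilities `P_A,n` / `P_B,n`. Because a single
#' sample feeds only one tally, the two cannot cross on the same sample.
#'
#' @param spec An [acc_spec()].
#' @param horizon Number of steps; must be large enough that the residual
#'   (undecided) mass is below 1e-3, otherwise a warning is issued.
#' @return An [fpt_dist()].
#' @examples
#' d <- accumulator_fpt(acc_spec(0.05, 0.1), horizon = 150)
#' choice_prob(d)
#' @export
accumulator_fpt <- function(spec, horizon) {
  stopifnot(inherits(spec, "acc_spec"), horizon >= 1)
  K <- spec$threshold
  C <- spec$state_cells
  h <- K / C
  if (h > spec$sigma / 2) {
    stop(sprintf(paste0(
      "state grid too coarse: cell width %.4g exceeds sigma/2 = %.4g; ",
      "increase `state_cells` to at least %d"),
      h, spec$sigma / 2, ceiling(2 * K / spec$sigma)), call. = FALSE)
  }
  # Toeplitz transition probabilities: displacement d cells, from midpoint m_i
  # P(i -> i + d) = P(x in [(d - 0.5) h, (d + 0.5) h) intersect (0, inf))
  d <- 0:(C - 1L)
  edge_lo <- pmax((d - 0.5) * h, 0)
  edge_hi <- (d + 0.5) * h
  p_pos <- stats::pnorm(edge_hi, spec$mu, spec$sigma) -
    stats::pnorm(edge_lo, spec$mu, spec$sigma)
  p_neg <- stats::pnorm(-edge_lo, spec$mu, spec$sigma) -
    stats::pnorm(-edge_hi, spec$mu, spec$sigma)
  T_A <- matrix(0, C, C)
  T_B <- matrix(0, C, C)
  for (i in seq_len(C)) {
    j <- i:C
    T_A[j, i] <- p_pos[j - i + 1L]
    T_B[j, i] <- p_neg[j - i + 1L]
  }
  # absorption is the complement of staying on the grid for that axis's sign,
  # so mass is conserved exactly under the cell-averaged discretization
  abs_A <- pmax(stats::pnorm(0, spec$mu, spec$sigma, lower.tail = FALSE) - colSums(T_A), 0)
  abs_B <- pmax(stats::pnorm(0, spec$mu, spec$sigma) - colSums(T_B), 0)

  M <- matrix(0, C, C)
  M[1L, 1L] <- 1  # both tallies start at 0 (first cell)
  p_up <- numeric(horizon)
  p_lo <- numeric(horizon)
  for (n in seq_len(horizon)) {
    rs <- rowSums(M)
    cs <- colSums(M)
    p_up[[n]] <- sum(abs_A * rs)
    p_lo[[n]] <- sum(abs_B * cs)
    M <- T_A %*% M + M %*% t(T_B)
  }
  out <- fpt_dist(p_up, p_lo, spec$step)
  if (1 - total_mass(out) > 1e-3) {
    warning(sprintf("residual undecided mass %.4g exceeds 1e-3; increase `horizon`",
                    1 - total_mass(out)), call. = FALSE)
  }
  out
}

#' Monte Carlo simulation of the accumulator race
#'
#' Direct trial-level simulation of the race between the two tallies;
#' reproducible given `seed`. A single sample feeds only one tally, so
#' simultaneous crossings cannot occur (a sample exactly equal to zero, a
#' null event, would leave both tallies unchanged).
#'
#' @param spec An [acc_spec()].
#' @param n_trials Number of trials (> 0).
#' @param seed Integer seed.
#' @param horizon Maximum number of steps; unabsorbed trials land in an
#'   overflow bucket reported via the `overflow` attribute.
#' @return An [fpt_dist()] of empirical relative frequencies.
#' @export
accumulator_simulate <- function(spec, n_trials, seed, horizon = 10000L) {
  stopifnot(inherits(spec, "acc_spec"), n_trials > 0)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  K <- spec$threshold
  sa <- numeric(n_trials)
  sb <- numeric(n_trials)
  idx <- seq_len(n_trials)
  out_n <- integer(n_trials)
  out_up <- logical(n_trials)
  for (n in seq_len(horizon)) {
    if (length(idx) == 0L) break
    x <- stats::rnorm(length(idx), spec$mu, spec$sigma)
    pos <- x > 0
    sa <- sa + ifelse(pos, x, 0)
    sb <- sb + ifelse(pos, 0, -x)
    hit_a <- sa >= K
    hit_b <- !hit_a & sb >= K
    hit <- hit_a | hit_b
    if (any(hit)) {
      out_n[idx[hit]] <- n
      out_up[idx[hit]] <- hit_a[hit]
      idx <- idx[!hit]
      sa <- sa[!hit]
      sb <- sb[!hit]
    }
  }
  done <- out_n > 0L
  n_steps <- max(out_n, 1L)
  p_up <- tabulate(out_n[done & out_up], nbins = n_steps) / n_trials
  p_lo <- tabulate(out_n[done & !out_up], nbins = n_steps) / n_trials
  out <- fpt_dist(p_up, p_lo, spec$step)
  attr(out, "overflow") <- 1 - sum(done) / n_trials
  out
}
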