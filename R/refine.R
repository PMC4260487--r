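#' Piecewise-linear corrective refinement of inverted boundaries
#'
#' Beyond the critical step the point-wise inversion accumulates numerical
#' error, so the boundary tail is refit as a connected piecewise-linear curve
#' with segments of `refine_segment_len` steps. Each segment's free endpoint
#' (one level per boundary; a single shared level in the symmetric case) is
#' chosen by direct search over the candidate grid — augmented with the
#' current point-wise value, so a segment can never get worse than it started
#' — to minimize the summed absolute deviation between the regenerated and
#' target per-step probabilities over the segment. Segments are committed
#' left to right, so the total objective never increases across segments.
#'
#' @param partial An `fpt_inversion` from [invert_boundaries()] or
#'   [invert_symmetric()].
#' @param target,ev,cfg Optional overrides; default to the values stored in
#'   `partial`.
#' @return An `fpt_inversion` with the tail rebuilt, `refined = TRUE`, and
#'   `converged = FALSE` if the direct search failed to reduce the total
#'   tail deviation below that of the unrefined tail (the better of the two
#'   tails is kept either way).
#' @examples
#' \donttest{
#' ev <- evidence(0.05, 0.1, 0.01)
#' target <- accumulator_fpt(acc_spec(0.05, 0.1), horizon = 300)
#' fit <- invert_boundaries(target, ev, inversion_config()) |> piecewise_refine()
#' fit$tv
#' }
#' @export
piecewise_refine <- function(partial, target = partial$target, ev = partial$ev,
                             cfg = partial$cfg, lookahead = c("slope", "flat", "none")) {
  lookahead <- match.arg(lookahead)
  stopifnot(inherits(partial, "fpt_inversion"))
  N <- nrow(partial$bounds)
  m0 <- partial$main_until
  if (m0 >= N) return(partial)  # nothing beyond the critical step: no-op
  step <- cfg$step
  I <- cfg$grid_cells
  L <- cfg$refine_segment_len
  su <- cfg$start_upper
  sl <- cfg$start_lower
  cu <- (seq_len(I) / I) * su
  cl <- -(seq_len(I) / I) * abs(sl)
  a1 <- partial$bounds$upper
  a2 <- partial$bounds$lower
  P_A <- target$p_upper
  P_B <- target$p_lower
  # self-consistent committed densities for the head
  g_all <- attr(partial$achieved, "g")
  g1 <- g_all$g_upper
  g2 <- g_all$g_lower
  unrefined_tail_obj <- sum(abs(partial$achieved$p_upper - P_A)[(m0 + 1L):N] +
                              abs(partial$achieved$p_lower - P_B)[(m0 + 1L):N])

  # segments are fitted only while the target still carries tail mass; beyond
  # that point the boundary is held flat (any remote level generates the same
  # negligible mass, and free segments there would chase quadrature noise)
  tail_mass <- rev(cumsum(rev(P_A + P_B)))
  refine_until <- max(which(tail_mass >= 1e-4), m0 + 1L)
  refine_until <- min(refine_until, N)

  seg_obj <- function(n0, len, a1v, a2v, look) {
    # deviation over steps n0+1..n0+len (+ a lookahead window with the
    # boundary held flat, so a segment cannot buy local fit by dumping mass
    # that the next steps will miss); extends the committed g
    if (lookahead == "none") look <- 0L
    to <- min(n0 + len + look, N)
    if (look > 0L && to > n0 + len) {
      ext <- seq_len(to - n0 - len)
      if (lookahead == "slope") {
        # continue each boundary at the segment's slope (floored so the two
        # sides cannot cross) — a closer stand-in for the next segment than a
        # flat continuation when the boundary is still descending
        sl_u <- a1v[[n0 + len]] - a1v[[n0 + len - 1L]]
        sl_l <- a2v[[n0 + len]] - a2v[[n0 + len - 1L]]
        a1v[(n0 + len + 1L):to] <- pmax(a1v[[n0 + len]] + ext * sl_u, 1e-4)
        a2v[(n0 + len + 1L):to] <- pmin(a2v[[n0 + len]] + ext * sl_l, -1e-4)
      } else {
        a1v[(n0 + len + 1L):to] <- a1v[[n0 + len]]
        a2v[(n0 + len + 1L):to] <- a2v[[n0 + len]]
      }
    }
    gg <- volterra_extend(a1v, a2v, step, ev, g1, g2, su, sl,
                          from = n0 + 1L, to = to)
    idx <- (n0 + 1L):to
    seg <- (n0 + 1L):(n0 + len)
    list(obj = sum(abs(pmax(gg$g1[idx] * step, 0) - P_A[idx]) +
                     abs(pmax(gg$g2[idx] * step, 0) - P_B[idx])),
         g1 = gg$g1[seg], g2 = gg$g2[seg])
  }

  n0 <- m0
  while (n0 < refine_until) {
    len <- min(L, N - n0)
    anchor_u <- if (n0 == 0L) su else a1[[n0]]
    anchor_l <- if (n0 == 0L) sl else a2[[n0]]
    w <- seq_len(len) / len
    e_u <- a1[[n0 + len]]
    e_l <- a2[[n0 + len]]
    cand_u <- unique(c(e_u, cu))
    cand_l <- unique(c(e_l, cl))
    eval_endpoints <- function(eu, el) {
      if (partial$symmetric) el <- -eu
      a1v <- a1; a2v <- a2
      a1v[(n0 + 1L):(n0 + len)] <- anchor_u + (eu - anchor_u) * w
      a2v[(n0 + 1L):(n0 + len)] <- anchor_l + (el - anchor_l) * w
      seg_obj(n0, len, a1v, a2v, look = len)
    }
    best <- NULL
    cell <- su / I
    for (sweep in 1:3) {
      for (side in c("u", "l")) {
        if (partial$symmetric && side == "l") next
        cand <- if (side == "u") cand_u else cand_l
        objs <- vapply(cand, function(cc) {
          if (side == "u") eval_endpoints(cc, e_l)$obj else eval_endpoints(e_u, cc)$obj
        }, numeric(1))
        ci <- which.min(objs)
        coarse <- cand[[ci]]
        # continuous polish of the endpoint within one grid cell of the
        # coarse optimum
        f1 <- function(cc) {
          if (side == "u") eval_endpoints(cc, e_l)$obj else eval_endpoints(e_u, cc)$obj
        }
        opt <- stats::optimize(f1, lower = coarse - cell, upper = coarse + cell,
                               tol = 1e-9)
        chosen <- if (opt$objective < objs[[ci]]) opt$minimum else coarse
        if (side == "u") e_u <- chosen else e_l <- chosen
        if (partial$symmetric) e_l <- -e_u
        best <- eval_endpoints(e_u, e_l)
      }
    }
    idx <- (n0 + 1L):(n0 + len)
    a1[idx] <- anchor_u + (e_u - anchor_u) * w
    a2[idx] <- anchor_l + (e_l - anchor_l) * w
    g1[idx] <- best$g1
    g2[idx] <- best$g2
    n0 <- n0 + len
  }
  if (n0 < N) {
    a1[(n0 + 1L):N] <- a1[[n0]]
    a2[(n0 + 1L):N] <- a2[[n0]]
  }

  out <- partial
  out$bounds <- boundary_pair(a1, a2, step, start_upper = su, start_lower = sl)
  out <- regenerate(out)
  refined_tail_obj <- sum(abs(out$achieved$p_upper - P_A)[(m0 + 1L):N] +
                            abs(out$achieved$p_lower - P_B)[(m0 + 1L):N])
  if (refined_tail_obj > unrefined_tail_obj) {
    out <- partial
    out$converged <- FALSE
    out$refined <- TRUE
    return(out)
  }
  out$refined <- TRUE
  out$converged <- TRUE
  out
}

# extend the Volterra recursion for steps from..to given committed g below
volterra_extend <- function(up, lo, step, ev, g1, g2, start_u, start_l, from, to) {
  dup <- c(up[[1]] - start_u, diff(up)) / step
  dlo <- c(lo[[1]] - start_l, diff(lo)) / step
  tt <- step * seq_along(up)
  for (n in from:to) {
    psi0_u <- psi_kernel(up[[n]], dup[[n]], tt[[n]], 0, 0, ev)
    psi0_l <- psi_kernel(lo[[n]], dlo[[n]], tt[[n]], 0, 0, ev)
    k <- seq_len(n - 1L)
    if (n == 1L) {
      g1[[1L]] <- -2 * psi0_u
      g2[[1L]] <- 2 * psi0_l
    } else {
      psi1_u <- psi_kernel(up[[n]], dup[[n]], tt[[n]], up[k], tt[k], ev)
      psi1_l <- psi_kernel(up[[n]], dup[[n]], tt[[n]], lo[k], tt[k], ev)
      psi2_u <- psi_kernel(lo[[n]], dlo[[n]], tt[[n]], up[k], tt[k], ev)
      psi2_l <- psi_kernel(lo[[n]], dlo[[n]], tt[[n]], lo[k], tt[k], ev)
      g1[[n]] <- -2 * psi0_u + 2 * step * sum(g1[k] * psi1_u + g2[k] * psi1_l)
      g2[[n]] <- 2 * psi0_l - 2 * step * sum(g1[k] * psi2_u + g2[k] * psi2_l)
    }
  }
  list(g1 = g1, g2 = g2)
}
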