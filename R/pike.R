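#' Discrete random-walk / race equivalence with unit-collapsing boundaries
#'
#' For evidence samples that are unit increments or decrements, a race model
#' whose two counters need `K` favorable samples is equivalent, path by path,
#' to a random walk on the summed evidence with time-varying boundaries that
#' decrease by one unit per step, starting at `+/-(2K - 1 + 1)`: the counter
#' for "A" reaches `K` at step `n` exactly when the walk `X_n` (pluses minus
#' minuses) reaches `2K - n`. These functions enumerate every sign sequence
#' of a given length and return the decision and decision step each model
#' produces, so the equivalence can be verified exhaustively.
#'
#' @param K Race criterion: number of favorable samples needed (>= 1).
#' @param n_steps Sequence length to enumerate (total sequences `2^n_steps`;
#'   keep below ~16).
#' @return A tibble with one row per sign sequence: `id`, `n_up` (number of
#'   +1 samples), `choice` ("A", "B" or NA if undecided), and `step` (decision
#'   step, NA if undecided).
#' @examples
#' identical(enumerate_race(2, 6)[c("choice", "step")],
#'           enumerate_walk_collapsing(2, 6)[c("choice", "step")])
#' @export
enumerate_race <- function(K, n_steps) {
  enumerate_signs(n_steps, function(x) {
    pos <- cumsum(x == 1L)
    neg <- cumsum(x == -1L)
    hit_a <- which(pos == K)
    hit_b <- which(neg == K)
    first_outcome(hit_a, hit_b)
  })
}

#' @rdname enumerate_race
#' @export
enumerate_walk_collapsing <- function(K, n_steps) {
  enumerate_signs(n_steps, function(x) {
    walk <- cumsum(x)
    n <- seq_along(x)
    hit_a <- which(walk >= 2 * K - n)
    hit_b <- which(walk <= -(2 * K - n))
    first_outcome(hit_a, hit_b)
  })
}

first_outcome <- function(hit_a, hit_b) {
  ta <- if (length(hit_a)) hit_a[[1L]] else Inf
  tb <- if (length(hit_b)) hit_b[[1L]] else Inf
  if (is.infinite(ta) && is.infinite(tb)) return(list(choice = NA_character_, step = NA_integer_))
  if (ta <= tb) list(choice = "A", step = as.integer(ta)) else list(choice = "B", step = as.integer(tb))
}

enumerate_signs <- function(n_steps, outcome_fun) {
  stopifnot(n_steps >= 1, n_steps <= 20)
  ids <- seq_len(2^n_steps) - 1L
  rows <- lapply(ids, function(id) {
    bits <- as.integer(intToBits(id))[seq_len(n_steps)]
    x <- ifelse(bits == 1L, 1L, -1L)
    out <- outcome_fun(x)
    list(id = id, n_up = sum(x == 1L), choice = out$choice, step = out$step)
  })
  tibble::tibble(
    id = vapply(rows, `[[`, integer(1), "id"),
    n_up = vapply(rows, `[[`, integer(1), "n_up"),
    choice = vapply(rows, `[[`, character(1), "choice"),
    step = vapply(rows, `[[`, integer(1), "step")
  )
}

#' Choice/RT distribution implied by an enumeration
#'
#' Weights each enumerated sequence by its Bernoulli probability and sums to
#' per-step defective choice probabilities.
#'
#' @param enum Output of [enumerate_race()] or [enumerate_walk_collapsing()].
#' @param p Probability of a +1 sample.
#' @param n_steps Horizon (defaults to the maximum decided step).
#' @param step Nominal step duration in seconds for the returned grid.
#' @return An [fpt_dist()].
#' @export
enumeration_dist <- function(enum, p = 0.5, n_steps = max(enum$step, na.rm = TRUE),
                             step = 1) {
  seq_len_total <- log2(nrow(enum))
  w <- p^enum$n_up * (1 - p)^(seq_len_total - enum$n_up)
  p_up <- p_lo <- numeric(n_steps)
  dec <- !is.na(enum$choice)
  for (i in which(dec)) {
    s <- enum$step[[i]]
    if (s <= n_steps) {
      if (enum$choice[[i]] == "A") p_up[[s]] <- p_up[[s]] + w[[i]]
      else p_lo[[s]] <- p_lo[[s]] + w[[i]]
    }
  }
  fpt_dist(p_up, p_lo, step)
}
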