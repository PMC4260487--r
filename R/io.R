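#' Read and write choice/RT distribution tables
#'
#' Distribution tables are CSV files with columns `step_index`, `time_s`,
#' `p_step_upper`, `p_step_lower` (any column order; addressed by name).
#' Writing uses full double precision so a write-then-read round trip is
#' lossless to well beyond 10 significant digits. Readers validate the
#' schema and report offending rows by line number.
#'
#' @param dist An [fpt_dist()].
#' @param path File path.
#' @return `read_distribution()` returns an [fpt_dist()];
#'   `write_distribution()` returns `path` invisibly.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "fpt_dist"))
  readr::write_csv(tibble::tibble(step_index = dist$n, time_s = dist$time,
                                  p_step_upper = dist$p_upper,
                                  p_step_lower = dist$p_lower), path)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  df <- read_validated(path, c("step_index", "time_s", "p_step_upper", "p_step_lower"))
  io_assert(df$p_step_upper >= 0, path, "negative p_step_upper")
  io_assert(df$p_step_lower >= 0, path, "negative p_step_lower")
  io_assert(c(TRUE, diff(df$time_s) > 0), path, "non-monotone time_s")
  step <- if (nrow(df) > 1) df$time_s[[2]] - df$time_s[[1]] else df$time_s[[1]]
  fpt_dist(df$p_step_upper, df$p_step_lower, step)
}

#' Read and write boundary tables
#'
#' Boundary tables are CSV files with columns `step_index`, `time_s`,
#' `upper`, `lower`; a `step_index` 0 row holds the starting values at time
#' 0.
#'
#' @param bounds A [boundary_pair()].
#' @param path File path.
#' @return `read_boundaries()` returns a [boundary_pair()];
#'   `write_boundaries()` returns `path` invisibly.
#' @export
write_boundaries <- function(bounds, path) {
  stopifnot(inherits(bounds, "boundary_tbl"))
  readr::write_csv(tibble::tibble(
    step_index = c(0L, bounds$n), time_s = c(0, bounds$time),
    upper = c(attr(bounds, "start_upper"), bounds$upper),
    lower = c(attr(bounds, "start_lower"), bounds$lower)), path)
  invisible(path)
}

#' @rdname write_boundaries
#' @export
read_boundaries <- function(path) {
  df <- read_validated(path, c("step_index", "time_s", "upper", "lower"))
  io_assert(c(TRUE, diff(df$time_s) > 0), path, "non-monotone time_s")
  # a step_index 0 row carries the starting values; without one, fall back to
  # the first row's levels
  has_start <- df$step_index[[1]] == 0
  start_u <- df$upper[[1]]
  start_l <- df$lower[[1]]
  body <- if (has_start) df[-1, ] else df
  step <- if (nrow(body) > 1) body$time_s[[2]] - body$time_s[[1]] else body$time_s[[1]]
  boundary_pair(body$upper, body$lower, step,
                start_upper = start_u, start_lower = start_l)
}

#' Read and write RT datasets
#'
#' RT datasets are CSV files with columns `subject`, `condition`, `choice`
#' ("A"/"B") and `rt_s` (seconds, positive).
#'
#' @param data A tibble with columns `subject`, `condition`, `choice`, `rt`.
#' @param path File path.
#' @return `read_rt_data()` returns the RT tibble (column `rt` in seconds);
#'   `write_rt_data()` returns `path` invisibly.
#' @export
write_rt_data <- function(data, path) {
  check_rt_data(data)
  readr::write_csv(tibble::tibble(subject = data$subject %||% "S1",
                                  condition = data$condition %||% "none",
                                  choice = data$choice, rt_s = data$rt), path)
  invisible(path)
}

#' @rdname write_rt_data
#' @export
read_rt_data <- function(path) {
  df <- read_validated(path, c("subject", "condition", "choice", "rt_s"))
  io_assert(is.finite(df$rt_s) & df$rt_s > 0, path, "non-positive rt_s")
  io_assert(df$choice %in% c("A", "B"), path, 'choice not "A"/"B"')
  tibble::tibble(subject = as.character(df$subject),
                 condition = as.character(df$condition),
                 choice = df$choice, rt = df$rt_s)
}

read_validated <- function(path, cols) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- suppressMessages(readr::read_csv(path, show_col_types = FALSE,
                                         progress = FALSE))
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

# data rows start at line 2 (after the header)
io_assert <- function(ok, path, what) {
  if (any(!ok)) {
    lines <- which(!ok) + 1L
    stop(sprintf("%s: %s at line(s) %s", path, what,
                 paste(utils::head(lines, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
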