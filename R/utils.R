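# Internal helpers shared across modules.

# Deterministic per-unit seed derivation; stays below .Machine$integer.max.
derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 7919 + as.numeric(index) * 104729) %%
               2147483629)
}

stopf <- function(fmt, ...) rlang::abort(sprintf(fmt, ...))
warnf <- function(fmt, ...) rlang::warn(sprintf(fmt, ...))

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("`%s` must be a probability in [0, 1].", name)
  invisible(x)
}

assert_pos <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stopf("`%s` must be strictly positive.", name)
  invisible(x)
}

cell_ids <- function(n) sprintf("cell_%03d", seq_len(n))

#' Convert a trace table to a frames-by-neurons matrix
#'
#' Trace tables carry one row per frame: a `time_s` column followed by one
#' numeric column per cell. All analysis code works on the plain matrix.
#'
#' @param traces A trace tibble (`time_s` plus one column per cell) or a
#'   numeric matrix already in frames x neurons orientation.
#' @return A numeric matrix, frames in rows, cells in columns, with cell IDs
#'   as column names.
#' @export
trace_matrix <- function(traces) {
  if (is.matrix(traces)) return(traces)
  stopifnot(is.data.frame(traces))
  keep <- setdiff(names(traces), "time_s")
  m <- as.matrix(traces[keep])
  if (!is.numeric(m)) stopf("trace columns must be numeric.")
  m
}

#' Assemble a trace tibble from a frames-by-neurons matrix
#'
#' @param mat Numeric matrix, frames in rows.
#' @param frame_rate_hz Acquisition rate used to fill `time_s`.
#' @return A tibble with `time_s` and one column per cell.
#' @export
as_trace_tbl <- function(mat, frame_rate_hz = 10) {
  colnames(mat) <- colnames(mat) %||% cell_ids(ncol(mat))
  dplyr::bind_cols(
    tibble::tibble(time_s = (seq_len(nrow(mat)) - 1) / frame_rate_hz),
    tibble::as_tibble(mat)
  )
}

# Moving average with a centered window; partial windows at the edges are
# normalized by the number of frames actually available, so output length and
# finiteness match the input.
centered_moving_average <- function(x, window) {
  if (window <= 1) return(x)
  n <- length(x)
  k <- rep(1, window)
  sums <- stats::filter(c(rep(0, window), x, rep(0, window)), k, sides = 2)
  sums <- sums[(window + 1):(window + n)]
  counts <- stats::filter(c(rep(0, window), rep(1, n), rep(0, window)),
                          k, sides = 2)[(window + 1):(window + n)]
  as.numeric(sums / counts)
}
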