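#' Read and write session components as delimited text
#'
#' Traces are stored as CSV with one row per frame (`time_s` plus one column
#' per cell), centroids as `cell_id, x_um, y_um`, events as
#' `time_s, event_type, correction_flag`, trials as the full trial table,
#' and ground truth as JSON.
#'
#' @param session A `cpt_session` from [generate_session()].
#' @param dir Output directory (created if missing).
#' @return `write_session()` returns the written file paths invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    traces = file.path(dir, "traces.csv"),
    centroids = file.path(dir, "centroids.csv"),
    events = file.path(dir, "events.csv"),
    trials = file.path(dir, "trials.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(session$traces, paths["traces"])
  readr::write_csv(session$centroids, paths["centroids"])
  readr::write_csv(session$events, paths["events"])
  readr::write_csv(session$trials, paths["trials"])
  jsonlite::write_json(session$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' @rdname write_session
#' @param path File path.
#' @export
read_traces <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  if (!"time_s" %in% names(tb)) stopf("trace file must have a time_s column.")
  tb
}

#' @rdname write_session
#' @export
read_centroids <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("cell_id", "x_um", "y_um")
  if (!all(need %in% names(tb)))
    stopf("centroid file needs columns: %s.", paste(need, collapse = ", "))
  tb
}

#' @rdname write_session
#' @export
read_events <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "event_type") %in% names(tb)))
    stopf("event file needs time_s and event_type columns.")
  tb
}

#' @rdname write_session
#' @export
read_trials <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  validate_trials(tb)
  tb
}
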