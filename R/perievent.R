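#' Peri-event analysis windows
#'
#' Window and test settings for peri-event modulation classification.
#' Defaults follow the standard workflow for this task: 8 s visual windows
#' on each side of the event, 3 s statistical windows ending/starting at the
#' event, 1000 circular shuffles, seed 0, two-tailed alpha 0.05.
#'
#' Statistical windows are half-open in frames: pre covers [-pre_start,
#' -pre_end) seconds and post covers [post_start, post_end) seconds relative
#' to the event frame, so with defaults each holds 30 frames at 10 Hz and
#' the event frame itself belongs to the post window.
#'
#' @param visual_pre_s,visual_post_s Visual window extent, seconds.
#' @param stat_pre_start_s,stat_pre_end_s Pre-event statistical window
#'   (seconds before the event; start > end).
#' @param stat_post_start_s,stat_post_end_s Post-event statistical window
#'   (seconds after the event; start < end).
#' @param n_shuffles Number of circular permutations.
#' @param alpha Two-tailed significance level.
#' @param seed RNG seed for the shuffle offsets.
#' @return List of class `peri_event_windows`.
#' @export
peri_event_windows <- function(visual_pre_s = 8, visual_post_s = 8,
                               stat_pre_start_s = 3, stat_pre_end_s = 0,
                               stat_post_start_s = 0, stat_post_end_s = 3,
                               n_shuffles = 1000, alpha = 0.05, seed = 0) {
  w <- list(visual_pre_s = visual_pre_s, visual_post_s = visual_post_s,
            stat_pre_start_s = stat_pre_start_s, stat_pre_end_s = stat_pre_end_s,
            stat_post_start_s = stat_post_start_s,
            stat_post_end_s = stat_post_end_s,
            n_shuffles = as.integer(n_shuffles), alpha = alpha,
            seed = as.integer(seed))
  if (w$n_shuffles < 1) stopf("n_shuffles must be >= 1.")
  if (w$alpha <= 0 || w$alpha >= 1) stopf("alpha must be in (0, 1).")
  if (w$stat_pre_start_s > w$visual_pre_s || w$stat_post_end_s > w$visual_post_s)
    stopf("visual windows must contain the statistical windows.")
  if (w$stat_pre_start_s <= w$stat_pre_end_s)
    stopf("stat_pre_start_s must exceed stat_pre_end_s.")
  if (w$stat_post_start_s >= w$stat_post_end_s)
    stopf("stat_post_end_s must exceed stat_post_start_s.")
  structure(w, class = "peri_event_windows")
}

# frame offsets (relative to the 0-based event frame) of the four windows
window_frames <- function(windows, rate) {
  list(
    vis = seq.int(-round(windows$visual_pre_s * rate),
                  round(windows$visual_post_s * rate)),
    pre = seq.int(-round(windows$stat_pre_start_s * rate),
                  -round(windows$stat_pre_end_s * rate) - 1L),
    post = seq.int(round(windows$stat_post_start_s * rate),
                   round(windows$stat_post_end_s * rate) - 1L)
  )
}

#' Z-score traces per neuron
#'
#' Standardizes each cell's trace to zero mean and unit SD over the full
#' session. Zero-variance cells are dropped with a warning.
#'
#' @param traces Trace tibble or frames x neurons matrix.
#' @return Object of the same kind as the input.
#' @export
zscore_traces <- function(traces) {
  m <- trace_matrix(traces)
  sds <- apply(m, 2, sd)
  bad <- sds == 0 | !is.finite(sds)
  if (any(bad)) {
    warnf("dropping %d zero-variance cell(s): %s.", sum(bad),
          paste(colnames(m)[bad], collapse = ", "))
    m <- m[, !bad, drop = FALSE]
    sds <- sds[!bad]
  }
  if (!ncol(m)) stopf("no cells left after removing zero-variance traces.")
  z <- scale(m)
  attr(z, "scaled:center") <- NULL; attr(z, "scaled:scale") <- NULL
  if (is.data.frame(traces)) {
    out <- as_trace_tbl(z, 1)
    out$time_s <- traces$time_s
    out
  } else z
}

#' Extract peri-event trace slices
#'
#' Cuts the visual window around each event into an event x neuron x frame
#' array at the native frame rate. The event frame is `floor(time * rate)`
#' (0-based); events whose visual window is not fully inside the session are
#' dropped and counted.
#'
#' @param traces Trace tibble or matrix (typically z-scored).
#' @param event_times_s Event times in seconds.
#' @param windows A [peri_event_windows()].
#' @param frame_rate_hz Acquisition rate.
#' @return Numeric array `events x neurons x frames` with attributes
#'   `frame_offsets` (frames relative to the event) and `n_dropped`.
#' @export
extract_peri_event <- function(traces, event_times_s,
                               windows = peri_event_windows(),
                               frame_rate_hz = 10) {
  m <- trace_matrix(traces)
  n_frames <- nrow(m)
  wf <- window_frames(windows, frame_rate_hz)
  ev0 <- floor(event_times_s * frame_rate_hz) # 0-based event frames
  keep <- ev0 + min(wf$vis) >= 0 & ev0 + max(wf$vis) <= n_frames - 1
  n_dropped <- sum(!keep)
  ev0 <- ev0[keep]
  if (!length(ev0)) stopf("no events with complete visual windows.")
  arr <- array(NA_real_, c(length(ev0), ncol(m), length(wf$vis)),
               dimnames = list(NULL, colnames(m), NULL))
  for (e in seq_along(ev0)) {
    arr[e, , ] <- t(m[ev0[e] + wf$vis + 1L, , drop = FALSE])
  }
  attr(arr, "frame_offsets") <- wf$vis
  attr(arr, "n_dropped") <- n_dropped
  attr(arr, "frame_rate_hz") <- frame_rate_hz
  attr(arr, "windows") <- windows
  arr
}

#' Peri-event delta activity
#'
#' Delta = mean over events of (mean activity in the post statistical window
#' minus mean activity in the pre statistical window), in z-units when the
#' input traces were z-scored.
#'
#' @param tensor Array from [extract_peri_event()].
#' @param windows A [peri_event_windows()]; defaults to the windows stored on
#'   the tensor.
#' @return Named numeric vector, one delta per neuron.
#' @export
delta_activity <- function(tensor, windows = attr(tensor, "windows")) {
  offs <- attr(tensor, "frame_offsets")
  rate <- attr(tensor, "frame_rate_hz")
  wf <- window_frames(windows, rate)
  pre_idx <- match(wf$pre, offs); post_idx <- match(wf$post, offs)
  if (anyNA(pre_idx) || anyNA(post_idx))
    stopf("statistical windows fall outside the extracted tensor.")
  post <- apply(tensor[, , post_idx, drop = FALSE], c(1, 2), mean)
  pre <- apply(tensor[, , pre_idx, drop = FALSE], c(1, 2), mean)
  colMeans(post - pre)
}

#' Circular-permutation null for delta activity
#'
#' Builds the null distribution of delta by circularly shifting the event
#' times relative to the trace: each shuffle draws one uniform offset in
#' [1, T-1] frames, shifts every event frame by it modulo T (one shared
#' offset per shuffle, preserving inter-event structure), and recomputes
#' delta with windows wrapping around the session edge. The same offsets
#' apply to every neuron.
#'
#' @inheritParams extract_peri_event
#' @return Matrix `n_shuffles x neurons` of null deltas, with attribute
#'   `offsets`.
#' @export
circular_permutation_null <- function(traces, event_times_s,
                                      windows = peri_event_windows(),
                                      frame_rate_hz = 10) {
  m <- trace_matrix(traces)
  n_frames <- nrow(m)
  wf <- window_frames(windows, frame_rate_hz)
  span <- max(abs(c(wf$pre, wf$post))) + 1L
  if (n_frames <= length(wf$vis))
    stopf("trace shorter than the peri-event window span.")
  ev0 <- floor(event_times_s * frame_rate_hz) %% n_frames
  set.seed(windows$seed)
  offsets <- sample.int(n_frames - 1L, windows$n_shuffles, replace = TRUE)
  null <- null_deltas_for_offsets(m, ev0, offsets, wf)
  attr(null, "offsets") <- offsets
  null
}

# Shared engine: wrapped-window deltas for arbitrary shift offsets, via
# cumulative sums over an edge-padded copy of the trace.
null_deltas_for_offsets <- function(m, ev0, offsets, wf) {
  n_frames <- nrow(m)
  pad <- max(abs(c(wf$pre, wf$post))) + 1L
  ext <- rbind(m[(n_frames - pad + 1):n_frames, , drop = FALSE], m,
               m[1:pad, , drop = FALSE])
  cs <- apply(ext, 2, cumsum)
  cs <- rbind(0, cs) # cs[i+1, ] = sum of ext rows 1..i
  # frame f (0-based, possibly in [-pad, n_frames+pad)) sits at ext row f+pad+1
  win_sum <- function(ev, lo, hi) {
    i1 <- ev + lo + pad      # row before the window start, 0-based+1 handled
    i2 <- ev + hi + pad + 1L
    (cs[i2 + 1L, , drop = FALSE] - cs[i1 + 1L, , drop = FALSE])
  }
  n_pre <- length(wf$pre); n_post <- length(wf$post)
  out <- matrix(NA_real_, length(offsets), ncol(m),
                dimnames = list(NULL, colnames(m)))
  for (j in seq_along(offsets)) {
    ev <- (ev0 + offsets[j]) %% n_frames
    post <- win_sum(ev, wf$post[1], wf$post[n_post])
    pre <- win_sum(ev, wf$pre[1], wf$pre[n_pre])
    out[j, ] <- colMeans(post / n_post - pre / n_pre)
  }
  out
}

#' Classify neurons by peri-event modulation
#'
#' The bootstrap probability of each neuron is the fraction of its null
#' deltas greater than or equal to the observed delta. A two-tailed test at
#' level `alpha` labels the neuron up-modulated when boot_p < alpha/2,
#' down-modulated when boot_p > 1 - alpha/2, and non-modulated otherwise.
#'
#' @param delta Named vector of observed deltas.
#' @param null_deltas Matrix from [circular_permutation_null()].
#' @param alpha Two-tailed significance level.
#' @return Tibble: `cell_id`, `delta`, `boot_p`, `label`.
#' @export
classify_modulation <- function(delta, null_deltas, alpha = 0.05) {
  if (!nrow(null_deltas)) stopf("empty null distribution.")
  stopifnot(length(delta) == ncol(null_deltas))
  boot_p <- colMeans(sweep(null_deltas, 2, delta, ">="))
  label <- dplyr::case_when(boot_p < alpha / 2 ~ "up",
                            boot_p > 1 - alpha / 2 ~ "down",
                            TRUE ~ "non")
  tibble::tibble(cell_id = names(delta) %||% cell_ids(length(delta)),
                 delta = unname(delta), boot_p = unname(boot_p),
                 label = factor(label, levels = c("up", "down", "non")))
}

#' Full peri-event modulation analysis
#'
#' Convenience wrapper: z-scores the traces, extracts peri-event slices,
#' computes observed deltas, builds the circular-permutation null, classifies
#' every neuron, and attaches the event-averaged visual-window trace.
#'
#' @inheritParams extract_peri_event
#' @return Tibble of class `perievent_result` (cell_id, delta, boot_p,
#'   label, mean_trace list-column) with the null matrix, windows, and event
#'   bookkeeping stored as attributes.
#' @export
peri_event_analysis <- function(traces, event_times_s,
                                windows = peri_event_windows(),
                                frame_rate_hz = 10) {
  z <- zscore_traces(traces)
  tensor <- extract_peri_event(z, event_times_s, windows, frame_rate_hz)
  delta <- delta_activity(tensor, windows)
  null <- circular_permutation_null(z, event_times_s, windows, frame_rate_hz)
  res <- classify_modulation(delta, null, windows$alpha)
  mean_mat <- apply(tensor, c(2, 3), mean)
  res$mean_trace <- lapply(seq_len(nrow(mean_mat)), function(i) mean_mat[i, ])
  structure(res,
            null_deltas = null,
            windows = windows,
            frame_offsets = attr(tensor, "frame_offsets"),
            n_events = dim(tensor)[1],
            n_dropped = attr(tensor, "n_dropped"),
            frame_rate_hz = frame_rate_hz,
            class = c("perievent_result", class(res)))
}

#' Event times for peri-event alignment
#'
#' Returns times of the selected active responses aligned either to the
#' screen touch (`"touch"`, the response time) or to the stimulus onset of
#' the same trials (`"stimulus"`).
#'
#' @param trials Trial table.
#' @param event_type `"hit"`, `"fa"`, or `"any"` (hits and false alarms).
#' @param alignment `"touch"` or `"stimulus"`.
#' @return Numeric vector of event times in seconds.
#' @export
peri_event_times <- function(trials, event_type = c("hit", "fa", "any"),
                             alignment = c("touch", "stimulus")) {
  event_type <- match.arg(event_type)
  alignment <- match.arg(alignment)
  keep <- switch(event_type,
                 hit = trials$outcome == "hit",
                 fa = trials$outcome == "FA",
                 any = trials$outcome %in% c("hit", "FA"))
  keep <- keep & !is.na(trials$response_s)
  if (alignment == "touch") trials$response_s[keep] else trials$onset_s[keep]
}

#' Overlap of modulated sets between two classifications
#'
#' Counts cells modulated in only one classification, the other, or both,
#' separately for up- and down-modulation (the Venn-diagram counts for e.g.
#' hit- vs false-alarm-locked modulation).
#'
#' @param labels_a,labels_b Classification tibbles (from
#'   [classify_modulation()] or [peri_event_analysis()]) over the same cells.
#' @return Tibble: `direction`, `only_a`, `only_b`, `both`.
#' @export
modulation_overlap <- function(labels_a, labels_b) {
  if (!setequal(labels_a$cell_id, labels_b$cell_id) ||
      nrow(labels_a) != nrow(labels_b))
    stopf("the two classifications must cover the same cells.")
  b <- labels_b[match(labels_a$cell_id, labels_b$cell_id), ]
  one <- function(dir) {
    a_set <- labels_a$label == dir; b_set <- b$label == dir
    tibble::tibble(direction = dir,
                   only_a = sum(a_set & !b_set),
                   only_b = sum(b_set & !a_set),
                   both = sum(a_set & b_set))
  }
  dplyr::bind_rows(one("up"), one("down"))
}
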