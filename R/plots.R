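#' Plot the decoded state sequence over behavior
#'
#' State ribbon over time with optional response markers.
#'
#' @param object A `state_sequence`.
#' @param trials Optional trial table; active responses are overlaid.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot state_sequence
#' @export
autoplot.state_sequence <- function(object, trials = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                        y = factor(.data$state))) +
    ggplot2::geom_tile(ggplot2::aes(fill = factor(.data$state)), height = 0.9) +
    ggplot2::labs(x = "time (s)", y = "decoded state", fill = "state") +
    ggplot2::theme_minimal()
  if (!is.null(trials)) {
    resp <- trials[trials$outcome %in% c("hit", "FA") &
                     !is.na(trials$response_s), ]
    p <- p + ggplot2::geom_rug(
      data = tibble::tibble(time_s = resp$response_s),
      ggplot2::aes(x = .data$time_s), inherit.aes = FALSE, sides = "t")
  }
  p
}

#' Plot peri-event mean traces by modulation label
#'
#' Event-averaged z-scored activity over the visual window, one line per
#' cell, faceted by classification.
#'
#' @param object A `perievent_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot perievent_result
#' @export
autoplot.perievent_result <- function(object, ...) {
  offs <- attr(object, "frame_offsets")
  rate <- attr(object, "frame_rate_hz")
  df <- tidyr::unnest_longer(
    dplyr::mutate(tibble::as_tibble(object),
                  t_s = list(offs / rate)),
    c("mean_trace", "t_s"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$mean_trace,
                                   group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "time from event (s)", y = "mean z-scored activity") +
    ggplot2::theme_minimal()
}

#' Plot an exponential decay fit
#'
#' Pair correlations against distance with the fitted A * exp(k * x) curve.
#'
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble::tibble(
    distance_um = seq(0, max(df$distance_um), length.out = 200))
  grid$r <- object$A * exp(object$k * grid$distance_um)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_um, y = .data$r)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_line(data = grid, color = "red") +
    ggplot2::labs(x = "pair distance (um)", y = "pairwise correlation") +
    ggplot2::theme_minimal()
}

#' Plot the inter-response latency series
#'
#' Latency between consecutive active responses over the session with the
#' mean + 2 SD disengagement threshold and detected periods shaded.
#'
#' @param trials Trial table or latency tibble.
#' @return A ggplot object.
#' @export
plot_latency_series <- function(trials) {
  dp <- detect_disengagement_periods(trials)
  p <- ggplot2::ggplot(dp$latencies,
                       ggplot2::aes(x = .data$response_time_s,
                                    y = .data$latency_s)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = mean(dp$latencies$latency_s),
                        linetype = 2, color = "red") +
    ggplot2::geom_hline(yintercept = dp$threshold_s, linetype = 3,
                        color = "blue") +
    ggplot2::labs(x = "time (s)", y = "latency between responses (s)") +
    ggplot2::theme_minimal()
  if (nrow(dp$periods))
    p <- p + ggplot2::geom_rect(
      data = dp$periods,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "blue")
  p
}

#' Plot a state correlation matrix
#'
#' Heatmap of the pairwise correlation matrix, optionally ordered by a
#' cluster assignment so block structure is visible.
#'
#' @param mat Correlation matrix with zero diagonal.
#' @param clusters Optional `state_clusters` (or assignment tibble) used to
#'   order the cells.
#' @return A ggplot object.
#' @export
plot_correlation_matrix <- function(mat, clusters = NULL) {
  ids <- rownames(mat) %||% cell_ids(nrow(mat))
  ord <- seq_len(nrow(mat))
  if (!is.null(clusters)) {
    asg <- if (inherits(clusters, "state_clusters")) clusters$assignments
           else clusters
    ord <- order(asg$cluster[match(ids, asg$cell_id)])
  }
  m <- mat[ord, ord]
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$r <- as.numeric(m)[(df$j - 1) * nrow(m) + df$i]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}
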