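#' Tidy an engagement HMM
#'
#' One row per transition-matrix entry plus one per state-mean coordinate.
#'
#' @param x An `engagement_hmm`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`.
#' @method tidy engagement_hmm
#' @export
tidy.engagement_hmm <- function(x, ...) {
  k <- x$n_states
  trans <- tibble::tibble(
    term = sprintf("transition_%d_%d", rep(seq_len(k), each = k),
                   rep(seq_len(k), k)),
    estimate = as.numeric(t(x$transmat)))
  means <- tibble::tibble(
    term = sprintf("mean_state%d_pc%d", rep(seq_len(k), each = x$n_features),
                   rep(seq_len(x$n_features), k)),
    estimate = as.numeric(t(x$means)))
  dplyr::bind_rows(trans, means)
}

#' @rdname tidy.engagement_hmm
#' @method glance engagement_hmm
#' @export
glance.engagement_hmm <- function(x, ...) {
  tibble::tibble(n_states = x$n_states, n_frames = x$n_frames,
                 n_features = x$n_features, loglik = x$loglik,
                 loglik_per_frame = x$loglik_per_frame,
                 n_iter = x$n_iter, converged = x$converged)
}

#' Tidy an exponential decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "k"),
                 estimate = c(x$A, x$k),
                 std.error = c(x$se_A, x$se_k),
                 conf.low = c(x$ci_A[1], x$ci_k[1]),
                 conf.high = c(x$ci_A[2], x$ci_k[2]))
}

#' @rdname tidy.decay_fit
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, category = x$category,
                 converged = x$converged, n_boot_ok = x$n_boot_ok)
}

#' Tidy an engagement-stats object
#'
#' @param x An `engagement_stats`.
#' @param ... Unused.
#' @return The posterior table with the engaged state flagged.
#' @method tidy engagement_stats
#' @export
tidy.engagement_stats <- function(x, ...) {
  dplyr::mutate(x$posteriors, engaged = .data$state == x$engaged_state)
}
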