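#' Event-conditioned state posteriors and engagement labeling
#'
#' For each event type — Hit, Mistake (false alarm), and their union Any —
#' converts event timestamps to frame indices (floor(time * rate),
#' binarized, so repeated events in one frame count once) and computes
#' P(state i | event type) as the fraction of event frames decoded in state
#' i. The engaged state is the one with the highest P(state | Any).
#' Optionally also reports the state composition of detected
#' disengagement-period frames.
#'
#' @param states A [decode_states()] result (or tibble with `frame`,
#'   `state`).
#' @param trials Trial table with `response_s` and `outcome`.
#' @param disengagement Optional [detect_disengagement_periods()] result;
#'   adds a `Disengagement period` row set over all frames inside periods.
#' @return Object of class `engagement_stats`: `posteriors` tibble
#'   (event_type, state, p, n_frames), `engaged_state`,
#'   `p_responses_engaged`, `p_disengaged_periods` (NA if no periods given).
#' @export
event_state_posteriors <- function(states, trials, disengagement = NULL) {
  rate <- attr(states, "frame_rate_hz") %||% 10
  n_frames <- nrow(states)
  to_frames <- function(times_s) {
    f <- floor(times_s * rate) + 1L
    dropped <- sum(f > n_frames | f < 1L)
    if (dropped) warnf("%d event(s) outside the decoded span dropped.", dropped)
    unique(f[f >= 1L & f <= n_frames])
  }
  hit_t <- trials$response_s[trials$outcome == "hit" & !is.na(trials$response_s)]
  fa_t <- trials$response_s[trials$outcome == "FA" & !is.na(trials$response_s)]
  sets <- list(Hit = to_frames(hit_t), Mistake = to_frames(fa_t),
               Any = to_frames(c(hit_t, fa_t)))
  ks <- sort(unique(states$state))
  post_one <- function(frames, type) {
    if (!length(frames)) {
      warnf("no %s events; posterior undefined.", type)
      return(tibble::tibble(event_type = type, state = ks, p = NA_real_,
                            n_frames = 0L))
    }
    st <- states$state[frames]
    tibble::tibble(event_type = type, state = ks,
                   p = vapply(ks, function(k) mean(st == k), 0),
                   n_frames = length(frames))
  }
  posteriors <- purrr::imap_dfr(sets, post_one)
  p_any <- posteriors[posteriors$event_type == "Any", ]
  engaged_state <- if (all(is.na(p_any$p))) NA_integer_
                   else p_any$state[which.max(p_any$p)]
  p_dis <- NA_real_
  if (!is.null(disengagement) && nrow(disengagement$periods)) {
    per <- disengagement$periods
    in_per <- rep(FALSE, n_frames)
    for (i in seq_len(nrow(per))) {
      f0 <- max(1L, floor(per$start_s[i] * rate) + 1L)
      f1 <- min(n_frames, floor(per$end_s[i] * rate) + 1L)
      if (f0 <= f1) in_per[f0:f1] <- TRUE
    }
    frames <- which(in_per)
    posteriors <- dplyr::bind_rows(posteriors,
                                   post_one(frames, "Disengagement period"))
    dis_state <- setdiff(ks, engaged_state)
    if (length(dis_state) && length(frames))
      p_dis <- mean(states$state[frames] %in% dis_state)
  }
  structure(list(
    posteriors = posteriors,
    engaged_state = engaged_state,
    p_responses_engaged = if (is.na(engaged_state)) NA_real_
      else p_any$p[p_any$state == engaged_state],
    p_disengaged_periods = p_dis
  ), class = "engagement_stats")
}

#' @export
print.engagement_stats <- function(x, ...) {
  cat(sprintf("engaged state: %d | P(responses | engaged) = %.3f",
              x$engaged_state, x$p_responses_engaged))
  if (!is.na(x$p_disengaged_periods))
    cat(sprintf(" | P(disengagement periods | disengaged) = %.3f",
                x$p_disengaged_periods))
  cat("\n")
  print(x$posteriors)
  invisible(x)
}

#' Correlate engagement probability with behavioral metrics
#'
#' Pearson correlation (with two-sided p) between the per-animal probability
#' of responses occurring in the engaged state and each supplied behavioral
#' metric — typically mean inter-response latency, its coefficient of
#' variation, the criterion c, and the raw response/hit/FA counts as null
#' comparisons.
#'
#' @param per_animal Tibble with a `p_responses_engaged` column plus one
#'   numeric column per behavioral metric.
#' @return Tibble: `metric`, `r`, `p`, `n`. Constant columns give NA with a
#'   warning.
#' @export
correlate_engagement_with_behavior <- function(per_animal) {
  if (nrow(per_animal) < 3) stopf("need at least 3 animals.")
  if (!"p_responses_engaged" %in% names(per_animal))
    stopf("`per_animal` must contain p_responses_engaged.")
  metrics <- setdiff(names(per_animal)[vapply(per_animal, is.numeric, TRUE)],
                     c("p_responses_engaged", "animal"))
  purrr::map_dfr(metrics, function(mname) {
    x <- per_animal$p_responses_engaged; y <- per_animal[[mname]]
    ok <- complete.cases(x, y)
    if (sd(y[ok]) == 0 || sd(x[ok]) == 0) {
      warnf("metric `%s` (or engagement) is constant; r undefined.", mname)
      return(tibble::tibble(metric = mname, r = NA_real_, p = NA_real_,
                            n = sum(ok)))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(metric = mname, r = unname(ct$estimate), p = ct$p.value,
                   n = sum(ok))
  })
}
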