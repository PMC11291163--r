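#' Score a CPT session with signal-detection measures
#'
#' Computes outcome counts, hit and false-alarm rates, the discrimination
#' index d' = z(HR) - z(FAR), the response criterion c = -(z(HR) + z(FAR))/2,
#' and mean response latencies. `z` is the standard-normal quantile function.
#' Correction trials (the forced S- re-presentations following a false
#' alarm) are excluded from the counts by default, so each rate reflects
#' free-choice trials only. Extreme rates (0 or 1) are replaced with the
#' log-linear correction `(x + 0.5) / (n + 1)` so the quantiles stay finite.
#'
#' @param trials Trial table: columns `stimulus` (`"S+"`/`"S-"`), `onset_s`,
#'   `response_s` (NA for no touch), `outcome` (`hit`/`miss`/`FA`/`CR`),
#'   `correction` (logical).
#' @param exclude_correction Drop correction trials before counting.
#' @return One-row tibble of class `session_score`: counts, `HR`, `FAR`,
#'   `d_prime`, `c`, `mean_latency_hit_s`, `mean_latency_FA_s`.
#' @examples
#' s <- generate_session(synthetic_config(n_neurons = 5, session_length_s = 300))
#' score_session(s$trials)
#' @export
score_session <- function(trials, exclude_correction = TRUE) {
  validate_trials(trials)
  tr <- if (exclude_correction) trials[!trials$correction, ] else trials
  hits <- sum(tr$outcome == "hit"); misses <- sum(tr$outcome == "miss")
  fas <- sum(tr$outcome == "FA"); crs <- sum(tr$outcome == "CR")
  if (hits + misses == 0) stopf("no S+ trials: hit rate undefined.")
  if (fas + crs == 0) stopf("no S- trials: false-alarm rate undefined.")
  hr <- corrected_rate(hits, hits + misses)
  far <- corrected_rate(fas, fas + crs)
  lat <- function(o) {
    x <- tr$response_s[tr$outcome == o] - tr$onset_s[tr$outcome == o]
    if (length(x)) mean(x) else NA_real_
  }
  tibble::new_tibble(tibble::tibble(
    hits = hits, misses = misses, FAs = fas, CRs = crs,
    HR = hr, FAR = far,
    d_prime = qnorm(hr) - qnorm(far),
    c = -(qnorm(hr) + qnorm(far)) / 2,
    mean_latency_hit_s = lat("hit"),
    mean_latency_FA_s = lat("FA")
  ), class = "session_score")
}

corrected_rate <- function(x, n) {
  if (x == 0 || x == n) (x + 0.5) / (n + 1) else x / n
}

validate_trials <- function(trials) {
  need <- c("stimulus", "onset_s", "response_s", "outcome", "correction")
  if (!all(need %in% names(trials)))
    stopf("trial table must have columns: %s.", paste(need, collapse = ", "))
  if (is.unsorted(trials$onset_s, strictly = TRUE))
    stopf("trial onsets must be strictly increasing.")
  ok <- ifelse(trials$stimulus == "S+", trials$outcome %in% c("hit", "miss"),
               trials$outcome %in% c("FA", "CR"))
  if (!all(ok)) stopf("outcome inconsistent with stimulus in %d trial(s).",
                      sum(!ok))
  resp <- !is.na(trials$response_s)
  if (any(trials$response_s[resp] < trials$onset_s[resp]))
    stopf("responses must not precede stimulus onset.")
  invisible(trials)
}

#' Inter-response latency series
#'
#' Time elapsed between consecutive active responses (hits or false alarms)
#' in session order; misses and correct rejections are ignored.
#'
#' @param trials Trial table (see [score_session()]).
#' @return Tibble with `response_time_s` (time of the later response of each
#'   pair) and `latency_s` (interval). Empty, with a warning, when fewer than
#'   two active responses exist.
#' @export
response_latency_series <- function(trials) {
  validate_trials(trials)
  rt <- sort(trials$response_s[trials$outcome %in% c("hit", "FA") &
                                 !is.na(trials$response_s)])
  if (length(rt) < 2) {
    warnf("fewer than two active responses; empty latency series.")
    return(tibble::tibble(response_time_s = numeric(), latency_s = numeric()))
  }
  tibble::tibble(response_time_s = rt[-1], latency_s = diff(rt))
}

#' Detect disengagement periods from response latencies
#'
#' Flags inter-response gaps exceeding the session threshold
#' mean(latency) + 2 * SD(latency) (sample SD) as non-responsive
#' (disengagement) periods, each spanning from the earlier to the later
#' response bounding the gap.
#'
#' @param trials Trial table, or a latency tibble from
#'   [response_latency_series()].
#' @return List of class `disengagement_periods`: `latencies` (tibble),
#'   `threshold_s`, and `periods` (tibble: start_s, end_s, duration_s).
#' @examples
#' lat <- tibble::tibble(response_time_s = cumsum(c(2, 2, 2, 40)),
#'                       latency_s = c(2, 2, 2, 40))
#' detect_disengagement_periods(lat)
#' @export
detect_disengagement_periods <- function(trials) {
  lat <- if (all(c("response_time_s", "latency_s") %in% names(trials))) {
    trials
  } else {
    response_latency_series(trials)
  }
  if (nrow(lat) < 2) stopf("need at least two inter-response intervals.")
  mu <- mean(lat$latency_s)
  sdev <- sd(lat$latency_s)
  threshold <- mu + 2 * sdev
  if (sdev == 0) {
    warnf("zero-variance latency series; threshold equals the mean, no periods.")
    periods <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                              duration_s = numeric())
  } else {
    hit <- lat$latency_s > threshold
    periods <- tibble::tibble(
      start_s = lat$response_time_s[hit] - lat$latency_s[hit],
      end_s = lat$response_time_s[hit],
      duration_s = lat$latency_s[hit]
    )
  }
  structure(list(latencies = lat, threshold_s = threshold, periods = periods),
            class = "disengagement_periods")
}

#' Check stage-advancement and recording criteria
#'
#' Stage 2 advances after at least 60 hits in two consecutive sessions;
#' stage 3 after d' of at least 0.6 on two consecutive days. A recording
#' session additionally requires at least 55 hits.
#'
#' @param scores Session scores in chronological order: a tibble with `hits`
#'   and (for stage 3) `d_prime` columns, e.g. row-bound [score_session()]
#'   outputs.
#' @param stage `"stage2"` or `"stage3"`.
#' @param hits_threshold,d_prime_threshold,recording_hits Criterion values.
#' @return One-row tibble: `stage`, `met`, `met_at_session` (index of the
#'   second qualifying session, NA if unmet), `n_recording_eligible`
#'   (sessions with at least `recording_hits` hits).
#' @export
check_stage_criteria <- function(scores, stage = c("stage3", "stage2"),
                                 hits_threshold = 60, d_prime_threshold = 0.6,
                                 recording_hits = 55) {
  stage <- match.arg(stage)
  if (!nrow(scores)) stopf("empty score list.")
  ok <- if (stage == "stage2") scores$hits >= hits_threshold
        else scores$d_prime >= d_prime_threshold
  pair <- which(ok[-1] & ok[-length(ok)])
  met_at <- if (length(pair)) pair[1] + 1L else NA_integer_
  tibble::tibble(stage = stage, met = !is.na(met_at), met_at_session = met_at,
                 n_recording_eligible = sum(scores$hits >= recording_hits))
}
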