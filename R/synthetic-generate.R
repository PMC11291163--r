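#' Simulate one CPT session with ground truth
#'
#' Generates a full synthetic session: a two-state engaged/disengaged Markov
#' chain at frame resolution, a stage-conditional trial schedule whose
#' response probability is gated by the latent state at stimulus onset,
#' and a calcium trace matrix built from (i) a state-dependent rate shift in
#' a subset of neurons, (ii) raised-cosine event-locked rate bumps (positive
#' for planted up-modulated neurons, negative for down-modulated ones)
#' centered at the screen touch (the causal calcium kernel then makes
#' activity rise between stimulus presentation and the response), and (iii)
#' a shared
#' Gaussian component whose pairwise correlation follows
#' `base * exp(-spatial_decay_rate * distance)` with assembly-block base
#' levels per state. The latent rate passes through a single-exponential
#' calcium kernel before white observation noise is added.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `cpt_session` with elements `trials` (tibble:
#'   trial_index, stimulus, onset_s, response_s, outcome, correction),
#'   `events` (tibble: time_s, event_type, correction_flag), `traces`
#'   (tibble: time_s plus one column per cell), `centroids` (tibble:
#'   cell_id, x_um, y_um), `truth` (ground-truth list: per-frame
#'   `state_sequence`, `up_neurons`, `down_neurons`, `state_mod_neurons`,
#'   `assembly`, `event_times`), and `config`.
#' @examples
#' s <- generate_session(synthetic_config(n_neurons = 20, session_length_s = 120))
#' dplyr::count(s$trials, outcome)
#' @export
generate_session <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  rate <- config$frame_rate_hz
  n_frames <- as.integer(round(config$session_length_s * rate))
  if (n_frames < 1) stopf("session too short: no frames at %g Hz.", rate)
  n <- config$n_neurons

  set.seed(config$seed)

  state <- simulate_state_chain(n_frames, config$state_mean_dwell_s, rate)
  beh <- simulate_trials(config, state, n_frames)

  centroids <- tibble::tibble(
    cell_id = cell_ids(n),
    x_um = runif(n, 0, config$fov_size_um),
    y_um = runif(n, 0, config$fov_size_um)
  )
  assembly <- assign_assemblies(centroids, config$corr_assemblies)

  n_up <- round(config$frac_up * n)
  n_down <- round(config$frac_down * n)
  mod_idx <- sample.int(n, n_up + n_down)
  up_neurons <- sort(mod_idx[seq_len(n_up)])
  down_neurons <- sort(mod_idx[n_up + seq_len(n_down)])
  state_mod_neurons <- sort(sample.int(n, round(config$state_mod_frac * n)))

  latent <- matrix(0, n_frames, n)

  # state-gated population shift (engaged state more active)
  if (length(state_mod_neurons) && config$state_mod_sd > 0) {
    shift <- config$state_mod_sd * config$noise_sd
    latent[state == 1L, state_mod_neurons] <-
      latent[state == 1L, state_mod_neurons] + shift
  }

  # event-locked raised-cosine bumps around active responses
  resp <- beh$trials[!is.na(beh$trials$response_s), ]
  if (nrow(resp) && (n_up + n_down) > 0 && config$event_effect_size > 0) {
    centers_s <- resp$response_s
    half_w <- 1 # seconds; bump width 2 s
    amp <- config$event_effect_size * config$noise_sd
    bump <- numeric(n_frames)
    for (cs in centers_s) {
      f0 <- floor((cs - half_w) * rate) + 1
      f1 <- ceiling((cs + half_w) * rate)
      fr <- max(1L, f0):min(n_frames, f1)
      tt <- (fr - 1) / rate
      bump[fr] <- bump[fr] + 0.5 * (1 + cos(pi * (tt - cs) / half_w))
    }
    if (n_up) latent[, up_neurons] <- latent[, up_neurons] + amp * bump
    if (n_down) latent[, down_neurons] <- latent[, down_neurons] - amp * bump
  }

  # shared spatially structured component, state-dependent coupling
  if (config$shared_sd > 0) {
    d_mat <- as.matrix(stats::dist(cbind(centroids$x_um, centroids$y_um)))
    for (s in 1:2) {
      idx <- which(state == s)
      if (!length(idx)) next
      sigma <- target_correlation(assembly, d_mat,
                                  config$within_assembly_corr[s],
                                  config$between_assembly_corr[s],
                                  config$spatial_decay_rate)
      ch <- safe_chol(sigma)
      z <- matrix(rnorm(length(idx) * n), length(idx), n) %*% ch
      latent[idx, ] <- latent[idx, ] + config$shared_sd * z
    }
  }

  traces <- calcium_convolve(latent, config$calcium_tau_s, rate)
  if (config$noise_sd > 0)
    traces <- traces + matrix(rnorm(n_frames * n, sd = config$noise_sd),
                              n_frames, n)
  if (any(!is.finite(traces))) stopf("internal: non-finite trace values.")
  colnames(traces) <- centroids$cell_id

  structure(list(
    trials = beh$trials,
    events = beh$events,
    traces = as_trace_tbl(traces, rate),
    centroids = centroids,
    truth = list(
      state_sequence = c("engaged", "disengaged")[state],
      up_neurons = up_neurons,
      down_neurons = down_neurons,
      state_mod_neurons = state_mod_neurons,
      assembly = assembly,
      event_times = beh$events[c("time_s", "event_type")]
    ),
    config = config
  ), class = "cpt_session")
}

# Discrete-time two-state chain; stay probability 1 - 1/(dwell_s * rate),
# started from its stationary distribution. 1 = engaged, 2 = disengaged.
simulate_state_chain <- function(n_frames, dwell_s, rate) {
  p_leave <- pmin(1, 1 / (dwell_s * rate))
  stat1 <- p_leave[2] / (p_leave[1] + p_leave[2])
  state <- integer(n_frames)
  state[1] <- if (runif(1) < stat1) 1L else 2L
  u <- runif(n_frames)
  for (t in 2:n_frames) {
    s <- state[t - 1]
    state[t] <- if (u[t] < p_leave[s]) 3L - s else s
  }
  state
}

simulate_trials <- function(config, state, n_frames) {
  rate <- config$frame_rate_hz
  sd_lh <- config$stimulus_duration_s + config$limited_hold_s
  t_now <- 0
  correction_next <- FALSE
  rows <- list()
  i <- 0L
  repeat {
    iti <- sample(config$iti_choices_s, 1)
    onset <- t_now + iti
    if (onset + sd_lh > config$session_length_s) break
    i <- i + 1L
    is_corr <- correction_next
    splus <- if (is_corr) FALSE else runif(1) < config$p_target
    f_on <- min(n_frames, floor(onset * rate) + 1)
    p_resp <- if (state[f_on] == 1L) config$p_respond_engaged
              else config$p_respond_disengaged
    responded <- runif(1) < p_resp
    if (responded) {
      latency <- runif(1, 0.5, sd_lh)
      response <- onset + latency
      outcome <- if (splus) "hit" else "FA"
      t_now <- response
    } else {
      response <- NA_real_
      outcome <- if (splus) "miss" else "CR"
      t_now <- onset + sd_lh
    }
    correction_next <- identical(outcome, "FA")
    rows[[i]] <- list(trial_index = i,
                      stimulus = if (splus) "S+" else "S-",
                      onset_s = onset, response_s = response,
                      outcome = outcome, correction = is_corr)
  }
  trials <- dplyr::bind_rows(rows)
  if (!nrow(trials)) stopf("session too short for a single trial.")
  attr(trials, "session_length_s") <- config$session_length_s
  attr(trials, "stage") <- config$stage
  list(trials = trials, events = events_from_trials(trials, config))
}

events_from_trials <- function(trials, config) {
  sd_lh <- config$stimulus_duration_s + config$limited_hold_s
  stim <- tibble::tibble(
    time_s = trials$onset_s,
    event_type = ifelse(trials$stimulus == "S+", "stim_on_splus", "stim_on_sminus"),
    correction_flag = trials$correction
  )
  out_time <- ifelse(is.na(trials$response_s),
                     trials$onset_s + sd_lh, trials$response_s)
  out_type <- c(hit = "hit", FA = "false_alarm", miss = "miss",
                CR = "correct_rejection")[trials$outcome]
  outc <- tibble::tibble(time_s = out_time, event_type = unname(out_type),
                         correction_flag = trials$correction)
  rew <- tibble::tibble(time_s = trials$response_s[trials$outcome == "hit"] + 1,
                        event_type = "reward_collect", correction_flag = FALSE)
  dplyr::arrange(dplyr::bind_rows(stim, outc, rew), .data$time_s)
}

# spatially contiguous assemblies via k-means on the centroid positions
assign_assemblies <- function(centroids, k) {
  if (k <= 1 || nrow(centroids) <= k) return(rep(1L, nrow(centroids)))
  km <- kmeans(cbind(centroids$x_um, centroids$y_um), centers = k, nstart = 5)
  as.integer(km$cluster)
}

# Target correlation: assembly-block base level shaped by exponential spatial
# decay; jitter added to the diagonal until Cholesky succeeds.
target_correlation <- function(assembly, d_mat, within, between, decay_rate) {
  base <- matrix(between, length(assembly), length(assembly))
  same <- outer(assembly, assembly, "==")
  base[same] <- within
  sigma <- base * exp(-decay_rate * d_mat)
  diag(sigma) <- 1
  sigma
}

safe_chol <- function(sigma) {
  eps <- 1e-8
  for (i in 1:12) {
    ch <- tryCatch(chol(sigma + diag(eps, nrow(sigma))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
    eps <- eps * 10
  }
  stopf("target correlation matrix is too far from positive definite.")
}

# single-exponential indicator kernel == first-order recursive filter
calcium_convolve <- function(latent, tau_s, rate) {
  a <- exp(-1 / (tau_s * rate))
  out <- apply(latent, 2, function(x)
    as.numeric(stats::filter(x, a, method = "recursive")))
  # rescale so a unit-variance white input keeps unit marginal variance
  out * sqrt(1 - a^2)
}

#' Simulate event-independent autocorrelated traces
#'
#' Stationary first-order autoregressive noise with unit marginal variance
#' and no event-locked structure, used to calibrate the false-positive rate
#' of the peri-event classifier. Centroids are uniform in the field of view.
#'
#' @param n_neurons,n_frames Matrix dimensions.
#' @param seed RNG seed.
#' @param ar_coef Lag-1 autoregressive coefficient in [0, 1).
#' @param frame_rate_hz Frame rate for the `time_s` column.
#' @param fov_size_um Field-of-view edge length for the centroids.
#' @return List with `traces` (tibble) and `centroids` (tibble).
#' @export
generate_null_traces <- function(n_neurons, n_frames, seed = 1,
                                 ar_coef = 0.8, frame_rate_hz = 10,
                                 fov_size_um = 450) {
  assert_pos(n_neurons, "n_neurons"); assert_pos(n_frames, "n_frames")
  if (ar_coef < 0 || ar_coef >= 1) stopf("ar_coef must be in [0, 1).")
  set.seed(as.integer(seed))
  innov_sd <- sqrt(1 - ar_coef^2)
  m <- matrix(rnorm(n_frames * n_neurons, sd = innov_sd), n_frames, n_neurons)
  if (ar_coef > 0)
    m <- apply(m, 2, function(x)
      as.numeric(stats::filter(x, ar_coef, method = "recursive")))
  m <- matrix(m, n_frames, n_neurons)
  colnames(m) <- cell_ids(n_neurons)
  list(
    traces = as_trace_tbl(m, frame_rate_hz),
    centroids = tibble::tibble(cell_id = cell_ids(n_neurons),
                               x_um = runif(n_neurons, 0, fov_size_um),
                               y_um = runif(n_neurons, 0, fov_size_um))
  )
}

#' Simulate a cohort of animals
#'
#' Per-animal seeds derive deterministically from `base_seed`; response
#' probabilities may be jittered across animals to create inter-animal
#' variability in engagement behavior.
#'
#' @param config Shared [synthetic_config()].
#' @param n_animals Number of animals (one session each).
#' @param base_seed Master seed for the cohort.
#' @param respond_jitter Half-width of the uniform jitter applied to the two
#'   response probabilities per animal (clipped to [0, 1]); 0 disables it.
#' @return List of `cpt_session` objects, each with an `animal` element.
#' @export
generate_cohort <- function(config = synthetic_config(), n_animals,
                            base_seed = config$seed, respond_jitter = 0) {
  if (n_animals < 1) stopf("n_animals must be >= 1.")
  set.seed(as.integer(base_seed))
  jit <- function(p, j) min(1, max(0, p + runif(1, -j, j)))
  lapply(seq_len(n_animals), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(base_seed, i)
    if (respond_jitter > 0) {
      cfg$p_respond_engaged <- jit(cfg$p_respond_engaged, respond_jitter)
      cfg$p_respond_disengaged <- jit(cfg$p_respond_disengaged, respond_jitter)
    }
    s <- generate_session(cfg)
    s$animal <- i
    s
  })
}
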