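#' Configuration for the synthetic session generator
#'
#' Bundles every knob of the synthetic continuous-performance-test (CPT)
#' session generator: task schedule (stimulus duration, limited hold,
#' inter-trial intervals, target probability), the two-state
#' engaged/disengaged Markov chain that gates responding, event-locked
#' neuronal modulation, state-dependent spatially decaying pairwise
#' correlations, and the calcium observation model.
#'
#' Defaults emulate the study conditions: 45-min sessions at 10 Hz,
#' 150 neurons, stage-3 schedule (2 s stimulus, 2.5 s limited hold, 2 or 3 s
#' ITI, 50% targets), 60 s mean dwell per engagement state, per-trial response
#' probability 0.9 when engaged versus 0.05 when disengaged, and a 1-SD
#' state-dependent rate shift on half of the population.
#'
#' @param n_neurons Number of cells to simulate.
#' @param session_length_s Session duration in seconds.
#' @param frame_rate_hz Acquisition rate (frames per second).
#' @param stage Task stage: `"stage3"` mixes targets (S+) and non-targets
#'   (S-) and schedules correction trials after false alarms; `"stage2"`
#'   presents only S+.
#' @param stimulus_duration_s,limited_hold_s Stimulus display time and the
#'   post-stimulus window in which a touch still counts, seconds.
#' @param iti_choices_s Candidate inter-trial intervals, sampled uniformly.
#' @param p_target Probability that a (non-correction) trial shows S+.
#'   Defaults to 0.5 for stage 3 and 1 for stage 2.
#' @param state_mean_dwell_s Length-2 vector, mean dwell time in seconds of
#'   the engaged and disengaged latent states.
#' @param p_respond_engaged,p_respond_disengaged Per-trial probability of an
#'   active screen touch conditional on the latent state at stimulus onset.
#' @param frac_up,frac_down Fractions of neurons with event-locked positive /
#'   negative rate modulation around active responses.
#' @param event_effect_size Peak event-locked rate change, in units of the
#'   baseline noise SD.
#' @param state_mod_frac,state_mod_sd Fraction of neurons whose latent rate
#'   mean shifts with the engagement state, and the shift size in baseline-SD
#'   units (positive shift in the engaged state).
#' @param corr_assemblies Number of spatially contiguous cell assemblies used
#'   to build block structure in the pairwise correlations.
#' @param within_assembly_corr,between_assembly_corr Length-2 vectors
#'   (engaged, disengaged): target zero-distance pairwise correlation of the
#'   shared latent signal for same-assembly / different-assembly pairs.
#' @param spatial_decay_rate Exponential decay constant of pairwise
#'   correlation with inter-cell distance, in 1/micrometer. The planted
#'   correlation between cells i and j is
#'   `base_ij * exp(-spatial_decay_rate * d_ij)`.
#' @param fov_size_um Field-of-view edge length; centroids are uniform on the
#'   square.
#' @param calcium_tau_s Exponential calcium-indicator decay constant in
#'   seconds (GCaMP6f-like at 10 Hz).
#' @param noise_sd SD of the additive white observation noise.
#' @param shared_sd SD of the shared (correlated) latent component before the
#'   calcium kernel.
#' @param seed RNG seed; identical seed and config give bit-identical output.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_neurons = 150,
                             session_length_s = 2700,
                             frame_rate_hz = 10,
                             stage = c("stage3", "stage2"),
                             stimulus_duration_s = 2,
                             limited_hold_s = 2.5,
                             iti_choices_s = c(2, 3),
                             p_target = NULL,
                             state_mean_dwell_s = c(engaged = 60, disengaged = 60),
                             p_respond_engaged = 0.9,
                             p_respond_disengaged = 0.05,
                             frac_up = 0.15,
                             frac_down = 0.10,
                             event_effect_size = 2,
                             state_mod_frac = 0.5,
                             state_mod_sd = 1,
                             corr_assemblies = 2,
                             within_assembly_corr = c(engaged = 0.25, disengaged = 0.35),
                             between_assembly_corr = c(engaged = 0.05, disengaged = 0.10),
                             spatial_decay_rate = 0.004,
                             fov_size_um = 450,
                             calcium_tau_s = 0.7,
                             noise_sd = 1,
                             shared_sd = 1,
                             seed = 1) {
  stage <- match.arg(stage)
  if (is.null(p_target)) p_target <- if (stage == "stage3") 0.5 else 1
  cfg <- list(
    n_neurons = as.integer(n_neurons),
    session_length_s = session_length_s,
    frame_rate_hz = frame_rate_hz,
    stage = stage,
    stimulus_duration_s = stimulus_duration_s,
    limited_hold_s = limited_hold_s,
    iti_choices_s = iti_choices_s,
    p_target = p_target,
    state_mean_dwell_s = rep_len(unname(state_mean_dwell_s), 2),
    p_respond_engaged = p_respond_engaged,
    p_respond_disengaged = p_respond_disengaged,
    frac_up = frac_up,
    frac_down = frac_down,
    event_effect_size = event_effect_size,
    state_mod_frac = state_mod_frac,
    state_mod_sd = state_mod_sd,
    corr_assemblies = as.integer(corr_assemblies),
    within_assembly_corr = rep_len(unname(within_assembly_corr), 2),
    between_assembly_corr = rep_len(unname(between_assembly_corr), 2),
    spatial_decay_rate = spatial_decay_rate,
    fov_size_um = fov_size_um,
    calcium_tau_s = calcium_tau_s,
    noise_sd = noise_sd,
    shared_sd = shared_sd,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  assert_pos(cfg$n_neurons, "n_neurons")
  assert_pos(cfg$session_length_s, "session_length_s")
  assert_pos(cfg$frame_rate_hz, "frame_rate_hz")
  assert_pos(cfg$state_mean_dwell_s, "state_mean_dwell_s")
  assert_pos(cfg$calcium_tau_s, "calcium_tau_s")
  assert_pos(cfg$fov_size_um, "fov_size_um")
  assert_prob(c(cfg$p_target, cfg$p_respond_engaged, cfg$p_respond_disengaged,
                cfg$frac_up, cfg$frac_down, cfg$state_mod_frac),
              "probability fields")
  if (cfg$frac_up + cfg$frac_down > 1)
    stopf("frac_up + frac_down must not exceed 1.")
  if (cfg$noise_sd < 0 || cfg$shared_sd < 0)
    stopf("noise_sd and shared_sd must be non-negative.")
  if (cfg$corr_assemblies < 1) stopf("corr_assemblies must be >= 1.")
  if (any(abs(cfg$within_assembly_corr) > 1) ||
      any(abs(cfg$between_assembly_corr) > 1))
    stopf("assembly correlation targets must lie in [-1, 1].")
  invisible(cfg)
}
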