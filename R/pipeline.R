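#' Run configuration for the end-to-end pipeline
#'
#' A single nested configuration driving [run_pipeline()]: either a
#' synthetic-session config or paths to trace/centroid/trial files, stage
#' toggles, and per-module parameter blocks. The structure round-trips
#' through JSON via [write_run_config()] / [read_run_config()].
#'
#' @param synthetic A [synthetic_config()], or NULL when real inputs are
#'   given.
#' @param inputs NULL, or a list with `traces`, `centroids`, `trials` file
#'   paths.
#' @param stages Named logical list toggling `perievent`, `engagement`,
#'   `network`.
#' @param perievent A [peri_event_windows()].
#' @param hmm An [hmm_config()].
#' @param network List with `n_perm`, `n_boot`, `k_grid`.
#' @param seed Global seed; every stochastic stage derives its seed from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(), inputs = NULL,
                       stages = list(perievent = TRUE, engagement = TRUE,
                                     network = TRUE),
                       perievent = peri_event_windows(),
                       hmm = hmm_config(),
                       network = list(n_perm = 10000, n_boot = 1000,
                                      k_grid = 2:6),
                       seed = 1) {
  if (is.null(synthetic) == is.null(inputs))
    stopf("provide exactly one of `synthetic` or `inputs`.")
  structure(list(synthetic = synthetic, inputs = inputs, stages = stages,
                 perievent = perievent, hmm = hmm, network = network,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- if (!is.null(raw$synthetic)) do.call(synthetic_config, raw$synthetic)
  pe <- do.call(peri_event_windows, raw$perievent)
  hm <- do.call(hmm_config, raw$hmm)
  run_config(synthetic = syn, inputs = raw$inputs,
             stages = raw$stages, perievent = pe, hmm = hm,
             network = raw$network, seed = raw$seed)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Validate delimited input files
#'
#' Checks header and shape consistency (trace cell columns match centroid
#' rows), monotone trial onsets, and parseability; reports one row per
#' check.
#'
#' @param trace_path,centroid_path,trial_path File paths.
#' @return Tibble: `file`, `check`, `pass`, `detail`.
#' @export
validate_inputs <- function(trace_path, centroid_path, trial_path) {
  checks <- list()
  add <- function(file, check, pass, detail = "") {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      file = file, check = check, pass = pass, detail = detail)
  }
  tr <- tryCatch(read_traces(trace_path), error = function(e) e)
  add(trace_path, "parse", !inherits(tr, "error"),
      if (inherits(tr, "error")) conditionMessage(tr) else "")
  ce <- tryCatch(read_centroids(centroid_path), error = function(e) e)
  add(centroid_path, "parse", !inherits(ce, "error"),
      if (inherits(ce, "error")) conditionMessage(ce) else "")
  if (!inherits(tr, "error") && !inherits(ce, "error")) {
    cells <- setdiff(names(tr), "time_s")
    add(trace_path, "cells_match_centroids",
        length(cells) == nrow(ce) && all(cells %in% ce$cell_id),
        sprintf("%d trace cells vs %d centroids", length(cells), nrow(ce)))
  }
  tl <- tryCatch(read_trials(trial_path), error = function(e) e)
  add(trial_path, "parse", !inherits(tl, "error"),
      if (inherits(tl, "error")) conditionMessage(tl) else "")
  if (!inherits(tl, "error")) {
    bad <- which(diff(tl$onset_s) <= 0)
    add(trial_path, "monotone_onsets", !length(bad),
        if (length(bad)) sprintf("first offending row: %d", bad[1] + 1) else "")
  }
  dplyr::bind_rows(checks)
}

#' Run the full pipeline on one session
#'
#' Simulates (or loads) a session, scores behavior, classifies peri-event
#' modulation for hits and false alarms under both alignments, infers
#' engagement states (preprocessing, state-count comparison, forward
#' cross-validation, decoding, event posteriors), and characterizes the
#' state-conditioned correlation networks. Outputs, parameters, seeds, and
#' file hashes are recorded in a manifest.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory; created if missing. NULL skips writing.
#' @return List of class `pipeline_result` with elements `session`, `score`,
#'   `perievent` (named list), `engagement`, `network`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stages <- config$stages
  if (!is.null(config$synthetic)) {
    session <- generate_session(config$synthetic)
  } else {
    session <- list(
      traces = read_traces(config$inputs$traces),
      centroids = read_centroids(config$inputs$centroids),
      trials = read_trials(config$inputs$trials)
    )
  }
  rate <- if (!is.null(config$synthetic)) config$synthetic$frame_rate_hz
          else config$hmm$frame_rate_hz

  score <- score_session(session$trials)
  latencies <- response_latency_series(session$trials)
  disengagement <- if (nrow(latencies) >= 2)
    detect_disengagement_periods(latencies) else NULL

  perievent <- NULL
  if (isTRUE(stages$perievent)) {
    w <- config$perievent
    w$seed <- derive_seed(config$seed, 11)
    combos <- expand.grid(event_type = c("hit", "fa"),
                          alignment = c("touch", "stimulus"),
                          stringsAsFactors = FALSE)
    perievent <- purrr::pmap(combos, function(event_type, alignment) {
      times <- peri_event_times(session$trials, event_type, alignment)
      if (length(times) < 2) return(NULL)
      peri_event_analysis(session$traces, times, w, rate)
    })
    names(perievent) <- paste(combos$event_type, combos$alignment, sep = "_")
  }

  engagement <- NULL
  if (isTRUE(stages$engagement)) {
    hcfg <- config$hmm
    hcfg$seed <- derive_seed(config$seed, 23)
    pcs <- preprocess_for_hmm(session$traces, hcfg)
    model <- fit_hmm(pcs, hcfg$n_states, hcfg)
    states <- decode_states(model, pcs)
    engagement <- list(
      model = model,
      states = states,
      state_count = select_state_count(pcs, 1:3, hcfg),
      cv = crossvalidate_hmm(pcs, hcfg),
      stats = event_state_posteriors(states, session$trials, disengagement),
      cumvar_retained = attr(pcs, "cumvar_retained")
    )
  }

  network <- NULL
  if (isTRUE(stages$network)) {
    if (is.null(engagement))
      stopf("the network stage requires the engagement stage.")
    st <- engagement$states
    eng_state <- engagement$stats$engaged_state
    masks <- list(engaged = st$state == eng_state,
                  disengaged = st$state != eng_state)
    n_frames_tr <- nrow(st)
    traces_trunc <- session$traces[seq_len(n_frames_tr), ]
    nets <- purrr::imap(masks, function(mask, nm)
      correlation_network(traces_trunc, mask, session$centroids,
                          n_perm = config$network$n_perm,
                          seed = derive_seed(config$seed, 31)))
    decays <- purrr::imap(nets, function(net, nm) {
      pos <- net$pairs[net$pairs$class == "positive", ]
      if (nrow(pos) >= 10)
        fit_correlation_decay(pos$r, pos$distance_um, "positive",
                              n_boot = config$network$n_boot,
                              seed = derive_seed(config$seed, 41))
    })
    clus <- cluster_states(nets$disengaged$matrix,
                           k_grid = config$network$k_grid,
                           seed = derive_seed(config$seed, 43))
    network <- list(
      networks = nets,
      decay = decays,
      decay_comparison = if (!is.null(decays$engaged) &&
                             !is.null(decays$disengaged))
        compare_decay_rates(decays$engaged, decays$disengaged),
      clusters = clus,
      cluster_metrics = cluster_metrics(clus, session$centroids),
      coupling = compare_cluster_coupling(
        nets$engaged$pairs, nets$disengaged$pairs, clus,
        pair_distances(session$centroids))
    )
  }

  result <- structure(list(session = session, score = score,
                           disengagement = disengagement,
                           perievent = perievent, engagement = engagement,
                           network = network, manifest = NULL),
                      class = "pipeline_result")
  if (!is.null(out_dir)) result$manifest <- write_pipeline_outputs(
    result, config, out_dir)
  result
}

write_pipeline_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p)
    files[[name]] <<- p
  }
  put_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, null = "null")
    files[[name]] <<- p
  }
  put_csv(result$score, "session_score.csv")
  if (!is.null(result$perievent)) {
    for (nm in names(result$perievent)) {
      pe <- result$perievent[[nm]]
      if (is.null(pe)) next
      put_csv(pe[c("cell_id", "delta", "boot_p", "label")],
              sprintf("perievent_%s.csv", nm))
    }
  }
  if (!is.null(result$engagement)) {
    put_csv(result$engagement$states, "state_sequence.csv")
    put_csv(result$engagement$cv, "hmm_crossvalidation.csv")
    put_csv(result$engagement$state_count, "hmm_state_count.csv")
    put_json(list(
      engaged_state = result$engagement$stats$engaged_state,
      p_responses_engaged = result$engagement$stats$p_responses_engaged,
      p_disengaged_periods = result$engagement$stats$p_disengaged_periods,
      transmat = result$engagement$model$transmat,
      loglik = result$engagement$model$loglik
    ), "engagement.json")
    put_csv(result$engagement$stats$posteriors, "state_posteriors.csv")
  }
  if (!is.null(result$network)) {
    for (nm in names(result$network$networks))
      put_csv(result$network$networks[[nm]]$pairs,
              sprintf("network_pairs_%s.csv", nm))
    put_csv(result$network$cluster_metrics, "cluster_metrics.csv")
    put_csv(result$network$coupling$tests, "coupling_tests.csv")
  }
  cfg_path <- file.path(out_dir, "run_config.json")
  write_run_config(config, cfg_path)
  files[["run_config.json"]] <- cfg_path
  manifest <- list(
    package_version = as.character(utils::packageVersion("cptstates")),
    seed = config$seed,
    stages = config$stages,
    files = lapply(files, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  put_json(manifest, "manifest.json")
  manifest
}
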