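#' Configuration for engagement-state HMM inference
#'
#' Preprocessing and model settings for population-state inference.
#' Defaults follow the standard recipe: truncate to the first 45 minutes,
#' z-score each neuron, smooth with a 1-second (10-frame, center-aligned)
#' moving average, retain the first 45 principal components as a variance
#' QC, fit a two-state Gaussian HMM with diagonal covariance on the first
#' 10 PCs, EM for up to 200 iterations.
#'
#' @param truncate_s Analysis span from session start, seconds.
#' @param frame_rate_hz Acquisition rate.
#' @param smooth_window_frames Moving-average window (frames, centered).
#' @param n_pcs_retained PCs kept for the cumulative-variance QC.
#' @param n_pcs_hmm PCs the HMM is fitted on.
#' @param n_states Number of hidden states.
#' @param max_iter Maximum EM iterations.
#' @param tol EM convergence tolerance on the total log-likelihood.
#' @param n_restarts Seeded EM restarts; the best train log-likelihood wins.
#' @param seed RNG seed for initialization.
#' @return List of class `hmm_config`.
#' @export
hmm_config <- function(truncate_s = 2700, frame_rate_hz = 10,
                       smooth_window_frames = 10, n_pcs_retained = 45,
                       n_pcs_hmm = 10, n_states = 2, max_iter = 200,
                       tol = 1e-2, n_restarts = 3, seed = 1) {
  cfg <- list(truncate_s = truncate_s, frame_rate_hz = frame_rate_hz,
              smooth_window_frames = as.integer(smooth_window_frames),
              n_pcs_retained = as.integer(n_pcs_retained),
              n_pcs_hmm = as.integer(n_pcs_hmm),
              n_states = as.integer(n_states),
              max_iter = as.integer(max_iter), tol = tol,
              n_restarts = as.integer(n_restarts), seed = as.integer(seed))
  if (cfg$n_pcs_hmm > cfg$n_pcs_retained)
    stopf("n_pcs_hmm must not exceed n_pcs_retained.")
  if (cfg$n_states < 1) stopf("n_states must be >= 1.")
  assert_pos(c(cfg$truncate_s, cfg$frame_rate_hz, cfg$max_iter), "hmm_config")
  structure(cfg, class = "hmm_config")
}

#' Preprocess traces for HMM fitting
#'
#' Truncates to the first `truncate_s` seconds, z-scores each neuron,
#' applies the centered moving average, and projects onto principal
#' components fitted on the smoothed matrix. Returns the first `n_pcs_hmm`
#' component scores; the cumulative variance explained by the first
#' `n_pcs_retained` components is recorded as a quality check.
#'
#' @param traces Trace tibble or frames x neurons matrix.
#' @param config An [hmm_config()].
#' @return Matrix frames x PCs with attributes `cumvar_retained` (cumulative
#'   variance fraction of the retained PCs) and `explained_variance`
#'   (per-PC fractions).
#' @export
preprocess_for_hmm <- function(traces, config = hmm_config()) {
  m <- trace_matrix(traces)
  n_keep <- as.integer(round(config$truncate_s * config$frame_rate_hz))
  if (nrow(m) < n_keep) {
    warnf("session shorter than truncate_s; using all %d frames.", nrow(m))
    n_keep <- nrow(m)
  }
  m <- m[seq_len(n_keep), , drop = FALSE]
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) stopf("zero-variance neuron(s) in the truncated span.")
  z <- scale(m)
  sm <- apply(z, 2, centered_moving_average, window = config$smooth_window_frames)
  p <- prcomp(sm, center = TRUE, scale. = FALSE)
  n_hmm <- min(config$n_pcs_hmm, ncol(p$x))
  if (n_hmm < config$n_pcs_hmm)
    warnf("only %d PCs available; reducing n_pcs_hmm.", n_hmm)
  ve <- p$sdev^2 / sum(p$sdev^2)
  out <- p$x[, seq_len(n_hmm), drop = FALSE]
  attr(out, "explained_variance") <- ve
  attr(out, "cumvar_retained") <-
    sum(ve[seq_len(min(config$n_pcs_retained, length(ve)))])
  attr(out, "frame_rate_hz") <- config$frame_rate_hz
  out
}

gaussian_logdens <- function(x, means, vars) {
  T_ <- nrow(x); K <- nrow(means)
  ld <- matrix(0, T_, K)
  for (k in seq_len(K)) {
    ld[, k] <- -0.5 * colSums((t(x) - means[k, ])^2 / vars[k, ]) -
      0.5 * sum(log(2 * pi * vars[k, ]))
  }
  ld
}

hmm_init <- function(x, k, seed) {
  set.seed(seed)
  if (k == 1) {
    means <- matrix(colMeans(x), 1)
  } else {
    km <- kmeans(x, centers = k, nstart = 3, iter.max = 50)
    means <- km$centers
  }
  vars <- matrix(rep(pmax(apply(x, 2, var), 1e-6), each = k), k)
  trans <- matrix(0.05 / max(1, k - 1), k, k)
  diag(trans) <- if (k > 1) 0.95 else 1
  list(means = means, vars = vars, transmat = trans,
       initprob = rep(1 / k, k))
}

hmm_em_once <- function(x, k, max_iter, tol, seed) {
  par <- hmm_init(x, k, seed)
  ll_old <- -Inf; ll_trace <- numeric(0); converged <- FALSE
  for (it in seq_len(max_iter)) {
    ld <- gaussian_logdens(x, par$means, par$vars)
    e <- hmm_forward_backward(ld, par$transmat, par$initprob)
    ll_trace <- c(ll_trace, e$loglik)
    if (is.finite(ll_old) && abs(e$loglik - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- e$loglik
    g <- e$gamma
    wk <- colSums(g)
    par$means <- (t(g) %*% x) / wk
    second <- (t(g) %*% (x^2)) / wk
    par$vars <- pmax(second - par$means^2, 1e-6)
    if (k > 1) {
      par$transmat <- e$xi / rowSums(e$xi)
      par$initprob <- g[1, ] / sum(g[1, ])
    }
  }
  list(par = par, loglik = ll_trace[length(ll_trace)], n_iter = length(ll_trace),
       converged = converged)
}

#' Fit a Gaussian HMM with diagonal covariance
#'
#' EM-fitted hidden Markov model on PC scores, with seeded k-means
#' initialization and multiple restarts (best training log-likelihood kept)
#' to guard against local optima.
#'
#' @param pcs Frame x PC matrix from [preprocess_for_hmm()] (any numeric
#'   matrix or data frame works).
#' @param n_states Number of hidden states.
#' @param config An [hmm_config()] supplying max_iter, tol, restarts, seed.
#' @return Object of class `engagement_hmm`: state means, diagonal
#'   variances, transition matrix, initial distribution, log-likelihood,
#'   convergence flag.
#' @export
fit_hmm <- function(pcs, n_states = config$n_states, config = hmm_config()) {
  x <- as.matrix(pcs)
  if (any(!is.finite(x))) stopf("non-finite values in the PC matrix.")
  fits <- lapply(seq_len(config$n_restarts), function(r)
    hmm_em_once(x, n_states, config$max_iter, config$tol,
                derive_seed(config$seed, r)))
  best <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  if (!best$converged)
    warnf("EM did not converge within %d iterations.", config$max_iter)
  structure(list(
    n_states = as.integer(n_states),
    means = best$par$means, vars = best$par$vars,
    transmat = best$par$transmat, initprob = best$par$initprob,
    loglik = best$loglik, loglik_per_frame = best$loglik / nrow(x),
    n_iter = best$n_iter, converged = best$converged,
    n_frames = nrow(x), n_features = ncol(x), seed = config$seed
  ), class = "engagement_hmm")
}

#' @export
print.engagement_hmm <- function(x, ...) {
  cat(sprintf("Gaussian HMM: %d state(s), %d features, %d frames\n",
              x$n_states, x$n_features, x$n_frames))
  cat(sprintf("log-likelihood %.2f (%.4f/frame), EM %s in %d iterations\n",
              x$loglik, x$loglik_per_frame,
              if (x$converged) "converged" else "did not converge", x$n_iter))
  cat("transition matrix:\n"); print(round(x$transmat, 4))
  invisible(x)
}

hmm_loglik <- function(model, x) {
  ld <- gaussian_logdens(as.matrix(x), model$means, model$vars)
  hmm_forward_backward(ld, model$transmat, model$initprob)$loglik
}

#' Compare HMMs across state counts
#'
#' Fits one model per candidate state count on the same data, with shared
#' preprocessing and seed policy.
#'
#' @param pcs Frame x PC matrix.
#' @param ks State counts to compare (default 1, 2, 3).
#' @param config An [hmm_config()].
#' @return Tibble: `k`, `loglik`, `loglik_per_frame`, `converged`.
#' @export
select_state_count <- function(pcs, ks = 1:3, config = hmm_config()) {
  if (!length(ks)) stopf("ks must be non-empty.")
  purrr::map_dfr(ks, function(k) {
    fit <- fit_hmm(pcs, n_states = k, config = config)
    tibble::tibble(k = k, loglik = fit$loglik,
                   loglik_per_frame = fit$loglik_per_frame,
                   converged = fit$converged)
  })
}

#' Forward (past-to-future) cross-validation of the HMM
#'
#' Splits the session into four contiguous quarters. Fold f trains on the
#' first f quarters and tests on quarter f + 1, so the model always trains
#' on the past and is evaluated on the future; log-likelihoods are
#' per-frame for comparability.
#'
#' @param pcs Frame x PC matrix.
#' @param config An [hmm_config()].
#' @param folds Number of folds (3 with quarter splits).
#' @return Tibble: `fold`, `n_train`, `n_test`, `train_ll_frame`,
#'   `test_ll_frame`.
#' @export
crossvalidate_hmm <- function(pcs, config = hmm_config(), folds = 3) {
  x <- as.matrix(pcs)
  n <- nrow(x)
  q <- n %/% (folds + 1)
  if (q < 10) stopf("too few frames per quarter for cross-validation.")
  purrr::map_dfr(seq_len(folds), function(f) {
    train <- seq_len(f * q)
    test_end <- if (f == folds) n else (f + 1) * q
    test <- (f * q + 1):test_end
    fit <- fit_hmm(x[train, , drop = FALSE], config$n_states, config)
    tibble::tibble(
      fold = f, n_train = length(train), n_test = length(test),
      train_ll_frame = fit$loglik / length(train),
      test_ll_frame = hmm_loglik(fit, x[test, , drop = FALSE]) / length(test)
    )
  })
}

#' Decode the state sequence
#'
#' Most-probable state path (Viterbi) by default; `method = "posterior"`
#' gives the per-frame posterior argmax instead.
#'
#' @param model An `engagement_hmm`.
#' @param pcs Frame x PC matrix with the model's feature count.
#' @param method `"viterbi"` or `"posterior"`.
#' @return Tibble of class `state_sequence`: `frame`, `time_s`, `state`
#'   (integer 1..k).
#' @export
decode_states <- function(model, pcs, method = c("viterbi", "posterior")) {
  method <- match.arg(method)
  x <- as.matrix(pcs)
  if (ncol(x) != model$n_features)
    stopf("PC matrix has %d features but the model expects %d.",
          ncol(x), model$n_features)
  ld <- gaussian_logdens(x, model$means, model$vars)
  states <- if (method == "viterbi") {
    as.integer(hmm_viterbi(ld, model$transmat, model$initprob))
  } else {
    as.integer(max.col(hmm_forward_backward(ld, model$transmat,
                                            model$initprob)$gamma))
  }
  rate <- attr(pcs, "frame_rate_hz") %||% 10
  out <- tibble::tibble(frame = seq_len(nrow(x)),
                        time_s = (seq_len(nrow(x)) - 1) / rate,
                        state = states)
  structure(out, frame_rate_hz = rate, n_states = model$n_states,
            class = c("state_sequence", class(out)))
}
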