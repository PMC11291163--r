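# Shared fixtures, all generated in code.

# small fast session for structural tests
small_session <- function(seed = 3, ...) {
  generate_session(synthetic_config(n_neurons = 25, session_length_s = 600,
                                    seed = seed, ...))
}

# trial table with prescribed outcome counts (free-choice trials only)
trials_from_counts <- function(hits, misses, fas, crs, spacing_s = 10) {
  outcome <- c(rep("hit", hits), rep("miss", misses),
               rep("FA", fas), rep("CR", crs))
  outcome <- sample(outcome) # order must not matter
  n <- length(outcome)
  onset <- seq_len(n) * spacing_s
  responded <- outcome %in% c("hit", "FA")
  tibble::tibble(
    trial_index = seq_len(n),
    stimulus = ifelse(outcome %in% c("hit", "miss"), "S+", "S-"),
    onset_s = onset,
    response_s = ifelse(responded, onset + 1.5, NA_real_),
    outcome = outcome,
    correction = FALSE
  )
}

# direct simulation from a known Gaussian HMM (features x frames)
simulate_gaussian_hmm <- function(n_frames, means, stay = 0.99, seed = 1) {
  set.seed(seed)
  k <- nrow(means); p <- ncol(means)
  states <- integer(n_frames)
  states[1] <- sample.int(k, 1)
  trans <- matrix((1 - stay) / (k - 1), k, k); diag(trans) <- stay
  for (t in 2:n_frames)
    states[t] <- sample.int(k, 1, prob = trans[states[t - 1], ])
  x <- means[states, , drop = FALSE] + matrix(rnorm(n_frames * p), n_frames, p)
  list(x = x, states = states, trans = trans)
}

# brute-force Pearson r from the textbook formula
pearson_direct <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# block correlation matrix with planted clusters
planted_block_matrix <- function(sizes, within = 0.6, between = 0) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  m <- matrix(between, n, n)
  m[outer(lab, lab, "==")] <- within
  diag(m) <- 0
  rownames(m) <- colnames(m) <- sprintf("cell_%03d", seq_len(n))
  m
}
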