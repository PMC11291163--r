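means2 <- matrix(c(-1.5, -1.5, -1.5, 1.5, 1.5, 1.5), 2, 3, byrow = TRUE)

test_that("preprocessing truncates, projects, and reports variance", {
  set.seed(1)
  m <- matrix(rnorm(30000 * 12), 30000, 12) # 3000 s at 10 Hz
  cfg <- hmm_config(n_pcs_retained = 12, n_pcs_hmm = 10)
  pcs <- preprocess_for_hmm(m, cfg)
  expect_equal(nrow(pcs), 27000) # first 45 minutes
  expect_equal(ncol(pcs), 10)
  expect_equal(attr(pcs, "cumvar_retained"), 1, tolerance = 1e-12)
  expect_true(all(is.finite(pcs)))
  expect_error(preprocess_for_hmm(matrix(1, 100, 5), hmm_config(truncate_s = 5)),
               "zero-variance")
  expect_warning(preprocess_for_hmm(matrix(rnorm(500), 100, 5),
                                    hmm_config(truncate_s = 20, n_pcs_hmm = 4,
                                               n_pcs_retained = 5)),
                 "shorter")
})

test_that("planted two-state model is recovered by EM and Viterbi", {
  sim <- simulate_gaussian_hmm(6000, means2, stay = 0.99, seed = 2)
  cfg <- hmm_config(seed = 3)
  fit <- fit_hmm(sim$x, 2, cfg)
  st <- decode_states(fit, sim$x)
  agree <- max(mean(st$state == sim$states), mean(st$state == 3 - sim$states))
  expect_gte(agree, 0.99)
  # identical seed gives identical parameters
  fit2 <- fit_hmm(sim$x, 2, cfg)
  expect_identical(fit$means, fit2$means)
  expect_identical(fit$transmat, fit2$transmat)
  st2 <- decode_states(fit2, sim$x)
  expect_identical(st$state, st2$state)
})

test_that("transition stay-probabilities are recovered within 0.05", {
  sim <- simulate_gaussian_hmm(27000, means2, stay = 0.9983, seed = 4)
  fit <- fit_hmm(sim$x, 2, hmm_config(seed = 5))
  expect_true(all(abs(diag(fit$transmat) - 0.9983) < 0.05))
})

test_that("a one-state model reduces to a single Gaussian", {
  set.seed(6)
  x <- matrix(rnorm(2000 * 3, sd = 2), 2000, 3)
  fit <- fit_hmm(x, 1, hmm_config(seed = 7))
  # closed-form log-likelihood of the MLE diagonal Gaussian
  mu <- colMeans(x)
  v <- colMeans(sweep(x, 2, mu)^2)
  ll <- sum(vapply(1:3, function(j)
    sum(dnorm(x[, j], mu[j], sqrt(v[j]), log = TRUE)), 0))
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
  st <- decode_states(fit, x)
  expect_true(all(st$state == 1))
})

test_that("state-count comparison favors the true two-state structure", {
  sim <- simulate_gaussian_hmm(4000, means2, stay = 0.99, seed = 8)
  tab <- select_state_count(sim$x, ks = 1:3, config = hmm_config(seed = 9))
  expect_equal(tab$k, 1:3)
  ll <- setNames(tab$loglik, tab$k)
  expect_gt(ll["2"], ll["1"])
  # nested family: more states never fit worse on training data
  expect_gte(ll["3"], ll["2"] - 1e-6)
  one <- select_state_count(sim$x, ks = 1, config = hmm_config(seed = 9))
  expect_equal(nrow(one), 1)
})

test_that("cross-validation trains on the past and tests on the future", {
  sim <- simulate_gaussian_hmm(27000, means2, stay = 0.995, seed = 10)
  cv <- crossvalidate_hmm(sim$x, hmm_config(seed = 11), folds = 3)
  expect_equal(cv$fold, 1:3)
  expect_equal(cv$n_train, c(6750, 13500, 20250))
  expect_equal(cv$n_test, c(6750, 6750, 6750))
  # stationary data: held-out per-frame LL close to the training value
  expect_true(all(abs(cv$test_ll_frame - cv$train_ll_frame) <
                    0.05 * abs(cv$train_ll_frame)))
  expect_error(crossvalidate_hmm(sim$x[1:20, ], hmm_config()), "too few")
})

test_that("event-state posteriors normalize and label the engaged state", {
  st <- tibble::tibble(frame = 1:4, time_s = (0:3) / 10,
                       state = c(1L, 1L, 2L, 2L))
  attr(st, "frame_rate_hz") <- 10
  tr <- tibble::tibble(trial_index = 1:2, stimulus = "S+",
                       onset_s = c(0, 0.2), response_s = c(0.0, 0.3),
                       outcome = "hit", correction = FALSE)
  es <- suppressWarnings(event_state_posteriors(st, tr))
  any_p <- es$posteriors[es$posteriors$event_type == "Any", ]
  expect_equal(any_p$p, c(0.5, 0.5))
  expect_equal(sum(any_p$p), 1)
  # all events in one state
  tr2 <- tibble::tibble(trial_index = 1:2, stimulus = "S+",
                        onset_s = c(0.15, 0.25), response_s = c(0.2, 0.3),
                        outcome = "hit", correction = FALSE)
  es2 <- suppressWarnings(event_state_posteriors(st, tr2))
  expect_equal(es2$engaged_state, 2L)
  expect_equal(es2$p_responses_engaged, 1)
  # posteriors sum to one for every defined event type
  sums <- tapply(es2$posteriors$p, es2$posteriors$event_type, sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))
})

test_that("engagement stats are invariant to state relabeling", {
  s <- small_session(seed = 31)
  hcfg <- hmm_config(truncate_s = 600, n_pcs_retained = 10, n_pcs_hmm = 5,
                     seed = 12)
  pcs <- preprocess_for_hmm(s$traces, hcfg)
  st <- decode_states(fit_hmm(pcs, 2, hcfg), pcs)
  dp <- detect_disengagement_periods(s$trials)
  es <- event_state_posteriors(st, s$trials, dp)
  # swap the labels
  st_sw <- st
  st_sw$state <- 3L - st_sw$state
  es_sw <- event_state_posteriors(st_sw, s$trials, dp)
  expect_equal(es_sw$engaged_state, 3L - es$engaged_state)
  expect_equal(es_sw$p_responses_engaged, es$p_responses_engaged)
  expect_equal(es_sw$p_disengaged_periods, es$p_disengaged_periods)
  p1 <- dplyr::arrange(es$posteriors, event_type, state)
  p2 <- dplyr::arrange(dplyr::mutate(es_sw$posteriors, state = 3L - state),
                       event_type, state)
  expect_equal(p1$p, p2$p)
})

test_that("engagement-behavior correlations behave like Pearson r", {
  df <- tibble::tibble(p_responses_engaged = seq(0.5, 0.9, length.out = 8),
                       latency_mean_s = 10 - 8 * seq(0.5, 0.9, length.out = 8),
                       flat = 1)
  expect_warning(out <- correlate_engagement_with_behavior(df), "constant")
  expect_equal(out$r[out$metric == "latency_mean_s"], -1, tolerance = 1e-12)
  expect_true(is.na(out$r[out$metric == "flat"]))
  # symmetry of r under argument order
  set.seed(13)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(cor(x, y), cor(y, x))
  expect_error(correlate_engagement_with_behavior(df[1:2, ]), "3 animals")
})

test_that("tidiers expose model parameters", {
  sim <- simulate_gaussian_hmm(1500, means2, stay = 0.98, seed = 14)
  fit <- fit_hmm(sim$x, 2, hmm_config(seed = 15))
  td <- tidy(fit)
  expect_equal(sum(td$estimate[td$term %in%
    c("transition_1_1", "transition_1_2")]), 1, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$n_states, 2L)
  expect_true(gl$loglik_per_frame < 0)
})
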