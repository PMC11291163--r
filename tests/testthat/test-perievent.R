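# small windows used by the toy tests (5-frame statistical windows at 10 Hz)
toy_windows <- function(n_shuffles = 100, seed = 0) {
  peri_event_windows(visual_pre_s = 1, visual_post_s = 1,
                     stat_pre_start_s = 0.5, stat_pre_end_s = 0,
                     stat_post_start_s = 0, stat_post_end_s = 0.5,
                     n_shuffles = n_shuffles, seed = seed)
}

test_that("z-scoring standardizes rows and is affine invariant", {
  set.seed(1)
  m <- matrix(rnorm(200, mean = 3, sd = 2), 50, 4)
  z <- zscore_traces(m)
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4), tolerance = 1e-12)
  z2 <- zscore_traces(5 * m - 7)
  expect_equal(z, z2, tolerance = 1e-12)
  m[, 2] <- 1
  expect_warning(z3 <- zscore_traces(m), "zero-variance")
  expect_equal(ncol(z3), 3)
})

test_that("peri-event extraction slices the visual window and drops edge events", {
  set.seed(2)
  m <- matrix(rnorm(3000 * 3), 3000, 3)
  w <- peri_event_windows()
  arr <- extract_peri_event(m, c(3, 100, 200), w, frame_rate_hz = 10)
  # event at 3 s cannot host an 8 s pre-window
  expect_equal(dim(arr), c(2, 3, 161))
  expect_equal(attr(arr, "n_dropped"), 1)
  # slice content: event frame floor(100*10) = 1000 (0-based)
  expect_equal(arr[1, 2, ], m[(1000 - 80):(1000 + 80) + 1, 2])
  expect_error(extract_peri_event(m, 2, w, 10), "no events")
})

test_that("delta activity is the mean post-minus-pre window difference", {
  w <- toy_windows()
  # step trace: 0 before each event frame, 1 from it onward
  n <- 400
  ev <- c(10, 20, 30)
  m <- matrix(0, n, 2)
  for (t in ev) m[(floor(t * 10) + 1):n, 1] <- m[(floor(t * 10) + 1):n, 1] + 1
  arr <- extract_peri_event(m, ev, w, 10)
  d <- delta_activity(arr, w)
  expect_equal(unname(d[1]), 1)   # one unit step at every event
  expect_equal(unname(d[2]), 0)   # flat zero trace
  # two events with per-event differences 0.4 and 0.8 average to 0.6
  m2 <- matrix(0, n, 1)
  m2[(101):n, 1] <- 0.4
  m2[(201):n, 1] <- m2[(201):n, 1] + 0.8
  arr2 <- extract_peri_event(m2, c(10, 20), w, 10)
  expect_equal(unname(delta_activity(arr2, w)), 0.6)
})

test_that("sampled circular null is a subsample of the exhaustive-shift null", {
  set.seed(3)
  n_frames <- 50
  trace <- matrix(rnorm(n_frames), n_frames, 1)
  ev <- 2.5 # event frame 25 (0-based)
  w <- toy_windows(n_shuffles = 500, seed = 42)
  # brute-force oracle: every circular shift, wrapped windows on the
  # tripled trace
  wrapped <- c(trace, trace, trace)
  oracle <- vapply(1:(n_frames - 1), function(off) {
    f <- (floor(ev * 10) + off) %% n_frames # 0-based shifted event frame
    pre <- mean(wrapped[n_frames + f + (-5:-1) + 1])
    post <- mean(wrapped[n_frames + f + (0:4) + 1])
    post - pre
  }, 0)
  null <- circular_permutation_null(trace, ev, w, 10)
  expect_equal(nrow(null), 500)
  # every sampled value equals the oracle value of its offset
  offs <- attr(null, "offsets")
  expect_equal(null[, 1], oracle[offs], tolerance = 1e-12)
  # enumerating all offsets reproduces the exhaustive null exactly
  full <- cptstates:::null_deltas_for_offsets(
    trace, floor(ev * 10), 1:(n_frames - 1),
    cptstates:::window_frames(w, 10))
  expect_equal(full[, 1], oracle, tolerance = 1e-12)
  # determinism under the seed stored in the windows
  null2 <- circular_permutation_null(trace, ev, w, 10)
  expect_identical(null, null2)
})

test_that("constant traces give an all-zero null", {
  w <- toy_windows(n_shuffles = 50)
  m <- matrix(2, 200, 1)
  null <- circular_permutation_null(m, c(5, 10), w, 10)
  expect_true(all(abs(null) < 1e-12))
})

test_that("classification follows the two-tailed bootstrap rule", {
  null <- matrix(rnorm(1000 * 3), 1000, 3)
  delta <- c(max(null[, 1]) + 1, stats::median(null[, 2]), min(null[, 3]) - 1)
  res <- classify_modulation(delta, null, alpha = 0.05)
  expect_equal(as.character(res$label), c("up", "non", "down"))
  expect_equal(res$boot_p[1], 0)
  expect_equal(res$boot_p[2], 0.5, tolerance = 0.01)
  expect_equal(res$boot_p[3], 1)
  # labels partition the population
  expect_equal(sum(table(res$label)), 3)
})

test_that("classification is invariant to a global circular shift of traces and events", {
  set.seed(4)
  n_frames <- 800
  m <- matrix(rnorm(n_frames * 6), n_frames, 6)
  ev <- c(20, 35, 50)
  w <- toy_windows(n_shuffles = 200, seed = 7)
  shift <- 150 # frames
  m_shift <- rbind(m[(n_frames - shift + 1):n_frames, ], m[1:(n_frames - shift), ])
  ev_shift <- ev + shift / 10
  r1 <- peri_event_analysis(m, ev, w, 10)
  r2 <- peri_event_analysis(m_shift, ev_shift, w, 10)
  expect_equal(r1$delta, r2$delta, tolerance = 1e-10)
  expect_identical(as.character(r1$label), as.character(r2$label))
})

test_that("null traces are classified at roughly the nominal rate", {
  nt <- generate_null_traces(300, 8000, seed = 5, ar_coef = 0.8)
  set.seed(6)
  ev <- sort(runif(25, 20, 780))
  w <- peri_event_windows(n_shuffles = 400, seed = 1)
  res <- peri_event_analysis(nt$traces, ev, w)
  fpr <- mean(res$label != "non")
  expect_gt(fpr, 0.01)
  expect_lt(fpr, 0.105)
})

test_that("planted up-modulated neurons are recovered at touch alignment", {
  s <- generate_session(synthetic_config(
    n_neurons = 40, session_length_s = 900, seed = 8, event_effect_size = 2))
  w <- peri_event_windows(n_shuffles = 500, seed = 2)
  res <- peri_event_analysis(s$traces, peri_event_times(s$trials, "any"), w)
  up_found <- which(res$label == "up")
  recall <- mean(s$truth$up_neurons %in% up_found)
  expect_gte(recall, 0.9)
  # stimulus alignment shifts windows but the pipeline still runs end-to-end
  res_stim <- peri_event_analysis(
    s$traces, peri_event_times(s$trials, "any", "stimulus"), w)
  expect_equal(nrow(res_stim), 40)
})

test_that("modulation overlap matches explicit set arithmetic", {
  set.seed(9)
  lab <- function(x) factor(x, levels = c("up", "down", "non"))
  ids <- sprintf("c%02d", 1:30)
  a <- tibble::tibble(cell_id = ids,
                      label = lab(sample(c("up", "down", "non"), 30, TRUE)))
  b <- tibble::tibble(cell_id = ids,
                      label = lab(sample(c("up", "down", "non"), 30, TRUE)))
  ov <- modulation_overlap(a, b)
  for (dir in c("up", "down")) {
    sa <- a$cell_id[a$label == dir]; sb <- b$cell_id[b$label == dir]
    row <- ov[ov$direction == dir, ]
    expect_equal(row$only_a, length(setdiff(sa, sb)))
    expect_equal(row$only_b, length(setdiff(sb, sa)))
    expect_equal(row$both, length(intersect(sa, sb)))
  }
  # identical labels: intersection equals set size
  ov2 <- modulation_overlap(a, a)
  expect_equal(ov2$both, c(sum(a$label == "up"), sum(a$label == "down")))
  expect_equal(ov2$only_a, c(0L, 0L))
  expect_error(modulation_overlap(a, b[1:10, ]), "same cells")
})
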