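test_that("state correlation matrix matches the direct Pearson formula", {
  set.seed(1)
  m <- matrix(rnorm(20 * 5), 20, 5)
  colnames(m) <- sprintf("cell_%03d", 1:5)
  r <- state_correlation_matrix(m, rep(TRUE, 20))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(r[i, j], pearson_direct(m[, i], m[, j]), tolerance = 1e-12)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(0, 5))
  # duplicated and negated pairs
  m2 <- cbind(m[, 1], m[, 1], -m[, 1])
  r2 <- state_correlation_matrix(m2, rep(TRUE, 20))
  expect_equal(r2[1, 2], 1)
  expect_equal(r2[1, 3], -1)
  # mask restricts the frames entering the correlation
  mask <- c(rep(TRUE, 10), rep(FALSE, 10))
  r3 <- state_correlation_matrix(m, mask)
  expect_equal(r3[1, 2], pearson_direct(m[1:10, 1], m[1:10, 2]),
               tolerance = 1e-12)
  m[, 2] <- 3
  expect_warning(r4 <- state_correlation_matrix(m, rep(TRUE, 20)),
                 "zero variance")
  expect_true(all(is.na(r4[2, -2])))
})

test_that("per-cell extremes match an explicit row scan", {
  mat <- rbind(c(0, 0.2, -0.6, 0.5),
               c(0.2, 0, 0.1, 0.3),
               c(-0.6, 0.1, 0, -0.2),
               c(0.5, 0.3, -0.2, 0))
  ext <- cell_max_correlations(mat)
  expect_equal(ext$max_positive[1], 0.5)
  expect_equal(ext$max_negative[1], -0.6)
  set.seed(2)
  rm_ <- matrix(runif(36, -1, 1), 6, 6); rm_ <- (rm_ + t(rm_)) / 2
  diag(rm_) <- 0
  ext2 <- cell_max_correlations(rm_)
  for (i in 1:6) {
    row <- rm_[i, -i]
    expect_equal(ext2$max_positive[i], max(row[row > 0]))
    expect_equal(ext2$max_negative[i], min(row[row < 0]))
  }
  allpos <- matrix(0.5, 3, 3); diag(allpos) <- 0
  expect_true(all(is.na(cell_max_correlations(allpos)$max_negative)))
})

test_that("KS statistic equals the maximal ECDF gap", {
  set.seed(3)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  out <- compare_state_distributions(x, y)
  grid <- sort(c(x, y))
  gap <- max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), 0)))
  expect_equal(out$D, gap, tolerance = 1e-12)
  same <- compare_state_distributions(x, x)
  expect_equal(same$D, 0)
  disjoint <- compare_state_distributions(1:20, 101:120)
  expect_equal(disjoint$D, 1)
  expect_equal(nrow(out$curves), 75)
})

test_that("sign-flip classification finds planted structure and is seeded", {
  set.seed(4)
  n_frames <- 600
  base <- rnorm(n_frames)
  m <- cbind(base + rnorm(n_frames, sd = 0.2),
             base + rnorm(n_frames, sd = 0.2),
             matrix(rnorm(n_frames * 4), n_frames))
  colnames(m) <- sprintf("cell_%03d", 1:6)
  cls <- classify_pair_correlations(m, rep(TRUE, n_frames), n_perm = 2000,
                                    seed = 5)
  pair12 <- cls[cls$cell_i == "cell_001" & cls$cell_j == "cell_002", ]
  expect_equal(pair12$class, "positive")
  cls2 <- classify_pair_correlations(m, rep(TRUE, n_frames), n_perm = 2000,
                                     seed = 5)
  expect_identical(cls$class, cls2$class)
  expect_warning(classify_pair_correlations(m, rep(TRUE, n_frames),
                                            n_perm = 50, seed = 5),
                 "unstable")
})

test_that("sign-flip false-positive rate on independent noise is near alpha", {
  set.seed(6)
  m <- matrix(rnorm(2000 * 40), 2000, 40) # 780 pairs
  cls <- classify_pair_correlations(m, rep(TRUE, 2000), n_perm = 10000,
                                    seed = 7)
  fpr <- mean(cls$class != "nonsignificant")
  expect_gte(fpr, 0.03)
  expect_lte(fpr, 0.07)
})

test_that("noiseless exponential decay is recovered exactly", {
  set.seed(8)
  x <- runif(300, 0, 400)
  y <- 2 * exp(-0.5 * x / 100) # A = 2, k = -0.005 per um
  fit <- fit_correlation_decay(y, x, "positive", n_boot = 50, seed = 9)
  expect_equal(fit$A, 2, tolerance = 1e-6)
  expect_equal(fit$k, -0.005, tolerance = 1e-6)
  expect_true(fit$converged)
  # A is the zero-distance intercept
  expect_equal(fit$A * exp(fit$k * 0), 2, tolerance = 1e-6)
  # negative category: sign convention restored
  fneg <- fit_correlation_decay(-y, x, "negative", n_boot = 50, seed = 9)
  expect_equal(fneg$A, -2, tolerance = 1e-6)
  expect_equal(fneg$k, -0.005, tolerance = 1e-6)
  expect_error(fit_correlation_decay(y[1:5], x[1:5]), "at least 10")
})

test_that("bootstrap CIs cover the true decay parameters in most seeded runs", {
  covered <- vapply(1:10, function(run) {
    set.seed(100 + run)
    x <- runif(2000, 0, 450)
    y <- 0.3 * exp(-0.004 * x) + rnorm(2000, sd = 0.05)
    fit <- fit_correlation_decay(y, x, "positive", n_boot = 200,
                                 seed = 200 + run)
    fit$ci_k[1] <= -0.004 && -0.004 <= fit$ci_k[2] &&
      fit$ci_A[1] <= 0.3 && 0.3 <= fit$ci_A[2]
  }, TRUE)
  expect_gte(mean(covered), 0.9)
})

test_that("decay-rate z-test follows the stated arithmetic", {
  f1 <- structure(list(k = -0.004, se_k = 0.0005), class = "decay_fit")
  f2 <- structure(list(k = -0.004, se_k = 0.0005), class = "decay_fit")
  out <- compare_decay_rates(f1, f2)
  expect_equal(out$z, 0)
  expect_equal(out$p, 1)
  se <- sqrt(2) * 0.0005
  f3 <- structure(list(k = -0.004 + 2 * se, se_k = 0.0005),
                  class = "decay_fit")
  expect_equal(compare_decay_rates(f3, f1)$z, 2, tolerance = 1e-12)
  expect_equal(compare_decay_rates(f1, f3)$z, -2, tolerance = 1e-12)
  f0 <- structure(list(k = 0, se_k = 0), class = "decay_fit")
  expect_error(compare_decay_rates(f0, f0), "zero combined")
})

test_that("k-means recovers planted blocks and selects their count", {
  m2 <- planted_block_matrix(c(12, 12))
  cl2 <- cluster_states(m2, k_grid = 2:5, seed = 10)
  expect_equal(cl2$k, 2L)
  lab <- rep(1:2, each = 12)
  expect_equal(length(unique(paste(cl2$assignments$cluster, lab))), 2)
  m3 <- planted_block_matrix(c(10, 10, 10))
  cl3 <- cluster_states(m3, k_grid = 2:5, seed = 11)
  expect_equal(cl3$k, 3L)
  cl2b <- cluster_states(m2, k_grid = 2:5, seed = 10)
  expect_identical(cl2$assignments, cl2b$assignments)
})

test_that("cluster metrics equal brute-force distance arithmetic", {
  cent <- tibble::tibble(cell_id = sprintf("c%d", 1:5),
                         x_um = c(0, 10, 0, 0, 5),
                         y_um = c(0, 0, 3, 4, 5))
  asg <- tibble::tibble(cell_id = cent$cell_id,
                        cluster = c(1L, 1L, 2L, 2L, 3L))
  cm <- cluster_metrics(asg, cent)
  # cluster 1: two cells 10 um apart -> mean distance to midpoint = 5
  expect_equal(cm$compactness_um[cm$cluster == 1], 5)
  # brute force for cluster 2
  cx <- mean(c(0, 0)); cy <- mean(c(3, 4))
  expect_equal(cm$compactness_um[cm$cluster == 2],
               mean(sqrt((c(0, 0) - cx)^2 + (c(3, 4) - cy)^2)))
  expect_equal(cm$size, c(2L, 2L, 1L))
  expect_true(cm$singleton[cm$cluster == 3])
  expect_equal(cm$compactness_um[cm$cluster == 3], 0)
  # all cells at one point
  cent0 <- dplyr::mutate(cent, x_um = 1, y_um = 1)
  cm0 <- cluster_metrics(asg, cent0)
  expect_true(all(cm0$compactness_um == 0))
})

test_that("coupling comparison detects planted state shifts", {
  set.seed(12)
  ids <- sprintf("cell_%03d", 1:10)
  pairs <- expand.grid(i = 1:10, j = 1:10)
  pairs <- pairs[pairs$i < pairs$j, ]
  base_r <- runif(nrow(pairs), 0.05, 0.6)
  pe <- tibble::tibble(cell_i = ids[pairs$i], cell_j = ids[pairs$j],
                       r = base_r)
  asg <- tibble::tibble(cell_id = ids, cluster = rep(1:2, each = 5L))
  cl <- stats::setNames(asg$cluster, asg$cell_id)
  intra <- cl[pe$cell_i] == cl[pe$cell_j]
  # identical states: zero differences, degenerate t
  out0 <- suppressWarnings(compare_cluster_coupling(pe, pe, asg))
  row <- out0$tests[out0$tests$partition == "intra" &
                      out0$tests$direction == "positive", ]
  expect_equal(row$mean_engaged, row$mean_disengaged)
  expect_true(is.na(row$t))
  # disengaged = engaged + 0.1 on intra pairs -> detected shift
  pd <- pe
  pd$r[intra] <- pd$r[intra] + 0.1
  out1 <- suppressWarnings(compare_cluster_coupling(pe, pd, asg))
  row1 <- out1$tests[out1$tests$partition == "intra" &
                       out1$tests$direction == "positive", ]
  expect_equal(row1$mean_disengaged - row1$mean_engaged, 0.1, tolerance = 1e-12)
  expect_lt(row1$p, 1e-6)
  # Spearman rho = -1 for strictly decreasing correlation vs distance
  dists <- tibble::tibble(cell_i = pe$cell_i, cell_j = pe$cell_j,
                          distance_um = rank(-pe$r) * 10)
  out2 <- suppressWarnings(
    compare_cluster_coupling(pe, pe, asg, distances = dists))
  expect_equal(out2$spearman$rho[out2$spearman$state == "engaged"], -1)
})

test_that("correlation_network assembles a consistent pair table", {
  s <- generate_session(synthetic_config(
    n_neurons = 20, session_length_s = 300, seed = 13, noise_sd = 0.5,
    frac_up = 0, frac_down = 0, state_mod_frac = 0))
  mask <- s$truth$state_sequence == "engaged"
  net <- correlation_network(s$traces, mask, s$centroids, n_perm = 500,
                             seed = 14)
  expect_equal(nrow(net$pairs), choose(20, 2))
  expect_setequal(unique(net$pairs$class) %in%
                    c("positive", "negative", "nonsignificant"), TRUE)
  expect_equal(net$matrix, t(net$matrix))
  expect_true(all(diag(net$matrix) == 0))
  # pair table r values agree with the matrix
  i <- match(net$pairs$cell_i[1], rownames(net$matrix))
  j <- match(net$pairs$cell_j[1], colnames(net$matrix))
  expect_equal(net$pairs$r[1], net$matrix[i, j])
})
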