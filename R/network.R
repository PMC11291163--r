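#' State-conditioned pairwise correlation matrix
#'
#' Collapses all frames assigned to one state and computes pairwise Pearson
#' correlation between all neuron pairs. Self-correlations (the diagonal)
#' are set to zero. Cells with zero variance within the state produce NA
#' pairs and are reported with a warning.
#'
#' @param traces Trace tibble or frames x neurons matrix.
#' @param state_mask Logical vector (length = frames) selecting the state's
#'   frames, or an integer vector of frame indices.
#' @return Symmetric correlation matrix with zero diagonal.
#' @export
state_correlation_matrix <- function(traces, state_mask) {
  m <- trace_matrix(traces)
  rows <- if (is.logical(state_mask)) which(state_mask) else as.integer(state_mask)
  if (length(rows) < 2) stopf("need at least 2 frames in the state.")
  if (ncol(m) < 2) stopf("need at least 2 neurons.")
  sub <- m[rows, , drop = FALSE]
  sds <- apply(sub, 2, sd)
  if (any(sds == 0))
    warnf("%d cell(s) with zero variance in this state; their pairs are NA.",
          sum(sds == 0))
  r <- suppressWarnings(cor(sub))
  diag(r) <- 0
  r
}

#' Per-cell extreme correlations
#'
#' For each cell, the largest positive and the most negative correlation
#' with any other cell (diagonal excluded). Cells with no positive (or no
#' negative) partner get NA in that column.
#'
#' @param mat Correlation matrix with zero diagonal.
#' @return Tibble: `cell_id`, `max_positive`, `max_negative`.
#' @export
cell_max_correlations <- function(mat) {
  if (nrow(mat) < 2) stopf("need at least 2 cells.")
  ids <- rownames(mat) %||% cell_ids(nrow(mat))
  one <- function(i) {
    row <- mat[i, -i]
    pos <- row[row > 0 & is.finite(row)]
    neg <- row[row < 0 & is.finite(row)]
    c(if (length(pos)) max(pos) else NA_real_,
      if (length(neg)) min(neg) else NA_real_)
  }
  ext <- t(vapply(seq_len(nrow(mat)), one, numeric(2)))
  tibble::tibble(cell_id = ids, max_positive = ext[, 1], max_negative = ext[, 2])
}

#' Compare correlation distributions between states
#'
#' Two-sample Kolmogorov-Smirnov test on pooled pair (or per-cell) values,
#' with the empirical cumulative curves for plotting.
#'
#' @param values_engaged,values_disengaged Numeric samples.
#' @return List of class `state_distribution_test`: `D`, `p`, `n_engaged`,
#'   `n_disengaged`, and `curves` (tibble: state, value, ecdf).
#' @export
compare_state_distributions <- function(values_engaged, values_disengaged) {
  x <- values_engaged[is.finite(values_engaged)]
  y <- values_disengaged[is.finite(values_disengaged)]
  if (!length(x) || !length(y)) stopf("both samples must be nonempty.")
  kt <- suppressWarnings(ks.test(x, y))
  curves <- dplyr::bind_rows(
    tibble::tibble(state = "engaged", value = sort(x),
                   ecdf = seq_along(x) / length(x)),
    tibble::tibble(state = "disengaged", value = sort(y),
                   ecdf = seq_along(y) / length(y))
  )
  structure(list(D = unname(kt$statistic), p = kt$p.value,
                 n_engaged = length(x), n_disengaged = length(y),
                 curves = curves),
            class = "state_distribution_test")
}

#' Sign-flip significance classes for correlation pairs
#'
#' Builds a permutation null for pairwise correlation by multiplying one
#' member of a pair by a random per-frame +-1 sign vector and recomputing r
#' (`n_perm` iterations over randomly drawn pairs). Pairs with observed r
#' above the 97.5th null percentile are classified positive, below the 2.5th
#' negative, otherwise nonsignificant (two-sided alpha 0.05).
#'
#' @param traces Trace tibble or matrix.
#' @param state_mask Frames of the state (logical or indices).
#' @param n_perm Number of sign-flip iterations (default 10000).
#' @param seed RNG seed.
#' @param alpha Two-sided level defining the percentile thresholds.
#' @return Tibble of class `pair_class_tbl`: `cell_i`, `cell_j`, `r`,
#'   `class`; thresholds and the null sample are attributes.
#' @export
classify_pair_correlations <- function(traces, state_mask, n_perm = 10000,
                                       seed = 1, alpha = 0.05) {
  if (n_perm < 100) warnf("n_perm < 100 gives unstable percentile thresholds.")
  m <- trace_matrix(traces)
  rows <- if (is.logical(state_mask)) which(state_mask) else as.integer(state_mask)
  sub <- m[rows, , drop = FALSE]
  n <- ncol(sub); T_ <- nrow(sub)
  if (n < 2 || T_ < 3) stopf("need >= 2 neurons and >= 3 frames.")
  r <- state_correlation_matrix(m, rows)
  set.seed(as.integer(seed))
  pick_i <- sample.int(n, n_perm, replace = TRUE)
  pick_j <- ((pick_i - 1L + sample.int(n - 1L, n_perm, replace = TRUE)) %% n) + 1L
  null_r <- vapply(seq_len(n_perm), function(it) {
    s <- sample(c(-1, 1), T_, replace = TRUE)
    suppressWarnings(cor(sub[, pick_i[it]] * s, sub[, pick_j[it]]))
  }, 0)
  null_r <- null_r[is.finite(null_r)]
  thr <- quantile(null_r, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  ids <- colnames(sub) %||% cell_ids(n)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[ut]
  cls <- dplyr::case_when(rv > thr[2] ~ "positive",
                          rv < thr[1] ~ "negative",
                          TRUE ~ "nonsignificant")
  out <- tibble::tibble(cell_i = ids[ut[, 1]], cell_j = ids[ut[, 2]],
                        r = rv, class = cls)
  structure(out, thresholds = thr, null_r = null_r,
            class = c("pair_class_tbl", class(out)))
}

#' Pairwise centroid distances
#'
#' @param centroids Tibble with `cell_id`, `x_um`, `y_um`.
#' @return Tibble: `cell_i`, `cell_j`, `distance_um` (upper triangle).
#' @export
pair_distances <- function(centroids) {
  d <- as.matrix(stats::dist(cbind(centroids$x_um, centroids$y_um)))
  ut <- which(upper.tri(d), arr.ind = TRUE)
  tibble::tibble(cell_i = centroids$cell_id[ut[, 1]],
                 cell_j = centroids$cell_id[ut[, 2]],
                 distance_um = d[ut])
}

#' Fit exponential decay of correlation with distance
#'
#' Nonlinear least-squares fit of y = A * exp(k * x) to pair correlation
#' strength versus inter-neuronal distance (Levenberg-Marquardt, log-linear
#' start). More negative k means faster spatial decay. For the negative
#' category the fit is on |r| and A is reported with its sign restored.
#' 95% confidence intervals come from a percentile bootstrap over pairs.
#'
#' @param pair_r Pair correlations.
#' @param pair_d Pair distances (micrometer).
#' @param category `"positive"`, `"negative"`, or `"nonsignificant"` —
#'   controls the sign convention only.
#' @param n_boot Bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `decay_fit`: `A`, `k`, `ci_A`, `ci_k`, `se_A`,
#'   `se_k`, `n_pairs`, `category`, `converged`.
#' @export
fit_correlation_decay <- function(pair_r, pair_d,
                                  category = c("positive", "negative",
                                               "nonsignificant"),
                                  n_boot = 1000, seed = 1) {
  category <- match.arg(category)
  ok <- is.finite(pair_r) & is.finite(pair_d)
  y <- pair_r[ok]; x <- pair_d[ok]
  if (length(y) < 10) stopf("need at least 10 pairs to fit the decay model.")
  neg <- category == "negative"
  if (neg) y <- abs(y)
  est <- decay_fit_once(y, x)
  set.seed(as.integer(seed))
  boot <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(y), replace = TRUE)
    fb <- tryCatch(decay_fit_once(y[idx], x[idx]), error = function(e) NULL)
    if (!is.null(fb)) boot[b, ] <- c(fb$A, fb$k)
  }
  boot <- boot[complete.cases(boot), , drop = FALSE]
  ci_A <- quantile(boot[, 1], c(0.025, 0.975), names = FALSE)
  ci_k <- quantile(boot[, 2], c(0.025, 0.975), names = FALSE)
  sgn <- if (neg) -1 else 1
  structure(list(
    A = sgn * est$A, k = est$k,
    ci_A = sort(sgn * ci_A), ci_k = ci_k,
    se_A = sd(boot[, 1]), se_k = sd(boot[, 2]),
    n_pairs = length(y), n_boot_ok = nrow(boot),
    category = category, converged = est$converged,
    data = tibble::tibble(r = sgn * y, distance_um = x)
  ), class = "decay_fit")
}

# single exponential fit; log-linear start, lm fallback on non-convergence
decay_fit_once <- function(y, x) {
  eps <- max(1e-6, min(y[y > 0], na.rm = TRUE) / 10)
  ll <- stats::lm(log(pmax(y, eps)) ~ x)
  start <- list(A = exp(coef(ll)[[1]]), k = coef(ll)[[2]])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(k * x), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    list(A = start$A, k = start$k, converged = FALSE)
  } else {
    cf <- coef(fit)
    list(A = cf[["A"]], k = cf[["k"]], converged = TRUE)
  }
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "exponential decay fit (%s, %d pairs): A = %.4f [%.4f, %.4f], k = %.5f [%.5f, %.5f] /um\n",
    x$category, x$n_pairs, x$A, x$ci_A[1], x$ci_A[2],
    x$k, x$ci_k[1], x$ci_k[2]))
  invisible(x)
}

#' z-test for a difference in decay rates
#'
#' Independent-parameter z-test on the decay constants of two exponential
#' fits: z = (k1 - k2) / sqrt(se1^2 + se2^2), two-sided normal p.
#'
#' @param fit1,fit2 `decay_fit` objects with bootstrap SEs.
#' @return Tibble: `k1`, `k2`, `z`, `p`.
#' @export
compare_decay_rates <- function(fit1, fit2) {
  se <- sqrt(fit1$se_k^2 + fit2$se_k^2)
  if (!is.finite(se) || se == 0) stopf("zero combined standard error.")
  z <- (fit1$k - fit2$k) / se
  tibble::tibble(k1 = fit1$k, k2 = fit2$k, z = z, p = 2 * pnorm(-abs(z)))
}

#' K-means clustering of the correlation matrix
#'
#' Clusters cells by their correlation profile (matrix rows as feature
#' vectors); the number of clusters is chosen by mean silhouette score over
#' a grid. Degenerate matrices with (near-)identical rows are flagged as a
#' single cluster.
#'
#' @param mat Correlation matrix with zero diagonal.
#' @param k_grid Candidate cluster counts (default 2..6).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart K-means restarts per k.
#' @return List of class `state_clusters`: `k`, `assignments` (tibble:
#'   cell_id, cluster), `silhouette` (tibble: k, mean_silhouette),
#'   `degenerate`.
#' @export
cluster_states <- function(mat, k_grid = 2:6, seed = 1, nstart = 10) {
  n <- nrow(mat)
  if (n < max(k_grid) + 1) stopf("need more cells than max(k_grid).")
  ids <- rownames(mat) %||% cell_ids(n)
  if (all(stats::dist(mat) < 1e-12)) {
    warnf("identical correlation profiles; returning a single cluster.")
    return(structure(list(
      k = 1L, assignments = tibble::tibble(cell_id = ids, cluster = 1L),
      silhouette = tibble::tibble(k = integer(), mean_silhouette = numeric()),
      degenerate = TRUE), class = "state_clusters"))
  }
  dmat <- stats::dist(mat)
  set.seed(as.integer(seed))
  fits <- lapply(k_grid, function(k) kmeans(mat, centers = k, nstart = nstart,
                                            iter.max = 100))
  sil <- vapply(seq_along(k_grid), function(i) {
    mean(cluster::silhouette(fits[[i]]$cluster, dmat)[, "sil_width"])
  }, 0)
  best <- which.max(sil)
  structure(list(
    k = as.integer(k_grid[best]),
    assignments = tibble::tibble(cell_id = ids,
                                 cluster = as.integer(fits[[best]]$cluster)),
    silhouette = tibble::tibble(k = as.integer(k_grid), mean_silhouette = sil),
    degenerate = FALSE
  ), class = "state_clusters")
}

#' Cluster size and spatial compactness
#'
#' Spatial compactness of a cluster is the mean Euclidean distance of its
#' member cells to the cluster's spatial centroid (micrometer). Singleton
#' clusters get compactness 0 and are flagged.
#'
#' @param assignments Tibble with `cell_id`, `cluster` (or a
#'   `state_clusters` object).
#' @param centroids Tibble with `cell_id`, `x_um`, `y_um`.
#' @return Tibble: `cluster`, `size`, `compactness_um`, `singleton`.
#' @export
cluster_metrics <- function(assignments, centroids) {
  if (inherits(assignments, "state_clusters"))
    assignments <- assignments$assignments
  df <- dplyr::inner_join(assignments, centroids, by = "cell_id")
  if (nrow(df) != nrow(assignments))
    stopf("every assigned cell needs a centroid.")
  df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      size = dplyr::n(),
      compactness_um = mean(sqrt((.data$x_um - mean(.data$x_um))^2 +
                                   (.data$y_um - mean(.data$y_um))^2)),
      .groups = "drop") |>
    dplyr::mutate(singleton = .data$size == 1L)
}

#' Compare intra- and inter-cluster coupling between states
#'
#' Partitions matched cell pairs into intra-/inter-cluster by a shared
#' cluster assignment, and into positive/negative by the sign of the pair's
#' correlation in both states (sign-discordant pairs are excluded and
#' counted). Each partition cell is compared between states with a paired
#' t-test. Spearman's rho of correlation versus distance is reported per
#' state for the positive pairs.
#'
#' @param pairs_engaged,pairs_disengaged Pair tibbles (`cell_i`, `cell_j`,
#'   `r`) for the two states, covering the same pairs.
#' @param assignments Cluster assignment tibble (`cell_id`, `cluster`).
#' @param distances Optional [pair_distances()] tibble for the Spearman
#'   summaries.
#' @return List of class `coupling_comparison`: `tests` tibble (partition,
#'   direction, n_pairs, mean_engaged, mean_disengaged, t, df, p),
#'   `spearman` tibble, `n_discordant`.
#' @export
compare_cluster_coupling <- function(pairs_engaged, pairs_disengaged,
                                     assignments, distances = NULL) {
  if (inherits(assignments, "state_clusters"))
    assignments <- assignments$assignments
  key <- function(d) paste(d$cell_i, d$cell_j)
  m <- match(key(pairs_engaged), key(pairs_disengaged))
  if (anyNA(m)) stopf("states must cover the same cell pairs.")
  eng <- pairs_engaged$r
  dis <- pairs_disengaged$r[m]
  cl <- setNames(assignments$cluster, assignments$cell_id)
  intra <- cl[pairs_engaged$cell_i] == cl[pairs_engaged$cell_j]
  pos <- eng > 0 & dis > 0
  negp <- eng < 0 & dis < 0
  discordant <- sum(!pos & !negp)
  grid <- expand.grid(partition = c("intra", "inter"),
                      direction = c("positive", "negative"),
                      stringsAsFactors = FALSE)
  tests <- purrr::pmap_dfr(grid, function(partition, direction) {
    sel <- (if (partition == "intra") intra else !intra) &
      (if (direction == "positive") pos else negp)
    if (sum(sel) < 3) {
      warnf("partition %s/%s has < 3 pairs; skipped.", partition, direction)
      return(tibble::tibble(partition = partition, direction = direction,
                            n_pairs = sum(sel), mean_engaged = NA_real_,
                            mean_disengaged = NA_real_, t = NA_real_,
                            df = NA_real_, p = NA_real_))
    }
    d <- eng[sel] - dis[sel]
    if (sd(d) <= 1e-10 * max(abs(mean(d)), .Machine$double.eps)) {
      # degenerate paired test: identical matrices give t = NA; an exactly
      # constant nonzero shift is detected with certainty
      tt <- if (abs(mean(d)) < 1e-12) {
        list(statistic = NA_real_, parameter = sum(sel) - 1,
             p.value = NA_real_)
      } else {
        list(statistic = sign(mean(d)) * Inf, parameter = sum(sel) - 1,
             p.value = 0)
      }
    } else {
      tt <- t.test(eng[sel], dis[sel], paired = TRUE)
    }
    tibble::tibble(partition = partition, direction = direction,
                   n_pairs = sum(sel),
                   mean_engaged = mean(eng[sel]),
                   mean_disengaged = mean(dis[sel]),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  })
  spearman <- NULL
  if (!is.null(distances)) {
    dm <- match(key(pairs_engaged), key(distances))
    if (anyNA(dm)) stopf("distance table must cover the same pairs.")
    dd <- distances$distance_um[dm]
    spearman <- purrr::map_dfr(
      list(engaged = eng, disengaged = dis),
      function(v) {
        sel <- v > 0
        ct <- suppressWarnings(cor.test(v[sel], dd[sel], method = "spearman"))
        tibble::tibble(rho = unname(ct$estimate), p = ct$p.value,
                       n_pairs = sum(sel))
      }, .id = "state")
  }
  structure(list(tests = tests, spearman = spearman,
                 n_discordant = discordant),
            class = "coupling_comparison")
}

#' Build a per-state correlation network
#'
#' Orchestrates the state-conditioned network characterization for one
#' state: correlation matrix, per-cell extremes, sign-flip pair classes,
#' and pair distances merged into one pair table.
#'
#' @param traces Trace tibble or matrix.
#' @param state_mask Logical frame mask or frame indices for the state.
#' @param centroids Centroid tibble (`cell_id`, `x_um`, `y_um`).
#' @param n_perm Sign-flip iterations.
#' @param seed RNG seed.
#' @return List of class `correlation_network`: `matrix`, `pairs` (cell_i,
#'   cell_j, r, distance_um, class), `cell_extremes`, `thresholds`.
#' @export
correlation_network <- function(traces, state_mask, centroids,
                                n_perm = 10000, seed = 1) {
  mat <- state_correlation_matrix(traces, state_mask)
  cls <- classify_pair_correlations(traces, state_mask, n_perm, seed)
  dist_tbl <- pair_distances(centroids)
  pairs <- dplyr::inner_join(cls, dist_tbl, by = c("cell_i", "cell_j"))
  structure(list(matrix = mat, pairs = pairs,
                 cell_extremes = cell_max_correlations(mat),
                 thresholds = attr(cls, "thresholds")),
            class = "correlation_network")
}
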