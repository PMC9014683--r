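make_two_blobs <- function(n_per = 20, p = 4, sep = 6, seed = 5) {
  set.seed(seed)
  vals <- rbind(matrix(rnorm(n_per * p, 0), n_per, p),
                matrix(rnorm(n_per * p, sep), n_per, p))
  rownames(vals) <- sprintf("s%02d", seq_len(2 * n_per))
  colnames(vals) <- paste0("f", seq_len(p))
  expression_matrix(vals)
}

test_that("with alpha = 0 and uniform weights the fit is plain K-means", {
  X <- make_two_blobs()
  init <- X$values[c(1, 21), ]
  m <- fit_rskc(X, K = 2, alpha = 0, l1_bound = 2, init_centers = init,
                uniform_weights = TRUE)
  km <- kmeans(X$values, centers = init, algorithm = "Lloyd", iter.max = 100)
  wss <- sum(vapply(1:2, function(k)
    sum(sweep(X$values[m$assignments == k, , drop = FALSE], 2,
              m$centers[k, ])^2), numeric(1)))
  expect_lt(abs(wss - km$tot.withinss), 1e-9)
  expect_length(m$trimmed_weighted, 0L)
  expect_length(m$trimmed_unweighted, 0L)
})

test_that("two point-clusters are recovered exactly", {
  v <- rbind(matrix(0, 5, 3), matrix(10, 5, 3))
  rownames(v) <- paste0("s", 1:10)
  colnames(v) <- paste0("f", 1:3)
  m <- fit_rskc(expression_matrix(v), K = 2, alpha = 0, l1_bound = sqrt(3),
                n_init = 3, seed = 1)
  expect_setequal(as.vector(round(m$centers, 12)), c(0, 10))
  expect_equal(length(unique(m$assignments[1:5])), 1L)
  expect_equal(length(unique(m$assignments[6:10])), 1L)
})

test_that("a gross outlier is trimmed and the fit matches the clean-data fit", {
  X <- make_two_blobs()
  init <- X$values[c(1, 21), ]
  v3 <- X$values
  v3[7, ] <- 100
  X3 <- expression_matrix(v3, X$sample_ids, X$feature_ids)
  m3 <- fit_rskc(X3, K = 2, alpha = 1 / 40, l1_bound = 2, init_centers = init)
  expect_equal(m3$trimmed_weighted, 7L)
  expect_equal(length(m3$trimmed_weighted), ceiling(1 / 40 * 40))
  expect_equal(length(m3$trimmed_unweighted), ceiling(1 / 40 * 40))
  # oracle: the same fit on the 39 clean samples
  X39 <- expression_matrix(X$values[-7, ], X$sample_ids[-7], X$feature_ids)
  m39 <- fit_rskc(X39, K = 2, alpha = 0, l1_bound = 2, init_centers = init)
  expect_lt(max(abs(m3$centers - m39$centers)), 1e-6)
  # outlier has maximal score, scores cover trimmed samples too
  sc <- rskc_outlier_scores(m3, X3)
  expect_length(sc, 40L)
  expect_equal(which.max(sc), 7L)
})

test_that("outlier scores are weighted distances to the assigned center", {
  X <- make_two_blobs()
  m <- fit_rskc(X, K = 2, alpha = 0.1, l1_bound = 2, n_init = 3, seed = 2)
  # a sample placed exactly on a center scores 0
  Xc <- expression_matrix(m$centers[1, , drop = FALSE], "on_center",
                          X$feature_ids)
  expect_equal(unname(rskc_outlier_scores(m, Xc)), 0)
  # zero-weight features cannot change any score
  zw <- which(m$feature_weights == 0)
  if (length(zw)) {
    v2 <- X$values
    v2[, zw] <- v2[, zw] * 2
    X2 <- expression_matrix(v2, X$sample_ids, X$feature_ids)
    expect_equal(rskc_outlier_scores(m, X2), rskc_outlier_scores(m, X))
  }
})

test_that("feature weights respect the L1/L2 constraints and sparsify", {
  set.seed(9)
  # informative features 1-2 separate the blobs; 8 noise features
  v <- cbind(rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2)),
             matrix(rnorm(40 * 8), 40, 8))
  rownames(v) <- sprintf("s%02d", 1:40)
  colnames(v) <- paste0("f", 1:10)
  X <- expression_matrix(v)
  m <- fit_rskc(X, K = 2, alpha = 0.05, l1_bound = 1.2, n_init = 3, seed = 3)
  expect_lte(sum(m$feature_weights^2), 1 + 1e-9)
  expect_lte(sum(m$feature_weights), 1.2 + 1e-9)
  expect_true(all(m$feature_weights >= 0))
  expect_true(all(c("f1", "f2") %in% m$selected_features))
  expect_lt(length(m$selected_features), 10L)
  # objective monitor: strictly monotone when nothing is trimmed; with
  # trimming the re-trimmed case subset changes between iterations, so only
  # near-monotonicity (no dip beyond 1% relative) is guaranteed
  m0 <- fit_rskc(X, K = 2, alpha = 0, l1_bound = 1.2, n_init = 3, seed = 3)
  expect_true(all(diff(m0$objective_trace) >= -1e-8 * max(1, m0$objective)))
  expect_true(all(diff(m$objective_trace) >= -0.01 * max(1, m$objective)))
})

test_that("sample order does not affect the fitted partition", {
  X <- make_two_blobs()
  m1 <- fit_rskc(X, K = 2, alpha = 0.1, l1_bound = 2, n_init = 4, seed = 7)
  perm <- sample(40)
  Xp <- expression_matrix(X$values[perm, ], X$sample_ids[perm], X$feature_ids)
  m2 <- fit_rskc(Xp, K = 2, alpha = 0.1, l1_bound = 2, n_init = 4, seed = 7)
  # same partition of sample IDs (cluster labels may swap)
  part1 <- split(X$sample_ids, m1$assignments)
  part2 <- split(Xp$sample_ids, m2$assignments)
  expect_true(setequal(lapply(part1, sort), lapply(part2, sort)))
  expect_setequal(X$sample_ids[m1$trimmed_weighted],
                  Xp$sample_ids[m2$trimmed_weighted])
})

test_that("cluster-to-class mapping minimizes misclassification", {
  y <- class_labels(c(0, 0, 1, 1), paste0("s", 1:4))
  expect_equal(map_clusters_to_labels(c(1L, 1L, 2L, 2L), y), c(0L, 0L, 1L, 1L))
  expect_equal(map_clusters_to_labels(c(2L, 2L, 1L, 1L), y), c(0L, 0L, 1L, 1L))
  # 2 misclassifications under either mapping; identity tie-break
  expect_equal(sum(map_clusters_to_labels(c(1L, 2L, 1L, 2L), y) != y$y), 2L)
  expect_equal(map_clusters_to_labels(c(1L, 2L, 1L, 2L), y), c(0L, 1L, 0L, 1L))
  expect_error(map_clusters_to_labels(c(1L, 3L, 1L, 2L), y), "K = 2")
})

test_that("degenerate configurations error cleanly", {
  X <- make_two_blobs(n_per = 3)
  expect_error(fit_rskc(X, K = 2, alpha = 0.45, l1_bound = 0.5), "l1_bound")
  expect_error(fit_rskc(expression_matrix(matrix(rnorm(8), 2, 4)), K = 2,
                        alpha = 0.4), "too few samples")
})
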