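# Robust sparse K-means: trimmed K-means in a weighted feature space with
# lasso-type (L1/L2-constrained) nonnegative feature weights.  Alternates
# (a) trimmed Lloyd steps under the current weights, (b) a second trim in
# unweighted distance space, and (c) a feature-weight update maximizing the
# weighted between-cluster sum of squares.

# squared distances of rows of M to each center (K x p), under feature
# weights fw; returns n x K matrix
weighted_dist2 <- function(M, centers, fw) {
  n <- nrow(M); K <- nrow(centers)
  D <- matrix(0, n, K)
  for (k in seq_len(K)) {
    diff <- sweep(M, 2L, centers[k, ])
    D[, k] <- drop(diff^2 %*% fw)
  }
  D
}

# Witten-Tibshirani style weight update: w = S(b, delta)/||.||_2 with
# ||w||_1 <= s, delta found by bisection.  b is the nonnegative vector of
# per-feature between-cluster sums of squares.
update_feature_weights <- function(b, s) {
  b <- pmax(b, 0)
  if (all(b <= 0)) return(rep(1 / sqrt(length(b)), length(b)))
  norm2 <- function(v) sqrt(sum(v^2))
  w <- b / norm2(b)
  if (sum(w) <= s + 1e-10) return(w)
  lo <- 0; hi <- max(b)
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    v <- pmax(b - mid, 0)
    if (sum(v) == 0) { hi <- mid; next }
    w <- v / norm2(v)
    if (sum(w) > s) lo <- mid else hi <- mid
  }
  v <- pmax(b - hi, 0)
  if (sum(v) == 0) v <- pmax(b - lo, 0)
  v / norm2(v)
}

# per-feature between-cluster sum of squares on the case subset `use`
between_ss <- function(M, cl, use, K) {
  Mu <- M[use, , drop = FALSE]
  clu <- cl[use]
  gm <- colMeans(Mu)
  b <- numeric(ncol(M))
  for (k in seq_len(K)) {
    idx <- clu == k
    if (any(idx)) {
      ck <- colMeans(Mu[idx, , drop = FALSE])
      b <- b + sum(idx) * (ck - gm)^2
    }
  }
  b
}

#' Fit robust sparse K-means
#'
#' Alternating optimization: trimmed Lloyd iterations in the weighted
#' feature space (trimming the `ceiling(alpha * n)` cases with largest
#' weighted distance, set `O_W`), a second trim in unweighted distance
#' space (set `O_E`) with center updates on untrimmed cases, and a feature
#' weight update maximizing the weighted between-cluster sum of squares
#' subject to `||w||_2 <= 1`, `||w||_1 <= l1_bound` (soft threshold with
#' bisection).  The best of `n_init` seeded restarts is kept; restarts
#' initialize centers from `K` distinct samples drawn by sorted sample ID,
#' so results do not depend on row order.
#'
#' @param X An [expression_matrix()].
#' @param K Number of clusters (the ensemble uses 2).
#' @param alpha Trimming proportion in `[0, 0.5)`.
#' @param l1_bound L1 bound `s` on the feature weights, in `[1, sqrt(p)]`.
#' @param n_init Number of random restarts.
#' @param max_iter Maximum alternating iterations per restart.
#' @param seed Integer seed for restarts.
#' @param init_centers Optional K x p matrix of initial centers (overrides
#'   the seeded initialization; used by oracle tests).
#' @param uniform_weights If `TRUE`, feature weights are held uniform
#'   (`1/sqrt(p)`), reducing the fit to trimmed K-means.
#' @return An object of class `rskc_model` with `centers`,
#'   `feature_weights`, `assignments`, `trimmed_weighted` (`O_W`),
#'   `trimmed_unweighted` (`O_E`), `selected_features`, `objective`,
#'   `objective_trace` and the configuration used.
#' @export
fit_rskc <- function(X, K = 2, alpha = 0.1, l1_bound = NULL, n_init = 10,
                     max_iter = 50, seed = 1, init_centers = NULL,
                     uniform_weights = FALSE) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  M <- X$values
  n <- nrow(M); p <- ncol(M)
  if (is.null(l1_bound)) l1_bound <- sqrt(p)
  stopifnot(alpha >= 0, alpha < 0.5, l1_bound >= 1, l1_bound <= sqrt(p) + 1e-9)
  if (n <= K / (1 - alpha)) stop("too few samples for K = ", K, ", alpha = ", alpha)
  ord_ids <- order(X$sample_ids)  # ID-based, order-independent initialization
  best <- NULL
  failures <- 0L
  if (!is.null(init_centers)) {
    stopifnot(nrow(init_centers) == K, ncol(init_centers) == p)
    best <- rskc_core(M, K, alpha, l1_bound, max_iter, init_centers,
                      uniform_weights)
    if (is.null(best)) stop("empty cluster after trimming with the given initial centers")
  } else {
    for (r in seq_len(n_init)) {
      init_idx <- with_seed(child_seed(seed, paste0("rskc", r)),
                            ord_ids[sample.int(n, K)])
      res <- rskc_core(M, K, alpha, l1_bound, max_iter,
                       M[init_idx, , drop = FALSE], uniform_weights)
      if (is.null(res)) { failures <- failures + 1L; next }
      if (is.null(best) || res$objective > best$objective) best <- res
    }
    if (is.null(best))
      stop("empty cluster after trimming in all ", n_init, " restarts")
  }
  structure(c(best,
              list(selected_features = X$feature_ids[best$feature_weights > 1e-10],
                   feature_ids = X$feature_ids,
                   sample_ids = X$sample_ids,
                   config = list(K = K, alpha = alpha, l1_bound = l1_bound,
                                 n_init = n_init, max_iter = max_iter,
                                 seed = seed,
                                 uniform_weights = uniform_weights))),
            class = "rskc_model")
}

rskc_core <- function(M, K, alpha, s, max_iter, centers, uniform_weights) {
  n <- nrow(M); p <- ncol(M)
  n_trim <- ceiling(alpha * n)
  fw <- rep(1 / sqrt(p), p)
  obj_trace <- numeric(0)
  cl <- rep(1L, n); ow <- integer(0); oe <- integer(0); obj <- NA_real_
  for (iter in seq_len(max_iter)) {
    for (ll in 1:25) {
      D <- weighted_dist2(M, centers, fw)
      cl_new <- max.col(-D, ties.method = "first")
      dmin <- D[cbind(seq_len(n), cl_new)]
      ow <- if (n_trim > 0) order(dmin, decreasing = TRUE)[seq_len(n_trim)] else integer(0)
      keep <- setdiff(seq_len(n), ow)
      if (length(unique(cl_new[keep])) < K) return(NULL)
      for (k in seq_len(K)) {
        idx <- keep[cl_new[keep] == k]
        centers[k, ] <- colMeans(M[idx, , drop = FALSE])
      }
      if (identical(cl_new, cl) && ll > 1) { cl <- cl_new; break }
      cl <- cl_new
    }
    Du <- weighted_dist2(M, centers, rep(1, p))
    du <- Du[cbind(seq_len(n), cl)]
    oe <- if (n_trim > 0) order(du, decreasing = TRUE)[seq_len(n_trim)] else integer(0)
    keep_e <- setdiff(seq_len(n), oe)
    if (length(unique(cl[keep_e])) < K) return(NULL)
    for (k in seq_len(K)) {
      idx <- keep_e[cl[keep_e] == k]
      centers[k, ] <- colMeans(M[idx, , drop = FALSE])
    }
    if (!uniform_weights) {
      b <- between_ss(M, cl, setdiff(seq_len(n), union(ow, oe)), K)
      fw <- update_feature_weights(b, s)
    }
    obj <- sum(fw * between_ss(M, cl, setdiff(seq_len(n), union(ow, oe)), K))
    obj_trace <- c(obj_trace, obj)
    if (iter > 1 && abs(obj - obj_trace[iter - 1]) <=
          1e-8 * max(1, abs(obj_trace[iter - 1]))) break
  }
  list(centers = centers, feature_weights = fw, assignments = cl,
       trimmed_weighted = sort(ow), trimmed_unweighted = sort(oe),
       objective = obj, objective_trace = obj_trace)
}

#' @export
print.rskc_model <- function(x, ...) {
  cat("RSKC model: K =", x$config$K, ", alpha =", x$config$alpha,
      ", l1_bound =", round(x$config$l1_bound, 3), "\n")
  cat(" ", length(x$selected_features), "features with positive weight;",
      length(x$trimmed_weighted), "cases trimmed\n")
  invisible(x)
}

#' Per-sample outlyingness scores from an RSKC fit
#'
#' The weighted squared distance to the nearest cluster center - the
#' quantity RSKC trims on - computed for all samples including trimmed
#' ones.
#'
#' @param model A fitted `rskc_model`.
#' @param X The [expression_matrix()] the model was fitted to (or new data
#'   with the same features).
#' @return Numeric vector of scores (larger = more outlying).
#' @export
rskc_outlier_scores <- function(model, X) {
  stopifnot(inherits(model, "rskc_model"), inherits(X, "ExpressionMatrix"))
  if (!identical(X$feature_ids, model$feature_ids))
    stop("feature IDs do not match the training features")
  D <- weighted_dist2(X$values, model$centers, model$feature_weights)
  D[cbind(seq_len(nrow(D)), max.col(-D, ties.method = "first"))]
}

#' Map K = 2 cluster assignments to class labels
#'
#' Chooses the cluster-to-class mapping that minimizes misclassifications
#' against the observed labels; ties go to the identity mapping (cluster k
#' -> class k - 1).
#'
#' @param assignments Integer vector of cluster assignments in `{1, 2}`.
#' @param labels A [class_labels()] (or 0/1 vector).
#' @return Integer vector of predicted labels in `{0, 1}`.
#' @export
map_clusters_to_labels <- function(assignments, labels) {
  y <- if (inherits(labels, "ClassLabels")) labels$y else as.integer(labels)
  K <- length(unique(assignments))
  if (any(!assignments %in% c(1L, 2L)))
    stop("cluster-to-label mapping requires K = 2 assignments in {1, 2}")
  identity_lab <- assignments - 1L
  swapped_lab <- 2L - assignments
  err_id <- sum(identity_lab != y)
  err_sw <- sum(swapped_lab != y)
  if (err_sw < err_id) swapped_lab else identity_lab
}
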