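# Orchestration of the main ensemble run: per-method hyperparameter
# optimization, the three independent fits, rank-product consensus over the
# per-sample outlyingness rankings, and feature intersection.

#' Default ensemble configuration
#'
#' Grids and fixed settings for the three methods.  Grid defaults are kept
#' deliberately small; every entry can be overridden.
#'
#' @param sprm List: `n_components_grid`, `eta_grid`, `weight_function`,
#'   `tuning_constant`.
#' @param rskc List: `alpha_grid`, `l1_grid` (`NULL` = data-driven grid),
#'   `n_init`, `n_permutations` for the gap statistic.
#' @param enetlts List: `h_fraction`, `alpha_grid`, `lambda_grid`,
#'   `n_starts`, `n_keep`.
#' @param q_threshold Influential-call threshold on the consensus q-value.
#' @param q_method FDR method, `"BH"` or `"storey"`.
#' @return A list of class `rosie_control`.
#' @export
rosie_control <- function(sprm = list(), rskc = list(), enetlts = list(),
                          q_threshold = 0.05, q_method = "BH") {
  ctl <- list(
    sprm = utils::modifyList(list(n_components_grid = c(1L, 2L),
                                  eta_grid = c(0.3, 0.5, 0.7),
                                  weight_function = "fair",
                                  tuning_constant = 4), sprm),
    rskc = utils::modifyList(list(alpha_grid = c(0.05, 0.1, 0.15),
                                  l1_grid = NULL, n_init = 5L,
                                  n_permutations = 25L), rskc),
    enetlts = utils::modifyList(list(h_fraction = 0.75,
                                     alpha_grid = 0.5,
                                     lambda_grid = c(0.01, 0.025, 0.05),
                                     n_starts = 20L, n_keep = 3L), enetlts),
    q_threshold = q_threshold, q_method = q_method)
  class(ctl) <- "rosie_control"
  ctl
}

# permutation gap statistic for the RSKC L1 bound (Witten-Tibshirani):
# gap(s) = log O(s; data) - mean log O(s; column-permuted data)
rskc_gap_l1 <- function(X, K, alpha, l1_grid, n_init, n_perm, seed) {
  p <- n_features(X)
  fit_obj <- function(Xm, s, sd)
    fit_rskc(Xm, K = K, alpha = alpha, l1_bound = s, n_init = n_init,
             seed = sd)$objective
  log_real <- vapply(l1_grid, function(s)
    log(max(fit_obj(X, s, child_seed(seed, paste0("real", s))), 1e-12)),
    numeric(1L))
  log_perm <- matrix(0, n_perm, length(l1_grid))
  for (b in seq_len(n_perm)) {
    Xp <- X
    Xp$values <- with_seed(child_seed(seed, paste0("perm", b)),
                           apply(X$values, 2L, sample))
    rownames(Xp$values) <- X$sample_ids
    for (j in seq_along(l1_grid))
      log_perm[b, j] <- log(max(fit_obj(Xp, l1_grid[j],
                                        child_seed(seed, paste0("pf", b, "_", j))),
                                1e-12))
  }
  gap <- log_real - colMeans(log_perm)
  l1_grid[which.max(gap)]
}

#' Optimize hyperparameters for one ensemble member
#'
#' SPRM: grid over `n_components x eta`, minimizing stratified 5-fold
#' cross-validated misclassification (ties resolved toward the sparser
#' model: larger eta, then fewer components).  RSKC: `l1_bound` by the
#' permutation gap statistic; `alpha` by maximal agreement of the mapped
#' cluster labels with reference label vectors (the other methods'
#' predictions) when supplied, otherwise with the observed labels.
#' enetLTS: delegates to its internal cross-validation over
#' `alpha_grid x lambda_grid`.  Deterministic given `seed`.
#'
#' @param X An [expression_matrix()].
#' @param labels A [class_labels()].
#' @param method_id One of `"sprm"`, `"rskc"`, `"enetlts"`.
#' @param control A [rosie_control()].
#' @param seed Integer seed.
#' @param reference_labels Optional list of 0/1 vectors (RSKC alpha tuning).
#' @return Named list of chosen hyperparameters.
#' @export
optimize_hyperparameters <- function(X, labels, method_id, control = rosie_control(),
                                     seed = 1, reference_labels = NULL) {
  method_id <- match.arg(method_id, c("sprm", "rskc", "enetlts"))
  n <- n_samples(X)
  if (method_id == "sprm") {
    g <- expand.grid(ncomp = control$sprm$n_components_grid,
                     eta = control$sprm$eta_grid)
    if (!nrow(g)) stop("empty SPRM grid")
    folds <- stratified_folds(labels$y, 5L, child_seed(seed, "sprmcv"))
    err <- rep(NA_real_, nrow(g))
    for (i in seq_len(nrow(g))) {
      tot <- 0; ok <- TRUE
      for (f in sort(unique(folds))) {
        tr <- which(folds != f); te <- which(folds == f)
        if (length(unique(labels$y[tr])) < 2L) next
        m <- tryCatch(quiet_nonconvergence(
          fit_sprm(subset_samples(X, tr),
                   class_labels(labels$y[tr], X$sample_ids[tr]),
                   n_components = g$ncomp[i], eta = g$eta[i],
                   weight_function = control$sprm$weight_function,
                   tuning_constant = control$sprm$tuning_constant)),
          error = function(e) NULL)
        if (is.null(m)) { ok <- FALSE; break }
        pr <- predict_sprm(m, subset_samples(X, te))
        tot <- tot + sum(pr != labels$y[te])
      }
      if (ok) err[i] <- tot
    }
    if (all(is.na(err))) stop("all SPRM grid points produced degenerate fits")
    ord <- order(err, -g$eta, g$ncomp)  # ties -> sparser
    list(n_components = g$ncomp[ord[1L]], eta = g$eta[ord[1L]])
  } else if (method_id == "rskc") {
    p <- n_features(X)
    l1_grid <- control$rskc$l1_grid %||%
      unique(pmax(1.01, pmin(sqrt(p), c(2, 4, sqrt(p) / 2, sqrt(p)))))
    alpha_grid <- control$rskc$alpha_grid
    if (!length(l1_grid) || !length(alpha_grid)) stop("empty RSKC grid")
    a0 <- alpha_grid[ceiling(length(alpha_grid) / 2)]
    s_best <- if (length(l1_grid) == 1L) l1_grid else
      rskc_gap_l1(X, K = 2L, alpha = a0, l1_grid = l1_grid,
                  n_init = control$rskc$n_init,
                  n_perm = control$rskc$n_permutations,
                  seed = child_seed(seed, "gap"))
    refs <- reference_labels %||% list(labels$y)
    agree <- vapply(alpha_grid, function(a) {
      m <- tryCatch(fit_rskc(X, K = 2L, alpha = a, l1_bound = s_best,
                             n_init = control$rskc$n_init,
                             seed = child_seed(seed, paste0("alpha", a))),
                    error = function(e) NULL)
      if (is.null(m)) return(-Inf)
      lab <- map_clusters_to_labels(m$assignments, labels)
      mean(vapply(refs, function(r) mean(lab == r), numeric(1L)))
    }, numeric(1L))
    if (all(!is.finite(agree))) stop("all RSKC grid points produced degenerate fits")
    list(alpha = alpha_grid[which.max(agree)], l1_bound = s_best)
  } else {
    fit <- fit_enetlts(X, labels, h_fraction = control$enetlts$h_fraction,
                       alpha_mix = control$enetlts$alpha_grid,
                       lambda = control$enetlts$lambda_grid,
                       n_starts = control$enetlts$n_starts,
                       n_keep = control$enetlts$n_keep,
                       seed = child_seed(seed, "enetcv"))
    list(alpha_mix = fit$alpha_used, lambda = fit$lambda_used)
  }
}

#' Run the full robust sparse ensemble
#'
#' Fits SPRM-DA, RSKC and enetLTS independently (optionally optimizing each
#' method's hyperparameters first), ranks each method's per-sample
#' outlyingness scores with average tie handling, fuses the three rankings
#' by the rank product with exact discrete-uniform p-values and FDR
#' q-values, calls influential samples at `q < q_threshold`, and intersects
#' the three selected feature sets.  Any method failure aborts the run
#' naming the method: the consensus is defined for exactly three rankings.
#'
#' @param X A preprocessed [expression_matrix()].
#' @param labels A [class_labels()] paired with `X`.
#' @param control A [rosie_control()].
#' @param seed Integer seed governing every stochastic step.
#' @param optimize Logical; run per-method hyperparameter optimization
#'   (otherwise the first grid entry / supplied `hyperparameters` are used).
#' @param hyperparameters Optional list with entries `sprm`, `rskc`,
#'   `enetlts` of fixed hyperparameters (as returned by
#'   [optimize_hyperparameters()]); used by the bootstrap validity check.
#' @return An object of class `rosie_result`: `per_method` (named list of
#'   method results: selected features, outlier scores, predicted labels,
#'   misclassified IDs, chosen hyperparameters), `consensus` (a
#'   `rosie_consensus`), `common_features`, `commonly_misclassified`,
#'   `hyperparameters`.
#' @export
run_rosie <- function(X, labels, control = rosie_control(), seed = 1,
                      optimize = TRUE, hyperparameters = NULL) {
  check_paired(X, labels)
  hp <- hyperparameters %||% list()

  fit_method <- function(id, expr) {
    tryCatch(expr, error = function(e)
      stop("ensemble member '", id, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # SPRM
  hp$sprm <- hp$sprm %||% (if (optimize)
    optimize_hyperparameters(X, labels, "sprm", control, seed)
    else list(n_components = control$sprm$n_components_grid[1L],
              eta = control$sprm$eta_grid[1L]))
  sprm_fit <- fit_method("sprm",
    fit_sprm(X, labels, n_components = hp$sprm$n_components,
             eta = hp$sprm$eta,
             weight_function = control$sprm$weight_function,
             tuning_constant = control$sprm$tuning_constant))
  sprm_pred <- predict_sprm(sprm_fit, X)

  # enetLTS
  hp$enetlts <- hp$enetlts %||% (if (optimize)
    optimize_hyperparameters(X, labels, "enetlts", control, seed)
    else list(alpha_mix = control$enetlts$alpha_grid[1L],
              lambda = control$enetlts$lambda_grid[1L]))
  enet_fit <- fit_method("enetlts",
    fit_enetlts(X, labels, h_fraction = control$enetlts$h_fraction,
                alpha_mix = hp$enetlts$alpha_mix, lambda = hp$enetlts$lambda,
                n_starts = control$enetlts$n_starts,
                n_keep = control$enetlts$n_keep,
                seed = child_seed(seed, "enetfit")))
  enet_pred <- predict_enetlts(enet_fit, X)

  # RSKC (alpha tuned against the supervised methods' predictions)
  hp$rskc <- hp$rskc %||% (if (optimize)
    optimize_hyperparameters(X, labels, "rskc", control, seed,
                             reference_labels = list(sprm_pred, enet_pred))
    else list(alpha = control$rskc$alpha_grid[1L], l1_bound = NULL))
  rskc_fit <- fit_method("rskc",
    fit_rskc(X, K = 2L, alpha = hp$rskc$alpha, l1_bound = hp$rskc$l1_bound,
             n_init = control$rskc$n_init, seed = child_seed(seed, "rskcfit")))
  rskc_pred <- map_clusters_to_labels(rskc_fit$assignments, labels)

  scores <- list(sprm = unname(sprm_outlier_scores(sprm_fit)),
                 rskc = unname(rskc_outlier_scores(rskc_fit, X)),
                 enetlts = unname(enetlts_outlier_scores(enet_fit)))
  consensus <- consensus_outliers(scores, X$sample_ids,
                                  q_threshold = control$q_threshold,
                                  q_method = control$q_method)

  mk_result <- function(id, fit, pred, chosen) {
    list(method_id = id,
         selected_features = fit$selected_features,
         outlier_scores = scores[[id]],
         predicted_labels = pred,
         misclassified = X$sample_ids[pred != labels$y],
         hyperparameters_chosen = chosen)
  }
  per_method <- list(
    sprm = mk_result("sprm", sprm_fit, sprm_pred, hp$sprm),
    rskc = mk_result("rskc", rskc_fit, rskc_pred, hp$rskc),
    enetlts = mk_result("enetlts", enet_fit, enet_pred, hp$enetlts))

  common_features <- Reduce(intersect,
                            lapply(per_method, `[[`, "selected_features"))
  commonly_misclassified <- Reduce(intersect,
                                   lapply(per_method, `[[`, "misclassified"))
  structure(list(per_method = per_method,
                 consensus = consensus,
                 common_features = common_features,
                 commonly_misclassified = commonly_misclassified,
                 hyperparameters = hp,
                 fits = list(sprm = sprm_fit, rskc = rskc_fit,
                             enetlts = enet_fit),
                 sample_ids = X$sample_ids),
            class = "rosie_result")
}

#' @export
print.rosie_result <- function(x, ...) {
  cat("Robust sparse ensemble result\n")
  for (m in x$per_method)
    cat(sprintf("  %-8s %5d selected features, %3d misclassified\n",
                m$method_id, length(m$selected_features),
                length(m$misclassified)))
  cat("  common features:", length(x$common_features),
      "| commonly misclassified:", length(x$commonly_misclassified), "\n")
  cat("  influential samples (q <", x$consensus$q_threshold, "):",
      length(x$consensus$influential), "\n")
  invisible(x)
}

#' Write ensemble outputs to a directory
#'
#' Writes the consensus table (TSV), the commonly selected features (TSV)
#' and per-method summaries (JSON if jsonlite is available, plain text
#' otherwise).
#'
#' @param result A `rosie_result`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_rosie_result <- function(result, dir) {
  stopifnot(inherits(result, "rosie_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_consensus_tsv(result$consensus, file.path(dir, "consensus.tsv"))
  utils::write.table(data.frame(feature_id = result$common_features),
                     file.path(dir, "common_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- lapply(result$per_method, function(m)
    list(n_selected = length(m$selected_features),
         n_misclassified = length(m$misclassified),
         hyperparameters = m$hyperparameters_chosen))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(meta, file.path(dir, "methods.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::capture.output(utils::str(meta),
                          file = file.path(dir, "methods.txt"))
  }
  invisible(dir)
}
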