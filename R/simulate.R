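# Contamination simulation study: balanced two-class Gaussian data with a
# sparse mean-shift signal, three planted-outlier scenarios (5% / 15% label
# switching, 3-SD expression shifts), and ROC/AUC evaluation of outlier
# rankings.

#' Generate a clean two-class dataset
#'
#' Balanced classes (`n/2` each).  The first `n_informative` features carry
#' a mean shift of `effect_size` in class 1 on unit-variance Gaussian
#' noise; the remaining features are pure standard Gaussian noise.
#'
#' @param n Number of samples (even).
#' @param p Number of features.
#' @param n_informative Number of informative features.
#' @param effect_size Class-1 mean shift on informative features.
#' @param seed Integer seed.
#' @return List with `X` (an [expression_matrix()]), `labels` (a
#'   [class_labels()] of the true labels) and `informative` (feature IDs
#'   carrying signal).
#' @export
generate_base_dataset <- function(n = 200, p = 3200, n_informative = 160,
                                  effect_size = 1.0, seed = 1) {
  stopifnot(n %% 2 == 0, n_informative <= p)
  y <- rep(c(0L, 1L), each = n / 2)
  vals <- with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  if (n_informative > 0)
    vals[y == 1L, seq_len(n_informative)] <-
      vals[y == 1L, seq_len(n_informative)] + effect_size
  ids <- sprintf("S%03d", seq_len(n))
  feats <- sprintf("F%04d", seq_len(p))
  X <- expression_matrix(vals, sample_ids = ids, feature_ids = feats)
  list(X = X, labels = class_labels(y, ids),
       informative = feats[seq_len(n_informative)])
}

#' Corrupt labels by random switching
#'
#' `floor(fraction * n)` samples are drawn without replacement (seeded) and
#' their labels flipped; exactly those samples are flagged as true
#' outliers.  The expression matrix is untouched.
#'
#' @param labels A [class_labels()] of true labels.
#' @param fraction Fraction of samples to switch, in `(0, 0.5)`.
#' @param seed Integer seed.
#' @return List with `labels` (a [class_labels()] of observed labels) and
#'   `outlier_truth` (logical vector).
#' @export
apply_label_switch <- function(labels, fraction, seed = 1) {
  stopifnot(inherits(labels, "ClassLabels"), fraction > 0, fraction < 0.5)
  n <- length(labels$y)
  n_switch <- floor(fraction * n)
  idx <- with_seed(seed, sample.int(n, n_switch))
  y_obs <- labels$y
  y_obs[idx] <- 1L - y_obs[idx]
  truth <- rep(FALSE, n)
  truth[idx] <- TRUE
  list(labels = class_labels(y_obs, labels$sample_ids,
                             labels$positive_class_name),
       outlier_truth = truth)
}

#' Corrupt expression values by additive SD shifts
#'
#' `floor(feature_fraction * p)` features are chosen (seeded) and their
#' per-feature standard deviation computed on the uncorrupted matrix; then
#' `floor(sample_fraction * n)` samples are chosen and, for every chosen
#' (sample, feature) cell, `multiplier` times that feature's SD is added.
#' The chosen samples are the true outliers; labels are untouched.
#'
#' @param X An [expression_matrix()].
#' @param feature_fraction Fraction of features to shift (default 0.15).
#' @param sample_fraction Fraction of samples to corrupt (default 0.05).
#' @param multiplier SD multiplier (default 3).
#' @param seed Integer seed.
#' @return List with `X` (corrupted matrix), `outlier_truth` (logical),
#'   `shifted_features` (feature IDs).
#' @export
apply_expression_shift <- function(X, feature_fraction = 0.15,
                                   sample_fraction = 0.05, multiplier = 3,
                                   seed = 1) {
  stopifnot(inherits(X, "ExpressionMatrix"),
            feature_fraction > 0, feature_fraction < 1,
            sample_fraction > 0, sample_fraction < 1, multiplier >= 0)
  n <- n_samples(X); p <- n_features(X)
  n_feat <- floor(feature_fraction * p)
  n_samp <- floor(sample_fraction * n)
  picks <- with_seed(seed, list(features = sample.int(p, n_feat),
                                samples = sample.int(n, n_samp)))
  sds <- apply(X$values[, picks$features, drop = FALSE], 2L, stats::sd)
  vals <- X$values
  vals[picks$samples, picks$features] <-
    vals[picks$samples, picks$features] +
    multiplier * matrix(sds, n_samp, n_feat, byrow = TRUE)
  truth <- rep(FALSE, n)
  truth[picks$samples] <- TRUE
  list(X = expression_matrix(vals, sample_ids = X$sample_ids,
                             feature_ids = X$feature_ids,
                             log_scale = X$log_scale),
       outlier_truth = truth,
       shifted_features = X$feature_ids[picks$features])
}

#' Generate one contamination scenario
#'
#' Scenarios: `"label_switch_5"` / `"label_switch_15"` (clean matrix,
#' 5% / 15% of labels flipped) and `"expression_shift"` (clean labels, 5%
#' of samples shifted by 3 SD on 15% of features).
#'
#' @param scenario Scenario name.
#' @param n,p,n_informative,effect_size Passed to
#'   [generate_base_dataset()].
#' @param seed Integer seed.
#' @return List with `X`, `y_true`, `y_observed`, `outlier_truth`,
#'   `scenario`, `seed`.
#' @export
simulate_scenario <- function(scenario = c("label_switch_5", "label_switch_15",
                                           "expression_shift"),
                              n = 200, p = 3200, n_informative = NULL,
                              effect_size = 1.0, seed = 1) {
  scenario <- match.arg(scenario)
  n_informative <- n_informative %||% max(1L, round(0.05 * p))
  base <- generate_base_dataset(n, p, n_informative, effect_size,
                                seed = child_seed(seed, "base"))
  if (scenario == "expression_shift") {
    cor <- apply_expression_shift(base$X, seed = child_seed(seed, "shift"))
    list(X = cor$X, y_true = base$labels, y_observed = base$labels,
         outlier_truth = cor$outlier_truth, scenario = scenario, seed = seed)
  } else {
    frac <- if (scenario == "label_switch_5") 0.05 else 0.15
    cor <- apply_label_switch(base$labels, frac, seed = child_seed(seed, "switch"))
    list(X = base$X, y_true = base$labels, y_observed = cor$labels,
         outlier_truth = cor$outlier_truth, scenario = scenario, seed = seed)
  }
}

#' ROC curve and AUC of an outlier ranking against known truth
#'
#' Thresholds sweep the distinct score values (ties grouped); the AUC is
#' the trapezoidal area, equal to the probability that a true outlier
#' outscores a non-outlier with ties counting one half.
#'
#' @param scores Numeric outlyingness scores (larger = more outlying).
#' @param outlier_truth Logical vector of ground-truth outlier flags (at
#'   least one `TRUE` and one `FALSE`).
#' @return An object of class `roc_curve`: `thresholds`, `fpr`, `tpr`,
#'   `auc`.
#' @export
evaluate_roc <- function(scores, outlier_truth) {
  truth <- as.logical(outlier_truth)
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  if (!any(truth) || all(truth))
    stop("outlier truth is degenerate: need at least one TRUE and one FALSE")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  grp_last <- which(diff(s) != 0)
  grp_last <- c(grp_last, length(s))        # last index of each tie group
  tp <- cumsum(t)[grp_last]
  fp <- cumsum(!t)[grp_last]
  tpr <- c(0, tp / sum(truth))
  fpr <- c(0, fp / sum(!truth))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[grp_last]), fpr = fpr, tpr = tpr,
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve over", length(x$thresholds), "thresholds; AUC =",
      round(x$auc, 4), "\n")
  invisible(x)
}

#' Fixed ensemble settings for the simulation study
#'
#' The study runs all replicates under one fixed configuration (no
#' per-replicate hyperparameter optimization) so AUCs are comparable
#' across seeds and scenarios: SPRM with 1 component and eta 0.3, RSKC
#' with alpha 0.1 and a dense L1 bound, enetLTS with h = 0.75 n, elastic
#' net mixing 0.5 and lambda 0.02.
#'
#' @return A [rosie_control()].
#' @export
simulation_control <- function() {
  rosie_control(
    sprm = list(n_components_grid = 1L, eta_grid = 0.3),
    rskc = list(alpha_grid = 0.1, l1_grid = NULL, n_init = 4L),
    enetlts = list(alpha_grid = 0.5, lambda_grid = 0.02,
                   n_starts = 10L, n_keep = 3L))
}

#' Run the contamination simulation study
#'
#' For each scenario and seed: generate the dataset, run the full ensemble
#' on the observed labels, and evaluate each method's outlyingness scores
#' and the consensus (scored as `-log RP`) against the planted outlier
#' truth by ROC/AUC.
#'
#' @param seeds Integer vector of replicate seeds.
#' @param scenarios Character vector of scenario names.
#' @param n,p,n_informative,effect_size Data-generation settings.
#' @param control A [rosie_control()].
#' @param optimize Logical; optimize hyperparameters per run (default
#'   `FALSE`: the study uses fixed settings so replicate AUCs are
#'   comparable).
#' @return Data frame with columns `scenario`, `seed`, `method`, `auc`.
#' @export
run_simulation_study <- function(seeds = 1, scenarios = c("label_switch_5",
                                                          "label_switch_15",
                                                          "expression_shift"),
                                 n = 200, p = 3200, n_informative = NULL,
                                 effect_size = 1.0,
                                 control = simulation_control(),
                                 optimize = FALSE) {
  n_informative <- n_informative %||% max(1L, round(0.05 * p))
  out <- list()
  for (sc in scenarios) {
    for (sd_ in seeds) {
      sim <- simulate_scenario(sc, n = n, p = p,
                               n_informative = n_informative,
                               effect_size = effect_size, seed = sd_)
      res <- run_rosie(sim$X, sim$y_observed, control = control,
                       seed = child_seed(sd_, sc), optimize = optimize)
      aucs <- c(
        vapply(res$per_method, function(m)
          evaluate_roc(m$outlier_scores, sim$outlier_truth)$auc, numeric(1L)),
        consensus = evaluate_roc(-log(res$consensus$table$rp),
                                 sim$outlier_truth)$auc)
      out[[length(out) + 1L]] <-
        data.frame(scenario = sc, seed = sd_,
                   method = names(aucs), auc = unname(aucs),
                   stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, out)
}
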