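#' Remove features that are constant across all samples
#'
#' Features whose expression never varies carry no class information and are
#' dropped before any model fitting.  Feature order is otherwise preserved.
#'
#' @param X An [expression_matrix()].
#' @return An [expression_matrix()] with constant features removed.
#' @export
drop_constant_features <- function(X) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  keep <- apply(X$values, 2L, function(v) max(v) > min(v))
  if (!any(keep)) stop("all features are constant; nothing left to classify")
  if (all(keep)) return(X)
  subset_features(X, which(keep))
}

# Rank-based single-feature AUC of `v` as a score for class 1, with the
# midrank tie correction (equivalent to the Wilcoxon statistic).
feature_auc <- function(v, y) {
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  r <- rank(v, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Filter features by single-feature ROC variable importance
#'
#' Each feature is scored by the area under its single-feature ROC curve
#' against the class labels, symmetrized as `max(AUC, 1 - AUC)` so that
#' features discriminating in either direction rank equally.  The `keep`
#' most important features are retained in their original order; ties at the
#' cut are broken by original feature order.
#'
#' @param X An [expression_matrix()].
#' @param labels A [class_labels()] paired with `X`.
#' @param keep Number of features to retain.
#' @return An [expression_matrix()] with `keep` features.
#' @export
auc_importance_filter <- function(X, labels, keep) {
  check_paired(X, labels)
  if (length(keep) != 1L || is.na(keep) || keep <= 0)
    stop("keep must be a positive integer")
  keep <- as.integer(keep)
  p <- n_features(X)
  if (keep > p) stop("keep (", keep, ") exceeds number of features (", p, ")")
  auc <- apply(X$values, 2L, feature_auc, y = labels$y)
  importance <- pmax(auc, 1 - auc)
  sel <- order(-importance, seq_len(p))[seq_len(keep)]  # stable: ties by column order
  subset_features(X, sort(sel))
}

#' Log-transform an expression matrix
#'
#' Replaces values by `log(x + offset)` in the given base (default
#' `log2(x + 1)`, the usual convention for FPKM-type abundances) and sets
#' the `log_scale` flag.
#'
#' @param X An [expression_matrix()] with non-negative values.
#' @param base Logarithm base.
#' @param offset Pseudo-count added before taking the log.
#' @return The transformed [expression_matrix()].
#' @export
log_transform <- function(X, base = 2, offset = 1) {
  stopifnot(inherits(X, "ExpressionMatrix"))
  v <- X$values
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1L, ]
    stop("negative value at sample '", X$sample_ids[bad[1L]], "', feature '",
         X$feature_ids[bad[2L]], "'; log transform requires non-negative input")
  }
  expression_matrix(log(v + offset, base = base), sample_ids = X$sample_ids,
                    feature_ids = X$feature_ids, log_scale = TRUE)
}
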