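#' Construct an expression matrix object
#'
#' The container consumed by every stage of the ensemble: a numeric
#' samples-by-features matrix with unique sample and feature identifiers and
#' a flag recording whether values are on the log scale.
#'
#' @param values Numeric matrix, samples in rows, features in columns. Row
#'   and column names are used as identifiers when `sample_ids` /
#'   `feature_ids` are not given.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param feature_ids Character vector of unique feature identifiers.
#' @param log_scale Logical; `TRUE` once values have been log-transformed.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `sample_ids`, `feature_ids`, `log_scale`.
#' @export
expression_matrix <- function(values,
                              sample_ids = rownames(values),
                              feature_ids = colnames(values),
                              log_scale = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length (", length(sample_ids), ") != number of rows (",
         nrow(values), ")")
  if (length(feature_ids) != ncol(values))
    stop("feature_ids length (", length(feature_ids), ") != number of columns (",
         ncol(values), ")")
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop("duplicate sample IDs: ", paste(unique(dup), collapse = ", "))
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup)) stop("duplicate feature IDs: ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite value at sample '", sample_ids[bad[1L]], "', feature '",
         feature_ids[bad[2L]], "'")
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 feature_ids = feature_ids, log_scale = isTRUE(log_scale)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix: ", length(x$sample_ids), " samples x ",
      length(x$feature_ids), " features",
      if (x$log_scale) " (log scale)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

n_samples <- function(x) nrow(x$values)
n_features <- function(x) ncol(x$values)

#' Construct binary class labels
#'
#' @param y Vector coercible to 0/1 integers, one entry per sample.
#' @param sample_ids Optional sample identifiers (taken from `names(y)` if
#'   present).
#' @param positive_class_name Human-readable name for class 1.
#'
#' @return An object of class `ClassLabels` with elements `y`, `sample_ids`,
#'   `positive_class_name`.
#' @export
class_labels <- function(y, sample_ids = names(y), positive_class_name = "1") {
  y <- as.integer(y)
  if (any(is.na(y)) || !all(y %in% c(0L, 1L)))
    stop("class labels must be 0/1")
  structure(list(y = y, sample_ids = as.character(sample_ids %||% seq_along(y)),
                 positive_class_name = positive_class_name),
            class = "ClassLabels")
}

#' @export
print.ClassLabels <- function(x, ...) {
  cat("ClassLabels: n=", length(x$y), ", class 1 ('", x$positive_class_name,
      "'): ", sum(x$y), ", class 0: ", sum(x$y == 0L), "\n", sep = "")
  invisible(x)
}

# Check that labels pair with a matrix and that both classes are present
# (required for supervised fitting).
check_paired <- function(X, labels, require_both = TRUE) {
  stopifnot(inherits(X, "ExpressionMatrix"), inherits(labels, "ClassLabels"))
  if (length(labels$y) != n_samples(X))
    stop("labels length (", length(labels$y), ") != number of samples (",
         n_samples(X), ")")
  if (require_both && length(unique(labels$y)) < 2L)
    stop("both classes must be present")
  invisible(TRUE)
}

#' Read an expression matrix and paired class labels from delimited files
#'
#' The matrix file has a header row of feature IDs and sample IDs in the
#' first column (samples in rows).  The label file has two columns: sample
#' ID and class (0/1).  Labels are reordered to match the matrix sample
#' order.
#'
#' @param path Path to the expression matrix file.
#' @param labels_path Path to the two-column label file.
#' @param sep Field delimiter (default tab).
#'
#' @return A list with elements `X` (an [expression_matrix()]) and `labels`
#'   (a [class_labels()]).
#' @export
read_expression <- function(path, labels_path, sep = "\t") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (!file.exists(labels_path)) stop("label file not found: ", labels_path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "\"")
  sample_ids <- raw[[1L]]
  feature_ids <- colnames(raw)[-1L]
  dupf <- feature_ids[duplicated(feature_ids)]
  if (length(dupf)) stop("duplicate feature IDs: ", paste(unique(dupf), collapse = ", "))
  dups <- sample_ids[duplicated(sample_ids)]
  if (length(dups)) stop("duplicate sample IDs: ", paste(unique(dups), collapse = ", "))
  vals <- matrix(NA_real_, nrow(raw), length(feature_ids),
                 dimnames = list(sample_ids, feature_ids))
  for (j in seq_along(feature_ids)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop("non-numeric value '", raw[[j + 1L]][i], "' at row ", i,
           " (sample '", sample_ids[i], "'), column '", feature_ids[j], "'")
    }
    vals[, j] <- v
  }
  lab <- utils::read.table(labels_path, header = FALSE, sep = sep,
                           check.names = FALSE, colClasses = "character")
  if (ncol(lab) < 2L) stop("label file must have two columns: sample ID, class")
  # tolerate a header line in the label file
  if (suppressWarnings(is.na(as.numeric(lab[[2L]][1L]))) && nrow(lab) > 1L)
    lab <- lab[-1L, , drop = FALSE]
  lab_ids <- lab[[1L]]
  missing <- setdiff(sample_ids, lab_ids)
  if (length(missing))
    stop("samples missing from label file: ", paste(missing, collapse = ", "))
  y <- as.numeric(lab[[2L]])[match(sample_ids, lab_ids)]
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  list(X = expression_matrix(vals), labels = class_labels(y, sample_ids))
}

#' Write an expression matrix and labels to delimited files
#'
#' @param X An [expression_matrix()].
#' @param labels A [class_labels()] or `NULL`.
#' @param path Output path for the matrix.
#' @param labels_path Output path for the labels (required when `labels` is
#'   given).
#' @param sep Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(X, path, labels = NULL, labels_path = NULL, sep = "\t") {
  df <- data.frame(sample_id = X$sample_ids, X$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(labels)) {
    stopifnot(!is.null(labels_path))
    utils::write.table(data.frame(labels$sample_ids, labels$y), labels_path,
                       sep = sep, quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

# Subset samples (indices or a multiset of indices); duplicate indices get
# uniquified IDs so the container invariants hold.
subset_samples <- function(X, idx) {
  ids <- X$sample_ids[idx]
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "#")
  expression_matrix(X$values[idx, , drop = FALSE], sample_ids = ids,
                    feature_ids = X$feature_ids, log_scale = X$log_scale)
}

subset_features <- function(X, j) {
  expression_matrix(X$values[, j, drop = FALSE], sample_ids = X$sample_ids,
                    feature_ids = X$feature_ids[j], log_scale = X$log_scale)
}
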