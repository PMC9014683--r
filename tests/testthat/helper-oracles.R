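# Independent oracles and fixture builders used across the suite.
# Each oracle is a direct, brute-force or closed-form computation that does
# not share code with the package implementation it checks.

# PLS1 regression coefficients via the Helland/Krylov closed form:
# beta = R (R' S R)^{-1} R' s with S = X'X, s = X'y, R = [s, S s, ...],
# on mean-centered data.  Independent of the NIPALS path used in-package.
pls1_krylov_oracle <- function(X, y, ncomp) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  s <- drop(crossprod(Xc, yc))
  S <- crossprod(Xc)
  R <- matrix(0, ncol(X), ncomp)
  v <- s
  for (a in seq_len(ncomp)) {
    R[, a] <- v
    v <- drop(S %*% v)
  }
  R <- qr.Q(qr(R))  # orthonormalize for numerical stability
  drop(R %*% solve(crossprod(R, S %*% R), crossprod(R, s)))
}

# AUC as the fraction of concordant (true-outlier, non-outlier) pairs,
# ties counting one half.
auc_pair_oracle <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# Exhaustive count of ordered k-tuples from {1..n} with product <= t.
rp_enum_oracle <- function(t, n, k) {
  grids <- rep(list(seq_len(n)), k)
  tuples <- do.call(expand.grid, grids)
  prod_vals <- Reduce(`*`, tuples)
  sum(prod_vals <= t)
}

# Two balanced Gaussian classes separated only on feature 1.
make_separable_fixture <- function(n = 40, p = 10, delta = 5, seed = 11) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  vals <- matrix(rnorm(n * p, sd = 0.5), n, p)
  vals[y == 1L, 1L] <- vals[y == 1L, 1L] + delta
  X <- expression_matrix(vals, sample_ids = sprintf("S%02d", 1:n),
                         feature_ids = paste0("F", 1:p))
  list(X = X, labels = class_labels(y, X$sample_ids))
}

# Overlapping (non-separable) two-class logistic fixture.
make_overlap_fixture <- function(n = 200, p = 5, seed = 7) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  beta <- c(1, -1, 0.5, 0, 0)
  prob <- 1 / (1 + exp(-(x %*% beta)))
  y <- as.integer(runif(n) < prob)
  X <- expression_matrix(x, sample_ids = sprintf("S%03d", 1:n),
                         feature_ids = paste0("F", 1:p))
  list(X = X, labels = class_labels(y, X$sample_ids))
}

# Write a small expression TSV + label TSV pair; returns the two paths.
write_fixture_files <- function(vals, y, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixture")
    dir.create(dir)
  }
  ids <- rownames(vals)
  fp <- file.path(dir, "expr.tsv")
  lp <- file.path(dir, "labels.tsv")
  df <- data.frame(sample_id = ids, vals, check.names = FALSE)
  write.table(df, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(ids, y), lp, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  list(expr = fp, labels = lp)
}

# The published consensus summary shipped with the package (11 influential
# samples from a TNBC-vs-non-TNBC cohort of n = 1019, k = 3 methods).
load_reference_consensus <- function() {
  path <- system.file("extdata", "tnbc_consensus_published.tsv",
                      package = "rosie")
  read.delim(path)
}

# small ensemble control for fast end-to-end tests
fast_control <- function(...) {
  rosie_control(
    sprm = list(n_components_grid = 1L, eta_grid = 0.5),
    rskc = list(alpha_grid = 0.1, l1_grid = 4, n_init = 3L,
                n_permutations = 5L),
    enetlts = list(alpha_grid = 0.5, lambda_grid = 0.02, n_starts = 8L,
                   n_keep = 2L),
    ...)
}
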