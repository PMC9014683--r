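#' Rank scores in decreasing order with average tie handling
#'
#' Rank 1 is assigned to the largest (most outlying) score; tied scores
#' receive the average of the ranks they span, so ranks always sum to
#' `n(n+1)/2`.
#'
#' @param scores Numeric vector, larger = more outlying.
#' @return Numeric vector of (possibly fractional) ranks.
#' @export
rank_with_ties <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  rank(-scores, ties.method = "average")
}

#' Rank product across methods
#'
#' Elementwise product of per-method outlyingness ranks: for sample i,
#' `RP(i) = prod_l R_l(i)`.  Small RP means the sample is consistently
#' top-ranked as an outlier.
#'
#' @param rankings List of k numeric rank vectors of equal length (k >= 2).
#' @return Numeric vector of rank products.
#' @export
rank_product <- function(rankings) {
  stopifnot(is.list(rankings), length(rankings) >= 2L)
  n <- unique(vapply(rankings, length, integer(1L)))
  if (length(n) != 1L)
    stop("rankings have unequal lengths: ", paste(vapply(rankings, length, integer(1L)), collapse = ", "))
  Reduce(`*`, rankings)
}

# Number of ordered pairs (a, b) with 1 <= a, b <= n and a*b <= t.
rp_count2 <- function(t, n) {
  if (t < 1) return(0)
  b <- seq_len(min(n, t))
  sum(pmin(n, t %/% b))
}

# Number of ordered k-tuples from {1..n} with product <= t (t integer).
# Capped divisor counting: O(n) for k = 2, O(n^2) (vectorized) for k = 3,
# recursive for larger k.
rp_count <- function(t, n, k) {
  t <- floor(t)
  if (t < 1) return(0)
  if (k == 1) return(min(n, t))
  if (k == 2) return(rp_count2(t, n))
  a <- seq_len(min(n, t))
  if (k == 3) {
    total <- 0
    for (ai in a) total <- total + rp_count2(t %/% ai, n)
    return(total)
  }
  total <- 0
  for (ai in a) total <- total + rp_count(t %/% ai, n, k - 1L)
  total
}

#' Exact tail p-value of a rank product under the discrete-uniform null
#'
#' The null treats the k ranks as independent uniforms on `{1, ..., n}`; the
#' p-value is `P(prod U_l <= rp)`, computed exactly by counting the ordered
#' k-tuples whose product does not exceed `rp` (a tuple's integer product is
#' `<= rp` iff it is `<= floor(rp)`, which also covers tie-averaged,
#' non-integer rank products).  A gamma tail approximation (the continuous
#' limit, `-sum log(U_l/n) ~ Gamma(k, 1)`) is available for large `k`.
#'
#' @param rp Rank product value in `[1, n^k]`.
#' @param n Number of samples (support of each rank).
#' @param k Number of fused rankings.
#' @param method `"exact"` (default) or `"gamma"`.
#' @return p-value in `[0, 1]`.
#' @export
rp_pvalue <- function(rp, n, k, method = c("exact", "gamma")) {
  method <- match.arg(method)
  stopifnot(length(rp) == 1L, is.finite(rp), n >= 1, k >= 1)
  if (rp < 1 || rp > n^k)
    stop("rp = ", rp, " outside [1, n^k] = [1, ", n^k, "]")
  if (method == "gamma")
    return(stats::pgamma(log(n^k / rp), shape = k, lower.tail = FALSE))
  rp_count(rp, n, k) / n^k
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q(i) = min_{j >= rank(i)} p_(j) * n / j`, mapped back to input order.
#' A thin, named wrapper over [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
bh_qvalues <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Storey-type q-values with a fixed-lambda pi0 estimate
#'
#' Estimates the null proportion `pi0 = #\{p > lambda\} / ((1 - lambda) m)`
#' (capped at 1) and scales the BH step-up quantities by it.  Offered as an
#' alternative FDR estimate; BH is the default throughout the package.
#'
#' @param p_values Numeric vector of p-values.
#' @param lambda Tuning point for the pi0 estimate.
#' @return Vector of q-values.
#' @export
storey_qvalues <- function(p_values, lambda = 0.5) {
  stopifnot(all(p_values >= 0 & p_values <= 1), lambda > 0, lambda < 1)
  m <- length(p_values)
  pi0 <- min(1, sum(p_values > lambda) / ((1 - lambda) * m))
  pmin(1, pi0 * stats::p.adjust(p_values, method = "BH"))
}

#' Call influential samples from consensus q-values
#'
#' @param consensus A `rosie_consensus` object (see [consensus_outliers()])
#'   or a data frame with columns `sample_id`, `rp`, `q`.
#' @param q_threshold Samples with `q <` this value are called influential.
#' @return Character vector of influential sample IDs, ordered by ascending
#'   q then ascending rank product.
#' @export
call_influential <- function(consensus, q_threshold = 0.05) {
  tab <- if (inherits(consensus, "rosie_consensus")) consensus$table else consensus
  stopifnot(all(c("sample_id", "rp", "q") %in% names(tab)))
  hit <- tab[tab$q < q_threshold, , drop = FALSE]
  hit <- hit[order(hit$q, hit$rp), , drop = FALSE]
  as.character(hit$sample_id)
}

#' Fuse per-method outlyingness scores into a consensus
#'
#' Ranks each score vector (rank 1 = most outlying, ties averaged), forms
#' the per-sample rank product, attaches exact discrete-uniform p-values,
#' FDR q-values, and influential-sample calls at `q < q_threshold`.
#'
#' @param score_list Named list of k numeric score vectors (larger = more
#'   outlying), one per method.
#' @param sample_ids Sample identifiers.
#' @param q_threshold Influential-call threshold on q.
#' @param q_method `"BH"` (default) or `"storey"`.
#' @return An object of class `rosie_consensus`: list with `table` (one row
#'   per sample: per-method ranks, `rp`, `p`, `q`, `influential`),
#'   `influential` (ordered IDs), `q_threshold`, `k`, `n`.
#' @export
consensus_outliers <- function(score_list, sample_ids,
                               q_threshold = 0.05,
                               q_method = c("BH", "storey")) {
  q_method <- match.arg(q_method)
  stopifnot(is.list(score_list), length(score_list) >= 2L)
  n <- length(sample_ids)
  ranks <- lapply(score_list, function(s) {
    stopifnot(length(s) == n)
    rank_with_ties(s)
  })
  rp <- rank_product(ranks)
  k <- length(ranks)
  p <- vapply(rp, rp_pvalue, numeric(1L), n = n, k = k)
  q <- if (q_method == "BH") bh_qvalues(p) else storey_qvalues(p)
  tab <- data.frame(sample_id = as.character(sample_ids),
                    stringsAsFactors = FALSE)
  mn <- names(score_list) %||% paste0("method", seq_len(k))
  for (l in seq_len(k)) tab[[paste0("rank_", mn[l])]] <- ranks[[l]]
  tab$rp <- rp
  tab$p <- p
  tab$q <- q
  tab$influential <- q < q_threshold
  res <- structure(list(table = tab, q_threshold = q_threshold,
                        k = k, n = n, q_method = q_method),
                   class = "rosie_consensus")
  res$influential <- call_influential(res, q_threshold)
  res
}

#' @export
print.rosie_consensus <- function(x, ...) {
  cat("Rank-product consensus over", x$k, "rankings of", x$n, "samples\n")
  cat("Influential (q <", x$q_threshold, "):", length(x$influential), "samples\n")
  if (length(x$influential)) {
    show <- x$table[x$table$influential, , drop = FALSE]
    show <- show[order(show$q, show$rp), , drop = FALSE]
    print(utils::head(show, 20), row.names = FALSE)
  }
  invisible(x)
}

#' Write a consensus table as TSV
#'
#' One row per sample: per-method ranks, rank product, p, q, influential
#' flag.
#'
#' @param consensus A `rosie_consensus` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_consensus_tsv <- function(consensus, path) {
  stopifnot(inherits(consensus, "rosie_consensus"))
  utils::write.table(consensus$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
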