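# Stratified block bootstrap for the validity check: every sample appears
# in at least one block (the blocks start as a stratified partition), each
# block is refilled to the original size by class-stratified sampling with
# replacement, so every block keeps the original class counts.

#' Construct stratified bootstrap blocks
#'
#' Samples are partitioned (stratified by class, block sizes differing by
#' at most one per class, remainders assigned by a seeded draw) into `m`
#' blocks; each block is then filled back to size `n` by class-stratified
#' sampling with replacement from all samples, so every block carries the
#' original class counts and every sample is contained in at least one
#' block.
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param labels A [class_labels()] (or 0/1 vector) paired with
#'   `sample_ids`.
#' @param m Number of blocks (>= 2).
#' @param seed Integer seed.
#' @return A list of `m` integer index multisets of length `n`, each with
#'   attributes `partition` (the indices contributed by the partition) and
#'   `fill` (the resampled indices).
#' @export
make_bootstrap_blocks <- function(sample_ids, labels, m = 5, seed = 1) {
  y <- if (inherits(labels, "ClassLabels")) labels$y else as.integer(labels)
  n <- length(sample_ids)
  stopifnot(length(y) == n, m >= 2)
  classes <- sort(unique(y))
  for (cls in classes)
    if (sum(y == cls) < m)
      stop("class ", cls, " has fewer than m = ", m, " members")
  parts <- rep(list(integer(0)), m)
  with_seed(seed, {
    # remainder queue shared across classes: a seeded shuffled order of
    # blocks, so extras spread over blocks before any block gets a second
    queue <- sample.int(m)
    for (cls in classes) {
      idx <- which(y == cls)
      idx <- idx[order(sample_ids[idx])]   # order-independent base
      idx <- idx[sample.int(length(idx))]  # seeded shuffle
      sizes <- rep(length(idx) %/% m, m)
      extra <- length(idx) %% m
      lucky <- integer(0)
      while (length(lucky) < extra) {
        if (!length(queue)) queue <- sample.int(m)
        cand <- queue[1L]
        queue <- queue[-1L]
        if (!(cand %in% lucky)) lucky <- c(lucky, cand)
      }
      sizes[lucky] <- sizes[lucky] + 1L
      at <- 1L
      for (b in seq_len(m)) {
        if (sizes[b] > 0) {
          parts[[b]] <- c(parts[[b]], idx[at:(at + sizes[b] - 1L)])
          at <- at + sizes[b]
        }
      }
    }
    lapply(parts, function(part) {
      fill <- integer(0)
      for (cls in classes) {
        need <- sum(y == cls) - sum(y[part] == cls)
        pool <- which(y == cls)
        pool <- pool[order(sample_ids[pool])]
        if (need > 0)
          fill <- c(fill, pool[sample.int(length(pool), need, replace = TRUE)])
      }
      block <- c(part, fill)
      attr(block, "partition") <- part
      attr(block, "fill") <- fill
      block
    })
  })
}

#' Bootstrap validity check of a main ensemble run
#'
#' Re-runs the three methods on each bootstrap block with the main run's
#' chosen hyperparameters (no re-optimization), recomputes the consensus
#' and common features per block, and tallies (i) for each main-run
#' influential sample, in how many blocks it appears and in how many of
#' those it is re-flagged, and (ii) for each main-run common feature, in
#' how many blocks it is again commonly selected.  Block p-values use the
#' block size as `n`, duplicates counted individually.  A failed block fit
#' is recorded, not fatal.
#'
#' @param X The [expression_matrix()] of the main run.
#' @param labels Its [class_labels()].
#' @param main_result The `rosie_result` of the main run.
#' @param m Number of bootstrap blocks.
#' @param seed Integer seed.
#' @param control The [rosie_control()] used in the main run.
#' @return An object of class `rosie_bootstrap`: `m`, `blocks`,
#'   `per_block` (influential IDs, common features or failure message),
#'   `influential_redetection` (data frame: sample_id, n_blocks_present,
#'   n_blocks_influential), `feature_support` (data frame: feature_id,
#'   n_blocks_common), `failed_blocks`.
#' @export
run_validity_check <- function(X, labels, main_result, m = 5, seed = 1,
                               control = rosie_control()) {
  check_paired(X, labels)
  stopifnot(inherits(main_result, "rosie_result"))
  blocks <- make_bootstrap_blocks(X$sample_ids, labels, m = m, seed = seed)
  hp <- main_result$hyperparameters
  per_block <- vector("list", m)
  failed <- integer(0)
  for (b in seq_len(m)) {
    idx <- as.integer(blocks[[b]])
    Xb <- subset_samples(X, idx)
    yb <- class_labels(labels$y[idx], Xb$sample_ids)
    res <- tryCatch(
      quiet_nonconvergence(
        run_rosie(Xb, yb, control = control,
                  seed = child_seed(seed, paste0("block", b)),
                  optimize = FALSE, hyperparameters = hp)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, b)
      per_block[[b]] <- list(ok = FALSE, message = conditionMessage(res))
    } else {
      # map (possibly uniquified) block IDs back to original sample IDs
      infl_orig <- unique(sub("#.*$", "", res$consensus$influential))
      per_block[[b]] <- list(ok = TRUE,
                             influential = infl_orig,
                             common_features = res$common_features,
                             original_ids = unique(X$sample_ids[idx]))
    }
  }
  main_infl <- main_result$consensus$influential
  redet <- data.frame(sample_id = main_infl,
                      n_blocks_present = integer(length(main_infl)),
                      n_blocks_influential = integer(length(main_infl)),
                      stringsAsFactors = FALSE)
  for (b in seq_len(m)) {
    pb <- per_block[[b]]
    if (!isTRUE(pb$ok)) next
    present <- redet$sample_id %in% pb$original_ids
    redet$n_blocks_present <- redet$n_blocks_present + present
    redet$n_blocks_influential <- redet$n_blocks_influential +
      (present & redet$sample_id %in% pb$influential)
  }
  feats <- main_result$common_features
  support <- data.frame(feature_id = feats, n_blocks_common = 0L,
                        stringsAsFactors = FALSE)
  for (b in seq_len(m)) {
    pb <- per_block[[b]]
    if (!isTRUE(pb$ok)) next
    support$n_blocks_common <- support$n_blocks_common +
      (support$feature_id %in% pb$common_features)
  }
  structure(list(m = m, blocks = blocks, per_block = per_block,
                 influential_redetection = redet,
                 feature_support = support,
                 failed_blocks = failed),
            class = "rosie_bootstrap")
}

#' @export
print.rosie_bootstrap <- function(x, ...) {
  cat("Bootstrap validity check:", x$m, "blocks",
      if (length(x$failed_blocks)) paste0("(", length(x$failed_blocks), " failed)") else "",
      "\n")
  if (nrow(x$influential_redetection)) {
    cat("Influential-sample redetection:\n")
    print(x$influential_redetection, row.names = FALSE)
  }
  cat("Feature support: ", sum(x$feature_support$n_blocks_common == x$m),
      "of", nrow(x$feature_support), "common features re-selected in all blocks\n")
  invisible(x)
}

#' Write bootstrap report tables as TSV
#'
#' @param report A `rosie_bootstrap`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_bootstrap_report <- function(report, dir) {
  stopifnot(inherits(report, "rosie_bootstrap"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$influential_redetection,
                     file.path(dir, "influential_redetection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$feature_support,
                     file.path(dir, "feature_support.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
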