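# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never disturb
# the global stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream label; keeps independent
# sub-streams reproducible while staying inside 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103L + sum(utf8ToInt(as.character(stream)))) %% 2147483647
}

col_medians <- function(x) apply(x, 2L, stats::median)

# MAD (consistent with sd under normality) with a floor so near-constant
# features cannot produce zero scales.
col_mads <- function(x, floor = 1e-8) {
  pmax(apply(x, 2L, stats::mad), floor)
}

# M-estimation weight functions, tuning constant c: map standardized
# residual/distance z to a case weight in (0, 1].
fair_weights <- function(z, c = 4) 1 / (1 + abs(z / c))^2

huber_weights <- function(z, c = 1.345) pmin(1, c / pmax(abs(z), .Machine$double.eps))

unit_weights <- function(z, c = 1) rep(1, length(z))

get_weight_fun <- function(name) {
  switch(match.arg(name, c("fair", "huber", "unit")),
    fair = fair_weights, huber = huber_weights, unit = unit_weights)
}

# Stratified k-fold assignment: returns integer fold id per observation,
# each class spread as evenly as possible across folds.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run a fit muffling the anticipated "did not converge" warning; used by
# cross-validation and bootstrap loops where a last-iterate fit is an
# acceptable scorer and the warning would only repeat per fold.
quiet_nonconvergence <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("did not converge", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}
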