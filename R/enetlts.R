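# Robust sparse logistic regression by least trimmed squares: elastic-net
# penalized logistic likelihood maximized over the best h-subset of cases,
# found by elemental starts plus concentration (C-) steps, followed by a
# reweighting step based on standardized Pearson residuals.  glmnet is the
# inner penalized solver; the trimming machinery lives here.

# penalized logistic fit at a single (alpha, lambda); returns intercept and
# coefficient vector.  glmnet prefers a descending lambda path, so the
# target lambda is embedded in a short path and extracted.
glmnet_logistic <- function(x, y, alpha, lambda, weights = NULL) {
  path <- lambda * c(16, 8, 4, 2, 1)
  # elemental starts fit on a handful of cases; glmnet warns about tiny
  # class counts there by design, so suppress
  fit <- suppressWarnings(
    glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                   lambda = path, weights = weights,
                   standardize = TRUE, thresh = 1e-10, maxit = 1e6))
  cf <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  list(intercept = cf[1L], beta = cf[-1L])
}

logistic_prob <- function(intercept, beta, x) {
  eta <- intercept + drop(x %*% beta)
  1 / (1 + exp(-pmin(pmax(eta, -30), 30)))
}

# deviance residuals (signed) of a 0/1 response
deviance_residuals <- function(y, prob) {
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  d2 <- -2 * (y * log(prob) + (1 - y) * log(1 - prob))
  sign(y - prob) * sqrt(pmax(d2, 0))
}

pearson_residuals <- function(y, prob) {
  prob <- pmin(pmax(prob, 1e-10), 1 - 1e-10)
  (y - prob) / sqrt(prob * (1 - prob))
}

# class-stratified h-subset: the h cases of smallest absolute deviance
# residual, split across classes in proportion to the class sizes so both
# classes are always represented.
stratified_h_subset <- function(absdev, y, h) {
  n <- length(y)
  n1 <- sum(y == 1L)
  h1 <- min(max(1L, round(h * n1 / n)), n1)
  h0 <- h - h1
  if (h0 > sum(y == 0L)) { h0 <- sum(y == 0L); h1 <- h - h0 }
  i1 <- which(y == 1L); i0 <- which(y == 0L)
  c(i1[order(absdev[i1])[seq_len(h1)]], i0[order(absdev[i0])[seq_len(h0)]])
}

# penalized trimmed objective used to compare candidate subsets
trimmed_objective <- function(y, prob, subset, beta, alpha, lambda) {
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  dev <- -2 * (y * log(prob) + (1 - y) * log(1 - prob))
  mean(dev[subset]) +
    lambda * ((1 - alpha) / 2 * sum(beta^2) + alpha * sum(abs(beta)))
}

# run C-steps from a given subset until the subset stabilizes
run_csteps <- function(x, y, subset, alpha, lambda, h, max_csteps) {
  obj_trace <- numeric(0)
  fit <- NULL
  for (cs in seq_len(max_csteps)) {
    fit <- glmnet_logistic(x[subset, , drop = FALSE], y[subset], alpha, lambda)
    prob <- logistic_prob(fit$intercept, fit$beta, x)
    new_subset <- stratified_h_subset(abs(deviance_residuals(y, prob)), y, h)
    obj_trace <- c(obj_trace,
                   trimmed_objective(y, prob, new_subset, fit$beta, alpha, lambda))
    if (setequal(new_subset, subset)) { subset <- new_subset; break }
    subset <- new_subset
  }
  list(subset = sort(subset), fit = fit,
       objective = obj_trace[length(obj_trace)], objective_trace = obj_trace)
}

#' Fit robust sparse logistic regression (elastic net over trimmed cases)
#'
#' For each candidate `(alpha_mix, lambda)`: elemental starts (small
#' class-stratified subsets, 3 per class, drawn by sorted sample ID) are
#' fitted and improved by two C-steps; the most promising starts get full
#' C-steps until the h-subset is a fixed point.  A C-step fits the
#' penalized logistic model on the current subset, recomputes deviance
#' residuals on all n cases and takes the h cases of smallest deviance
#' (class-stratified) as the new subset, which cannot increase the trimmed
#' penalized objective.  Optionally the raw fit is reweighted: cases whose
#' standardized Pearson residual is below the configured normal quantile
#' are refitted on.  When grids are supplied, `(alpha_mix, lambda)` is
#' chosen by 5-fold stratified cross-validated trimmed deviance on the
#' final subset.
#'
#' @param X An [expression_matrix()].
#' @param labels A [class_labels()] paired with `X`.
#' @param h_fraction Subset fraction in `(0.5, 1]`; `h = ceiling(h_fraction * n)`.
#' @param alpha_mix Elastic-net mixing parameter(s) in `(0, 1]`; a vector is
#'   treated as a CV grid.
#' @param lambda Penalty strength(s); a vector is treated as a CV grid.
#' @param n_starts Number of elemental starts.
#' @param n_keep Number of best starts continued with full C-steps.
#' @param max_csteps C-step cap per start.
#' @param reweight Logical; apply the reweighting step.
#' @param reweight_quantile Normal quantile for the residual cutoff
#'   (default 0.9875).
#' @param seed Integer seed for the elemental starts and CV folds.
#' @return An object of class `enetlts_model` with `coefficients`,
#'   `intercept`, `h_subset`, `std_residuals` (standardized Pearson
#'   residuals of the final fit on all cases), `selected_features`,
#'   `lambda_used`, `alpha_used`, `reweighted`, `objective_trace` and the
#'   configuration used.
#' @export
fit_enetlts <- function(X, labels, h_fraction = 0.75, alpha_mix = 0.5,
                        lambda = 0.05, n_starts = 40, n_keep = 5,
                        max_csteps = 20, reweight = TRUE,
                        reweight_quantile = 0.9875, seed = 1) {
  check_paired(X, labels)
  stopifnot(h_fraction > 0.5, h_fraction <= 1, all(alpha_mix > 0),
            all(alpha_mix <= 1), all(lambda > 0))
  x <- X$values
  y <- labels$y
  n <- nrow(x)
  h <- as.integer(ceiling(h_fraction * n))
  grid <- expand.grid(alpha = alpha_mix, lambda = lambda)
  use_cv <- nrow(grid) > 1L

  fit_one <- function(a, l) {
    if (h >= n) {
      # no trimming: single penalized fit on all cases
      fit <- glmnet_logistic(x, y, a, l)
      prob <- logistic_prob(fit$intercept, fit$beta, x)
      return(list(subset = seq_len(n), fit = fit,
                  objective = trimmed_objective(y, prob, seq_len(n), fit$beta, a, l),
                  objective_trace = numeric(0)))
    }
    ord_ids <- order(X$sample_ids)  # ID-based, order-independent starts
    i1 <- which(y[ord_ids] == 1L); i0 <- which(y[ord_ids] == 0L)
    cands <- list()
    for (r in seq_len(n_starts)) {
      el <- with_seed(child_seed(seed, paste0("enet", r)), {
        c(ord_ids[i1[sample.int(length(i1), min(3L, length(i1)))]],
          ord_ids[i0[sample.int(length(i0), min(3L, length(i0)))]])
      })
      res <- tryCatch({
        fit <- glmnet_logistic(x[el, , drop = FALSE], y[el], a, l)
        prob <- logistic_prob(fit$intercept, fit$beta, x)
        subset <- stratified_h_subset(abs(deviance_residuals(y, prob)), y, h)
        run_csteps(x, y, subset, a, l, h, max_csteps = 2L)
      }, error = function(e) NULL)
      if (!is.null(res)) cands[[length(cands) + 1L]] <- res
    }
    if (!length(cands)) stop("all elemental starts failed")
    objs <- vapply(cands, `[[`, numeric(1L), "objective")
    keep <- order(objs)[seq_len(min(n_keep, length(cands)))]
    best <- NULL
    for (i in keep) {
      res <- run_csteps(x, y, cands[[i]]$subset, a, l, h, max_csteps)
      if (is.null(best) || res$objective < best$objective) best <- res
    }
    best
  }

  choose <- grid[1L, ]
  if (use_cv) {
    cv_scores <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      a <- grid$alpha[g]; l <- grid$lambda[g]
      raw <- fit_one(a, l)
      sub <- raw$subset
      ysub <- y[sub]
      folds <- stratified_folds(ysub, 5L, child_seed(seed, paste0("cv", g)))
      dev_sum <- 0
      for (f in sort(unique(folds))) {
        tr <- sub[folds != f]; te <- sub[folds == f]
        if (length(unique(y[tr])) < 2L) next
        fit <- glmnet_logistic(x[tr, , drop = FALSE], y[tr], a, l)
        prob <- pmin(pmax(logistic_prob(fit$intercept, fit$beta,
                                        x[te, , drop = FALSE]), 1e-12), 1 - 1e-12)
        dev_sum <- dev_sum + sum(-2 * (y[te] * log(prob) + (1 - y[te]) * log(1 - prob)))
      }
      cv_scores[g] <- dev_sum / length(sub)
    }
    # ties broken toward the sparser model: larger lambda, then larger alpha
    ord <- order(cv_scores, -grid$lambda, -grid$alpha)
    choose <- grid[ord[1L], ]
  }
  a_use <- choose$alpha; l_use <- choose$lambda
  raw <- fit_one(a_use, l_use)

  reweighted <- FALSE
  final_fit <- raw$fit
  final_subset <- raw$subset
  if (reweight && h < n) {
    prob <- logistic_prob(raw$fit$intercept, raw$fit$beta, x)
    r <- pearson_residuals(y, prob)
    r_std <- r / max(stats::mad(r[raw$subset]), 1e-8)
    keep <- which(abs(r_std) <= stats::qnorm(reweight_quantile))
    if (length(unique(y[keep])) == 2L && length(keep) >= h) {
      final_fit <- glmnet_logistic(x[keep, , drop = FALSE], y[keep], a_use, l_use)
      reweighted <- TRUE
    }
  }
  prob_all <- logistic_prob(final_fit$intercept, final_fit$beta, x)
  r <- pearson_residuals(y, prob_all)
  r_std <- r / max(stats::mad(r[final_subset]), 1e-8)
  beta <- stats::setNames(final_fit$beta, X$feature_ids)
  structure(list(coefficients = beta,
                 intercept = final_fit$intercept,
                 h = h,
                 h_subset = sort(final_subset),
                 std_residuals = stats::setNames(r_std, X$sample_ids),
                 selected_features = X$feature_ids[abs(beta) > 1e-12],
                 lambda_used = l_use, alpha_used = a_use,
                 reweighted = reweighted,
                 objective = raw$objective,
                 objective_trace = raw$objective_trace,
                 feature_ids = X$feature_ids,
                 config = list(h_fraction = h_fraction, alpha_mix = alpha_mix,
                               lambda = lambda, n_starts = n_starts,
                               n_keep = n_keep, max_csteps = max_csteps,
                               reweight = reweight,
                               reweight_quantile = reweight_quantile,
                               seed = seed)),
            class = "enetlts_model")
}

#' @export
print.enetlts_model <- function(x, ...) {
  cat("enetLTS model: h =", x$h, ", alpha =", x$alpha_used,
      ", lambda =", signif(x$lambda_used, 3),
      if (x$reweighted) "(reweighted)" else "(raw)", "\n")
  cat(" ", length(x$selected_features), "selected features\n")
  invisible(x)
}

#' Predict class labels from a fitted enetLTS model
#'
#' Label 1 iff the fitted probability is at least 0.5.
#'
#' @param model A fitted `enetlts_model`.
#' @param X An [expression_matrix()] with the training feature set.
#' @return Integer vector of predicted labels in `{0, 1}`.
#' @export
predict_enetlts <- function(model, X) {
  stopifnot(inherits(model, "enetlts_model"), inherits(X, "ExpressionMatrix"))
  if (!identical(X$feature_ids, model$feature_ids))
    stop("feature IDs do not match the training features")
  prob <- logistic_prob(model$intercept, unname(model$coefficients), X$values)
  as.integer(prob >= 0.5)
}

#' Per-sample outlyingness scores from an enetLTS fit
#'
#' Absolute standardized Pearson residuals under the final (reweighted, if
#' applied) fit.
#'
#' @param model A fitted `enetlts_model`.
#' @return Numeric vector of scores (larger = more outlying).
#' @export
enetlts_outlier_scores <- function(model) {
  stopifnot(inherits(model, "enetlts_model"))
  abs(model$std_residuals)
}
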