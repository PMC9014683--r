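# Sparse partial robust M-regression discriminant analysis (SPRM-DA).
#
# A PLS-type binary classifier made robust by iteratively reweighted case
# weights (M-estimation weights on residuals and on score-space leverage)
# and sparse by soft-thresholding each latent direction vector.

# Weighted sparse NIPALS PLS1 on pre-standardized data Z with response ytil
# and case weights w.  Works on sqrt(w)-scaled, weighted-mean-centered data;
# returns loadings and the coefficient vector in the standardized space.
sprm_pls_core <- function(Z, ytil, w, ncomp, eta) {
  n <- nrow(Z); p <- ncol(Z)
  sw <- sqrt(w)
  mu_x <- colSums(Z * w) / sum(w)
  mu_y <- sum(ytil * w) / sum(w)
  Xc <- sweep(Z, 2L, mu_x)
  yc <- ytil - mu_y
  Xa <- Xc * sw
  ya <- yc * sw
  V <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); qv <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    v <- drop(crossprod(Xa, ya))
    if (eta > 0) {
      thr <- eta * max(abs(v))
      v <- sign(v) * pmax(abs(v) - thr, 0)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12)
      stop("n_components (", ncomp, ") exceeds the rank of the weighted data ",
           "(direction ", a, " is degenerate)")
    v <- v / nv
    t_ <- drop(Xa %*% v)
    tt <- sum(t_^2)
    if (tt < 1e-12)
      stop("n_components (", ncomp, ") exceeds the rank of the weighted data")
    P[, a] <- drop(crossprod(Xa, t_)) / tt
    qv[a] <- sum(ya * t_) / tt
    Xa <- Xa - tcrossprod(t_, P[, a])
    ya <- ya - t_ * qv[a]
    V[, a] <- v
  }
  R <- V %*% solve(crossprod(P, V))        # X-score rotation: T = Xc R
  beta <- drop(R %*% qv)
  scores <- Xc %*% R                        # scores for all samples, unweighted
  fitted <- mu_y + drop(Xc %*% beta)
  list(beta = beta, intercept = mu_y, mu_x = mu_x, V = V, P = P, q = qv,
       R = R, scores = scores, fitted = fitted)
}

#' Fit a sparse partial robust M-regression discriminant model
#'
#' The binary response is encoded as centered group codes (class 1 ->
#' `n0/n`, class 0 -> `-n1/n`), features are robustly standardized
#' (median/MAD with a floor), and a weighted sparse NIPALS PLS fit is
#' iterated with case weights recomputed from standardized residuals
#' (`w_r`) and score-space leverage (`w_x`) via an M-weight function;
#' `case_weights = w_r * w_x`.  Soft-thresholding of each direction vector
#' at `eta * max|v|` yields sparsity in the coefficients.
#'
#' @param X An [expression_matrix()].
#' @param labels A [class_labels()] paired with `X` (both classes present).
#' @param n_components Number of latent components.
#' @param eta Sparsity parameter in `[0, 1)`; 0 gives a dense PLS fit.
#' @param weight_function `"fair"` (default), `"huber"`, or `"unit"`
#'   (constant 1, i.e. no robustness - useful for oracle comparisons).
#' @param tuning_constant Tuning constant of the weight function.
#' @param max_iter,tol Iteration cap and convergence tolerance on the
#'   maximum coefficient change.
#' @return An object of class `sprm_model` with `coefficients` (original
#'   scale), `coefficients_std` (standardized scale), `intercept`, `scores`,
#'   `case_weights`, `selected_features`, `converged`, centers/scales and
#'   the configuration used.
#' @export
fit_sprm <- function(X, labels, n_components = 2, eta = 0.5,
                     weight_function = c("fair", "huber", "unit"),
                     tuning_constant = 4, max_iter = 50, tol = 1e-4) {
  check_paired(X, labels)
  weight_function <- match.arg(weight_function)
  wfun <- get_weight_fun(weight_function)
  stopifnot(eta >= 0, eta < 1, tol > 0, n_components >= 1)
  n <- n_samples(X)
  if (n < 2 * n_components)
    stop("need n >= 2 * n_components (n = ", n, ")")
  y <- labels$y
  n1 <- sum(y == 1L); n0 <- n - n1
  ytil <- ifelse(y == 1L, n0 / n, -n1 / n)

  centers <- col_medians(X$values)
  scales <- col_mads(X$values)
  Z <- sweep(sweep(X$values, 2L, centers), 2L, scales, "/")

  # initial case weights from robust standardized distances to the feature-
  # wise median (columns of Z are already median-centered, MAD-scaled)
  d0 <- sqrt(rowSums(Z^2))
  md <- stats::median(d0)
  w <- if (md < 1e-12) rep(1, n) else wfun(d0 / md, tuning_constant)
  w <- pmax(w, 1e-6)

  beta_old <- NULL
  converged <- FALSE
  fit <- NULL
  for (iter in seq_len(max_iter)) {
    fit <- sprm_pls_core(Z, ytil, w, n_components, eta)
    r <- ytil - fit$fitted
    s <- stats::mad(r)
    w_r <- if (s < 1e-8) rep(1, n) else wfun(r / s, tuning_constant)
    Tm <- fit$scores
    t_med <- apply(Tm, 2L, stats::median)
    t_mad <- pmax(apply(Tm, 2L, stats::mad), 1e-8)
    d <- sqrt(rowSums(sweep(sweep(Tm, 2L, t_med), 2L, t_mad, "/")^2))
    dmed <- stats::median(d)
    # scale so a typical score distance maps near the chi distribution median
    w_x <- if (dmed < 1e-8) rep(1, n)
           else wfun(d / dmed * sqrt(stats::qchisq(0.5, n_components)), tuning_constant)
    # damped update: plain w <- w_r * w_x can settle into a period-2 cycle
    # of the reweighting map; averaging with the previous weights keeps the
    # same fixed points and collapses the cycle
    w_new <- pmax((w_r * w_x + w) / 2, 1e-6)
    if (!is.null(beta_old)) {
      delta <- sqrt(sum((fit$beta - beta_old)^2) / max(sum(beta_old^2), 1e-24))
      if (delta < tol) { converged <- TRUE; w <- w_new; break }
    }
    beta_old <- fit$beta
    w <- w_new
    if (weight_function == "unit") { converged <- TRUE; break }
  }
  if (!converged)
    warning("SPRM did not converge in ", max_iter, " iterations; returning last iterate")

  beta_orig <- fit$beta / scales
  sel <- X$feature_ids[abs(fit$beta) > 1e-12]
  # weighted class centroids in score space, used by predict
  cent <- rbind(colSums(fit$scores * (w * (y == 0L))) / sum(w * (y == 0L)),
                colSums(fit$scores * (w * (y == 1L))) / sum(w * (y == 1L)))
  structure(list(coefficients = stats::setNames(beta_orig, X$feature_ids),
                 coefficients_std = stats::setNames(fit$beta, X$feature_ids),
                 intercept = fit$intercept,
                 scores = fit$scores,
                 case_weights = stats::setNames(w, X$sample_ids),
                 selected_features = sel,
                 centers = centers, scales = scales, mu_x = fit$mu_x,
                 rotation = fit$R, centroids = cent,
                 feature_ids = X$feature_ids,
                 encoded_levels = c(`0` = -n1 / n, `1` = n0 / n),
                 converged = converged, n_iter = iter,
                 config = list(n_components = n_components, eta = eta,
                               weight_function = weight_function,
                               tuning_constant = tuning_constant,
                               max_iter = max_iter, tol = tol)),
            class = "sprm_model")
}

#' @export
print.sprm_model <- function(x, ...) {
  cat("SPRM-DA model:", length(x$selected_features), "selected features,",
      x$config$n_components, "components, eta =", x$config$eta,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Predict class labels from a fitted SPRM model
#'
#' New samples are standardized with the training centers/scales, projected
#' into the latent score space, and assigned to the nearest case-weighted
#' class centroid.  A point exactly midway between centroids is assigned
#' class 0.
#'
#' @param model A fitted `sprm_model`.
#' @param X An [expression_matrix()] with the training feature set.
#' @return Integer vector of predicted labels in `{0, 1}`.
#' @export
predict_sprm <- function(model, X) {
  stopifnot(inherits(model, "sprm_model"), inherits(X, "ExpressionMatrix"))
  if (!identical(X$feature_ids, model$feature_ids))
    stop("feature IDs do not match the training features")
  Z <- sweep(sweep(X$values, 2L, model$centers), 2L, model$scales, "/")
  Tm <- sweep(Z, 2L, model$mu_x) %*% model$rotation
  d0 <- rowSums(sweep(Tm, 2L, model$centroids[1L, ])^2)
  d1 <- rowSums(sweep(Tm, 2L, model$centroids[2L, ])^2)
  as.integer(d1 < d0)   # ties (d1 == d0) -> class 0
}

#' Per-sample outlyingness scores from an SPRM fit
#'
#' The case weight is SPRM's inherent robustness measure; outlyingness is
#' `1 - case_weight` (larger = more outlying).
#'
#' @param model A fitted `sprm_model`.
#' @return Numeric vector of scores in `[0, 1)`, one per training sample.
#' @export
sprm_outlier_scores <- function(model) {
  stopifnot(inherits(model, "sprm_model"))
  1 - model$case_weights
}
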