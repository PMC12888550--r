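# Frequentist penalized estimators: lasso, elastic net, adaptive lasso.
# All assume a standardized design and centered response, fit without an
# intercept, and choose the penalty by 10-fold cross-validation at
# lambda.min. The lambda path has 100 log-spaced values down to
# 1e-4 * lambda_max.

cv_foldid <- function(n, n_folds, seed) {
  if (n < n_folds) stopf("fewer rows (%d) than CV folds (%d)", n, n_folds)
  with_local_seed(seed, sample(rep_len(seq_len(n_folds), n)))
}

glmnet_cv_fit <- function(x, y, alpha, n_folds, seed, penalty_factor = NULL,
                          thresh = 1e-10) {
  foldid <- cv_foldid(nrow(x), n_folds, seed)
  args <- list(x = x, y = y, alpha = alpha, foldid = foldid,
               standardize = FALSE, intercept = FALSE,
               nlambda = 100, lambda.min.ratio = 1e-4, thresh = thresh)
  if (!is.null(penalty_factor)) args$penalty.factor <- penalty_factor
  cv <- do.call(glmnet::cv.glmnet, args)
  beta <- as.numeric(coef(cv, s = "lambda.min"))[-1]
  list(beta = beta, lambda = cv$lambda.min, cv = cv)
}

#' Lasso with cross-validated penalty
#'
#' l1-penalized least squares solved by glmnet's coordinate descent, with the
#' penalty chosen as the `lambda.min` of 10-fold cross-validation. The
#' returned coefficients contain exact zeros, so selection is by the nonzero
#' pattern.
#'
#' @param x Standardized design matrix.
#' @param y Centered response.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Seed controlling the fold assignment (fixed folds make the
#'   lambda choice deterministic).
#' @param thresh Coordinate-descent convergence threshold passed to glmnet.
#' @return An `sb_fit` with `beta_hat` and the chosen `lambda` in
#'   `hyperparams`.
#' @export
fit_lasso <- function(x, y, n_folds = 10, seed = 1L, thresh = 1e-10) {
  assert_matrix_response(x, y)
  tm <- timed(glmnet_cv_fit(x, y, alpha = 1, n_folds, seed, thresh = thresh))
  new_sb_fit("lasso", tm$value$beta,
             hyperparams = list(lambda = tm$value$lambda, alpha = 1),
             runtime_s = tm$elapsed, selection_rule = "nonzero")
}

#' Elastic net with cross-validated penalty
#'
#' Mixture of l1 and l2 penalties at mixing weight `alpha` (0.5 in the
#' benchmark; `alpha = 1` reduces exactly to the lasso).
#'
#' @inheritParams fit_lasso
#' @param alpha Elastic-net mixing weight in \[0, 1\] (1 = pure l1).
#' @return An `sb_fit`.
#' @export
fit_elastic_net <- function(x, y, alpha = 0.5, n_folds = 10, seed = 1L,
                            thresh = 1e-10) {
  assert_matrix_response(x, y)
  if (alpha < 0 || alpha > 1) stopf("`alpha` must lie in [0, 1]")
  tm <- timed(glmnet_cv_fit(x, y, alpha = alpha, n_folds, seed,
                            thresh = thresh))
  new_sb_fit("enet", tm$value$beta,
             hyperparams = list(lambda = tm$value$lambda, alpha = alpha),
             runtime_s = tm$elapsed, selection_rule = "nonzero")
}

#' Adaptive lasso with ridge-based weights
#'
#' Two stages: (1) ridge regression with its own cross-validated penalty
#' yields initial estimates `beta_init`; (2) a weighted lasso with penalty
#' multipliers `w_j = 1 / |beta_init_j|` (capped at 1e8 when the initial
#' estimate is exactly zero) and cross-validated lambda. Strong initial
#' signals therefore receive light shrinkage, weak ones heavy shrinkage.
#'
#' @inheritParams fit_lasso
#' @param weight_cap Upper bound for the penalty multipliers.
#' @return An `sb_fit`; `hyperparams` records both stage penalties.
#' @export
fit_alasso <- function(x, y, n_folds = 10, seed = 1L, weight_cap = 1e8,
                       thresh = 1e-10) {
  assert_matrix_response(x, y)
  tm <- timed({
    ridge <- glmnet_cv_fit(x, y, alpha = 0, n_folds, seed, thresh = thresh)
    w <- pmin(1 / abs(ridge$beta), weight_cap)
    stage2 <- glmnet_cv_fit(x, y, alpha = 1, n_folds,
                            seed = child_seed(seed, 2L),
                            penalty_factor = w, thresh = thresh)
    list(beta = stage2$beta, lambda_ridge = ridge$lambda,
         lambda = stage2$lambda, weights = w)
  })
  new_sb_fit("alasso", tm$value$beta,
             hyperparams = list(lambda = tm$value$lambda,
                                lambda_ridge = tm$value$lambda_ridge),
             runtime_s = tm$elapsed, selection_rule = "nonzero",
             extras = list(weights = tm$value$weights))
}
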