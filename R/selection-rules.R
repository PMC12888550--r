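# Rules converting method output into a binary selection vector. Sparse
# solvers select their exact-zero pattern; PIP-carrying methods threshold at
# 0.5; continuous shrinkage posteriors are binarized by 1-D k-means on
# absolute posterior means (these priors never produce exact zeros).

new_selection_result <- function(selected, rule, rule_params = list()) {
  structure(list(selected = as.integer(selected), rule = rule,
                 rule_params = rule_params),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d of %d selected (rule '%s')\n",
              sum(x$selected), length(x$selected), x$rule))
  invisible(x)
}

#' Select the nonzero coefficients
#'
#' For solvers that produce exact zeros (lasso family, SSLASSO, refit-based
#' hybrids). A dense estimate such as ridge would select everything, which
#' is why this rule is reserved for sparse solvers.
#'
#' @param beta_hat Coefficient vector.
#' @return A `selection_result`.
#' @export
select_nonzero <- function(beta_hat) {
  new_selection_result(abs(beta_hat) > 0, "nonzero")
}

#' Select by posterior inclusion probability
#'
#' @param pip Vector of posterior inclusion probabilities in \[0, 1\].
#' @param threshold Inclusive threshold (default 0.5).
#' @return A `selection_result`.
#' @export
select_pip <- function(pip, threshold = 0.5) {
  if (any(pip < 0 | pip > 1)) stopf("PIPs must lie in [0, 1]")
  new_selection_result(pip >= threshold, "pip_threshold",
                       list(threshold = threshold))
}

# Deterministic 1-D k-means: best of one quantile-spread start plus
# additional random starts under a fixed seed.
kmeans_1d <- function(v, k, n_restarts = 20, seed = 1L) {
  uq <- unique(v)
  # stats::kmeans needs k strictly below the number of points and at most
  # the number of distinct values
  if (length(uq) < k || length(v) <= k) return(NULL)
  with_local_seed(seed, {
    centers0 <- quantile(v, probs = seq(0, 1, length.out = k + 2)[2:(k + 1)],
                         names = FALSE)
    if (length(unique(centers0)) < k) centers0 <- sort(sample(uq, k))
    best <- suppressWarnings(
      kmeans(v, centers = matrix(centers0, ncol = 1), iter.max = 100))
    for (r in seq_len(n_restarts - 1)) {
      cand <- suppressWarnings(
        kmeans(v, centers = matrix(sample(uq, k), ncol = 1), iter.max = 100))
      if (cand$tot.withinss < best$tot.withinss) best <- cand
    }
    best
  })
}

#' Binarize magnitudes by k-means clustering
#'
#' Runs 1-D k-means on non-negative magnitudes (absolute posterior means)
#' for k in 2, 3, 4 and picks k by the elbow of the within-cluster sum of
#' squares: the k with the largest relative WCSS drop from k - 1 (with the
#' k = 1 WCSS as baseline; ties favour the smaller k). The cluster with the
#' most members is labelled non-significant and every feature outside it is
#' selected; among equally large clusters the one with the lowest center is
#' the inactive one. All-equal input degenerates to a single cluster and an
#' empty selection.
#'
#' @param values Non-negative magnitudes, length p.
#' @param k_choices Candidate numbers of clusters (default 2:4).
#' @param n_restarts Restarts per k (default 20; one quantile-spread start,
#'   the rest random under `seed`).
#' @param seed Seed making the clustering deterministic.
#' @return A `selection_result` with the chosen `k` in `rule_params`.
#' @export
kmeans_binarize <- function(values, k_choices = 2:4, n_restarts = 20,
                            seed = 1L) {
  if (any(values < 0)) stopf("`values` must be non-negative (pass magnitudes)")
  p <- length(values)
  if (length(unique(values)) == 1) {
    return(new_selection_result(rep(0L, p), "kmeans", list(k = 1L)))
  }
  wcss <- c(sum((values - mean(values))^2))
  fits <- list()
  for (k in k_choices) {
    fit <- kmeans_1d(values, k, n_restarts, seed)
    if (is.null(fit)) break
    fits[[as.character(k)]] <- fit
    wcss <- c(wcss, fit$tot.withinss)
  }
  if (length(fits) == 0) {
    return(new_selection_result(rep(0L, p), "kmeans", list(k = 1L)))
  }
  ks <- as.integer(names(fits))
  drops <- vapply(seq_along(ks), function(i) {
    prev <- wcss[i]
    if (prev <= 0) return(0)
    (prev - wcss[i + 1]) / prev
  }, numeric(1))
  k_best <- ks[which.max(drops)]
  fit <- fits[[as.character(k_best)]]
  sizes <- tabulate(fit$cluster, nbins = k_best)
  centers <- as.numeric(fit$centers)
  inactive <- order(-sizes, centers)[1]
  new_selection_result(fit$cluster != inactive, "kmeans",
                       list(k = k_best))
}

#' Apply a fitted method's declared selection rule
#'
#' Dispatches on the `selection_rule` carried by the fit: nonzero pattern,
#' PIP thresholding, or k-means binarization of absolute posterior means.
#'
#' @param fit An `sb_fit`.
#' @param pip_threshold Threshold for PIP-based rules (default 0.5).
#' @param seed Seed for the k-means rule.
#' @return A `selection_result`.
#' @export
select_features <- function(fit, pip_threshold = 0.5, seed = 1L) {
  stopifnot(inherits(fit, "sb_fit"))
  switch(fit$selection_rule,
    nonzero = select_nonzero(fit$beta_hat),
    pip_threshold = select_pip(fit$pip, pip_threshold),
    kmeans = kmeans_binarize(abs(fit$posterior_mean), seed = seed)
  )
}
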