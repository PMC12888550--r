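# Two-stage procedures: sure independence screening, random-forest
# minimum-depth ranking, forward stepwise selection under BIC, and their
# composites SIS+lasso, RF, and RFSFS.

#' Screening set size
#'
#' The number of features retained by both screening rules,
#' `dn = floor(n / log(n))` (natural logarithm).
#'
#' @param n Sample size.
#' @return Integer screening size.
#' @export
#' @examples
#' screening_size(200) # 37
screening_size <- function(n) {
  as.integer(floor(n / log(n)))
}

new_screening_result <- function(kept, score, dn, method) {
  structure(list(kept = kept, score = score, dn = dn, method = method),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result: %s> kept %d of %d features (dn = %d)\n",
              x$method, length(x$kept), length(x$score), x$dn))
  invisible(x)
}

#' Sure independence screening
#'
#' Ranks features by absolute marginal Pearson correlation with the response
#' and keeps the top `dn = floor(n / log n)`. Constant columns get score 0.
#'
#' @param x Design matrix.
#' @param y Response.
#' @return A `screening_result` with `kept` (indices of the retained
#'   features), `score` (the absolute correlations) and `dn`.
#' @export
sis_screen <- function(x, y) {
  assert_matrix_response(x, y)
  n <- nrow(x)
  if (n < 3) stopf("SIS needs at least 3 rows")
  score <- suppressWarnings(abs(as.numeric(cor(x, y))))
  score[!is.finite(score)] <- 0
  dn <- screening_size(n)
  kept <- order(-score, seq_along(score))[seq_len(min(dn, ncol(x)))]
  new_screening_result(sort(kept), score, dn, "sis")
}

# Average minimal split depth of each feature across a ranger forest. Trees
# in which a feature never splits contribute (maximal observed tree depth in
# the forest) + 1.
ranger_min_depth <- function(forest, p) {
  n_trees <- forest$num.trees
  min_depth <- matrix(NA_real_, n_trees, p)
  max_depth <- 0
  for (t in seq_len(n_trees)) {
    left <- forest$child.nodeIDs[[t]][[1]]
    right <- forest$child.nodeIDs[[t]][[2]]
    sv <- forest$split.varIDs[[t]]
    nn <- length(left)
    depth <- numeric(nn)
    for (i in seq_len(nn)) {
      if (left[i] > 0) {
        depth[left[i] + 1] <- depth[i] + 1
        depth[right[i] + 1] <- depth[i] + 1
      }
    }
    is_split <- left > 0
    if (!any(is_split)) next
    v <- sv[is_split] + 1L
    d_tree <- tapply(depth[is_split], v, min)
    min_depth[t, as.integer(names(d_tree))] <- d_tree
    max_depth <- max(max_depth, max(depth))
  }
  penalty <- max_depth + 1
  colMeans(ifelse(is.na(min_depth), penalty, min_depth))
}

#' Random-forest minimum-depth screening
#'
#' Grows a regression forest (bootstrap rows, random feature subsets per
#' split) and scores every feature by the average depth of its first
#' (shallowest) split across trees; features that never split in a tree are
#' charged the maximal observed tree depth plus one for that tree. The `dn =
#' floor(n / log n)` smallest-average-depth features are retained. Unlike
#' correlation screening, this picks up features associated with the
#' response through nonlinear transforms or interactions.
#'
#' @param x Design matrix.
#' @param y Response.
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split; defaults to the regression-forest
#'   convention `floor(p / 3)`.
#' @param min_node_size Minimal node size (default 5).
#' @param seed Seed for the forest (fixed seed makes the screen
#'   deterministic).
#' @return A `screening_result` (`score` = average minimal depth; smaller is
#'   better).
#' @export
rf_min_depth <- function(x, y, n_trees = 500, mtry = NULL,
                         min_node_size = 5, seed = 1L) {
  assert_matrix_response(x, y)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 10) stopf("random-forest screening needs at least 10 rows")
  if (var(y) == 0) stopf("response is constant; forest cannot be grown")
  mtry <- mtry %||% max(1L, floor(p / 3))
  colnames(x) <- paste0("x", seq_len(p))
  fit <- ranger::ranger(
    x = x, y = as.numeric(y), num.trees = n_trees, mtry = mtry,
    min.node.size = min_node_size, num.threads = 1, seed = seed,
    oob.error = FALSE
  )
  score <- ranger_min_depth(fit$forest, p)
  dn <- screening_size(n)
  kept <- order(score, seq_len(p))[seq_len(min(dn, p))]
  new_screening_result(sort(kept), score, dn, "rf_min_depth")
}

#' Forward stepwise selection under BIC
#'
#' Greedy search: each round evaluates the BIC of adding every unused
#' feature and of dropping every included one, and accepts the single action
#' with the lowest BIC if it improves on the current model, stopping
#' otherwise. `BIC = n log(RSS / n) + k log(n)` with `k` = number of
#' included features + 1 (intercept). An exact zero RSS stops the search
#' (the log is undefined and the fit cannot improve).
#'
#' @param x Candidate design matrix (typically a screened subset; columns
#'   should be linearly independent).
#' @param y Response.
#' @param drop_steps If `TRUE` (default), each round also considers dropping
#'   an included feature (stepwise-both); `FALSE` gives pure forward
#'   selection.
#' @return A `forward_path`: list with `final` (selected column indices of
#'   `x`) and `steps`, a tibble of accepted actions with the BIC after each.
#' @export
forward_bic <- function(x, y, drop_steps = TRUE) {
  assert_matrix_response(x, y)
  n <- nrow(x)
  p <- ncol(x)
  rss_of <- function(idx) {
    if (length(idx) == 0) return(sum(y^2))
    fit <- lm.fit(x[, idx, drop = FALSE], y)
    sum(fit$residuals^2)
  }
  bic_of <- function(rss, k) {
    if (rss <= 0) return(-Inf)
    n * log(rss / n) + (k + 1) * log(n)
  }
  included <- integer(0)
  current_rss <- rss_of(included)
  current_bic <- bic_of(current_rss, 0)
  steps <- list()
  repeat {
    if (current_rss <= 0) break
    best <- list(bic = Inf, action = NA_character_, feature = NA_integer_)
    for (j in setdiff(seq_len(p), included)) {
      b <- bic_of(rss_of(c(included, j)), length(included) + 1)
      if (b < best$bic) best <- list(bic = b, action = "add", feature = j)
    }
    if (drop_steps && length(included) > 0) {
      for (j in included) {
        b <- bic_of(rss_of(setdiff(included, j)), length(included) - 1)
        if (b < best$bic) best <- list(bic = b, action = "drop", feature = j)
      }
    }
    if (!is.finite(best$bic) && best$bic > 0) break
    if (best$bic >= current_bic - 1e-10) break
    included <- if (best$action == "add") {
      c(included, best$feature)
    } else {
      setdiff(included, best$feature)
    }
    current_rss <- rss_of(included)
    current_bic <- best$bic
    steps[[length(steps) + 1]] <- tibble::tibble(
      action = best$action, feature = best$feature, bic = best$bic)
    if (current_bic == -Inf) break
  }
  structure(
    list(final = sort(included),
         steps = if (length(steps)) dplyr::bind_rows(steps) else
           tibble::tibble(action = character(), feature = integer(),
                          bic = double())),
    class = "forward_path"
  )
}

#' @export
print.forward_path <- function(x, ...) {
  cat(sprintf("<forward_path> %d accepted steps, final model of %d features\n",
              nrow(x$steps), length(x$final)))
  invisible(x)
}

# OLS refit over a selected set, zeros elsewhere; rank-deficient columns get
# coefficient 0.
ols_refit <- function(x, y, support) {
  beta <- numeric(ncol(x))
  if (length(support) > 0) {
    cf <- lm.fit(x[, support, drop = FALSE], y)$coefficients
    cf[is.na(cf)] <- 0
    beta[support] <- cf
  }
  beta
}

#' RFSFS: random-forest screening followed by forward selection with BIC
#'
#' The two-stage hybrid selector: a 500-tree minimum-depth screen keeps the
#' `floor(n / log n)` most important features, then forward stepwise
#' regression under BIC (with drop checks) picks the final model, which is
#' refit by ordinary least squares. Requires no oracle information about the
#' true model size.
#'
#' @inheritParams rf_min_depth
#' @param drop_steps Passed to [forward_bic()].
#' @return An `sb_fit` with OLS-refit coefficients on the selected set
#'   (`nonzero` selection rule); `extras` carry the screen and the forward
#'   path.
#' @export
fit_rfsfs <- function(x, y, n_trees = 500, mtry = NULL, min_node_size = 5,
                      seed = 1L, drop_steps = TRUE) {
  tm <- timed({
    screen <- rf_min_depth(x, y, n_trees = n_trees, mtry = mtry,
                           min_node_size = min_node_size, seed = seed)
    path <- forward_bic(x[, screen$kept, drop = FALSE], y,
                        drop_steps = drop_steps)
    support <- screen$kept[path$final]
    list(beta = ols_refit(x, y, support), screen = screen, path = path)
  })
  new_sb_fit("rfsfs", tm$value$beta,
             hyperparams = list(n_trees = n_trees, dn = tm$value$screen$dn),
             runtime_s = tm$elapsed, selection_rule = "nonzero",
             extras = list(screen = tm$value$screen, path = tm$value$path))
}

#' SIS + lasso
#'
#' Sure independence screening keeps the `floor(n / log n)` features with
#' the largest absolute marginal correlations; a cross-validated lasso on
#' the reduced design gives the final sparse fit (zeros outside the screen).
#'
#' @inheritParams fit_lasso
#' @return An `sb_fit` (`nonzero` selection rule) with the screen in
#'   `extras`.
#' @export
fit_sisl <- function(x, y, n_folds = 10, seed = 1L) {
  tm <- timed({
    screen <- sis_screen(x, y)
    sub <- fit_lasso(x[, screen$kept, drop = FALSE], y, n_folds = n_folds,
                     seed = seed)
    beta <- numeric(ncol(x))
    beta[screen$kept] <- sub$beta_hat
    list(beta = beta, screen = screen, lambda = sub$hyperparams$lambda)
  })
  new_sb_fit("sisl", tm$value$beta,
             hyperparams = list(lambda = tm$value$lambda),
             runtime_s = tm$elapsed, selection_rule = "nonzero",
             extras = list(screen = tm$value$screen))
}

#' Standalone random-forest selector
#'
#' Minimum-depth screening as in [rf_min_depth()], with the final selection
#' being the screened features whose average minimal depth lies below the
#' forest-wide mean of the average depths (a depth threshold rather than the
#' full top-`dn` set), refit by OLS.
#'
#' @inheritParams rf_min_depth
#' @return An `sb_fit` (`nonzero` selection rule).
#' @export
fit_rf <- function(x, y, n_trees = 500, mtry = NULL, min_node_size = 5,
                   seed = 1L) {
  tm <- timed({
    screen <- rf_min_depth(x, y, n_trees = n_trees, mtry = mtry,
                           min_node_size = min_node_size, seed = seed)
    support <- intersect(screen$kept,
                         which(screen$score < mean(screen$score)))
    list(beta = ols_refit(x, y, support), screen = screen)
  })
  new_sb_fit("rf", tm$value$beta,
             hyperparams = list(n_trees = n_trees, dn = tm$value$screen$dn),
             runtime_s = tm$elapsed, selection_rule = "nonzero",
             extras = list(screen = tm$value$screen))
}
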