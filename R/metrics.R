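# Evaluation metrics: confusion counts, FDR, FNR, F-score, MSPE.

#' Confusion counts of a selection against the true support
#'
#' @param selection A `selection_result`, binary vector, or integer index
#'   set of selected features.
#' @param support True active indices (1-based).
#' @param p Total number of features.
#' @return List with `tp`, `fp`, `fn`, `tn` (summing to `p`).
#' @export
confusion_counts <- function(selection, support, p) {
  sel_idx <- selection_indices(selection, p)
  if (length(support) > 0 && (min(support) < 1 || max(support) > p)) {
    stopf("support indices must lie in 1..p")
  }
  if (length(sel_idx) > 0 && (min(sel_idx) < 1 || max(sel_idx) > p)) {
    stopf("selected indices must lie in 1..p")
  }
  tp <- length(intersect(sel_idx, support))
  fp <- length(setdiff(sel_idx, support))
  fn <- length(setdiff(support, sel_idx))
  list(tp = tp, fp = fp, fn = fn, tn = as.integer(p) - tp - fp - fn)
}

selection_indices <- function(selection, p) {
  if (inherits(selection, "selection_result")) {
    return(which(selection$selected == 1))
  }
  if (is.logical(selection)) return(which(selection))
  selection <- as.integer(selection)
  # A length-p vector of 0/1 values is read as a binary selection vector;
  # anything else as an index set.
  if (length(selection) == p && all(selection %in% c(0L, 1L))) {
    return(which(selection == 1L))
  }
  selection
}

#' False discovery rate: FP / (TP + FP)
#'
#' Defined as 0 when nothing is selected (no false discoveries were made).
#' @param counts Output of [confusion_counts()].
#' @return FDR in \[0, 1\].
#' @export
fdr <- function(counts) {
  denom <- counts$tp + counts$fp
  if (denom == 0) 0 else counts$fp / denom
}

#' False negative rate: FN / (TP + FN)
#'
#' Defined as 0 when the true support is empty.
#' @param counts Output of [confusion_counts()].
#' @return FNR in \[0, 1\].
#' @export
fnr <- function(counts) {
  denom <- counts$tp + counts$fn
  if (denom == 0) 0 else counts$fn / denom
}

#' F-score: harmonic mean of precision (1 - FDR) and recall (1 - FNR)
#'
#' Defined as 0 when precision + recall = 0. A replicate that misses the
#' entire support (TP = 0, FNR = 1) is degenerate; such replicates are
#' flagged so that completely failing methods can be left unranked
#' downstream.
#'
#' @param counts Output of [confusion_counts()].
#' @return F-score in \[0, 1\], with attribute `degenerate`.
#' @export
fscore <- function(counts) {
  precision <- 1 - fdr(counts)
  recall <- 1 - fnr(counts)
  f <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(f, degenerate = counts$tp == 0)
}

#' Mean squared prediction error of a coefficient vector
#'
#' `mean((y - X beta)^2)`; evaluated on the training rows for in-sample
#' MSPE and on the held-out test rows for out-of-sample MSPE.
#'
#' @param beta_hat Coefficient vector.
#' @param x Design matrix.
#' @param y Response.
#' @return Non-negative scalar.
#' @export
mspe <- function(beta_hat, x, y) {
  assert_matrix_response(x, y)
  mean((y - as.numeric(x %*% beta_hat))^2)
}
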