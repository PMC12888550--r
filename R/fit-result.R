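# Common container for every method's output.

new_sb_fit <- function(method, beta_hat, pip = NULL, posterior_mean = NULL,
                       hyperparams = list(), runtime_s = NA_real_,
                       selection_rule = c("nonzero", "pip_threshold", "kmeans"),
                       extras = list()) {
  selection_rule <- match.arg(selection_rule)
  if (!is.null(pip) && (any(pip < -1e-9) || any(pip > 1 + 1e-9))) {
    stopf("posterior inclusion probabilities outside [0, 1]")
  }
  structure(
    c(list(method = method, beta_hat = as.numeric(beta_hat),
           pip = if (is.null(pip)) NULL else pmin(pmax(pip, 0), 1),
           posterior_mean = posterior_mean,
           hyperparams = hyperparams, runtime_s = runtime_s,
           selection_rule = selection_rule),
      extras),
    class = "sb_fit"
  )
}

#' @export
print.sb_fit <- function(x, ...) {
  nz <- sum(x$beta_hat != 0)
  cat(sprintf("<sb_fit: %s> p = %d, %d nonzero coefficients, selection rule '%s'\n",
              x$method, length(x$beta_hat), nz, x$selection_rule))
  if (!is.null(x$pip)) {
    cat(sprintf("  PIPs available; %d features with PIP >= 0.5\n",
                sum(x$pip >= 0.5)))
  }
  if (is.finite(x$runtime_s)) cat(sprintf("  fit in %.2f s\n", x$runtime_s))
  invisible(x)
}

#' Tidy a fitted selector
#'
#' One row per feature: point estimate, posterior mean and posterior
#' inclusion probability where the method provides them.
#'
#' @param x An `sb_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, and optionally
#'   `posterior_mean`, `pip`.
#' @export
tidy.sb_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = seq_along(x$beta_hat),
    estimate = x$beta_hat
  )
  if (!is.null(x$posterior_mean)) out$posterior_mean <- x$posterior_mean
  if (!is.null(x$pip)) out$pip <- x$pip
  out
}

#' One-row summary of a fitted selector
#'
#' @param x An `sb_fit` object.
#' @param ... Unused.
#' @return A tibble with the method label, number of nonzero coefficients,
#'   selection rule, and runtime.
#' @export
glance.sb_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    p = length(x$beta_hat),
    n_nonzero = sum(x$beta_hat != 0),
    selection_rule = x$selection_rule,
    runtime_s = x$runtime_s
  )
}

timed <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- force(expr)
  list(value = value, elapsed = proc.time()[["elapsed"]] - t0)
}
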