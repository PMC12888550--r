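# Shared machinery for the Gibbs samplers.

# Exact draw from N(Sigma Phi' alpha, Sigma) with Sigma = (Phi'Phi + D^-1)^-1
# and D = diag(d), using the data-augmentation identity whose cost scales as
# n^2 p instead of p^3 -- the right regime for p >> n. Innovations (z, delta)
# can be injected to check algebraic equivalence against a direct
# Cholesky-based draw.
fast_mvn_draw <- function(phi, alpha, d, z = NULL, delta = NULL) {
  n <- nrow(phi)
  p <- ncol(phi)
  if (is.null(z)) z <- rnorm(p)
  if (is.null(delta)) delta <- rnorm(n)
  sd_d <- sqrt(d)
  phisd <- phi * rep(sd_d, each = n)
  u <- sd_d * z
  v <- as.numeric(phisd %*% z) + delta
  m <- tcrossprod(phisd)
  diag(m) <- diag(m) + 1
  r <- chol(m)
  w <- backsolve(r, backsolve(r, alpha - v, transpose = TRUE))
  as.numeric(u + d * crossprod(phi, w))
}

# Reference draw through the p x p posterior precision, same innovations.
direct_mvn_draw <- function(phi, alpha, d, z, delta) {
  p <- ncol(phi)
  prec <- crossprod(phi)
  diag(prec) <- diag(prec) + 1 / d
  sigma <- solve(prec)
  u <- sqrt(d) * z
  as.numeric(sigma %*% crossprod(phi, alpha - delta) +
               (diag(p) - sigma %*% crossprod(phi)) %*% u)
}

# Inverse-gamma draw parameterised by (shape, scale): density proportional to
# x^-(shape+1) exp(-scale / x).
rinvgamma <- function(n, shape, scale) {
  1 / rgamma(n, shape = shape, rate = scale)
}

clip_scale <- function(x, lo = 1e-12, hi = 1e12) {
  pmin(pmax(x, lo), hi)
}

# sigma^2 full conditional: Jeffreys pi(sigma^2) ~ 1/sigma^2 corresponds to
# prior shape/scale (0, 0); a proper inverse-gamma pair can be supplied (used
# by the distributional validation harness).
draw_sigma2 <- function(rss, n_eff, prior = c(0, 0)) {
  clip_scale(rinvgamma(1, shape = prior[1] + n_eff / 2,
                       scale = prior[2] + rss / 2))
}

#' MCMC sampler settings
#'
#' @param n_iter Total number of sampling iterations (default 5000).
#' @param burn_in Iterations discarded before averaging (default 1000).
#' @param thin Keep every `thin`-th post-burn-in draw (default 1).
#' @param seed Integer seed; the chain is a pure function of
#'   (data, config, seed).
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_iter = 5000, burn_in = 1000, thin = 1, seed = 1L) {
  if (burn_in >= n_iter) stopf("`burn_in` (%d) must be below `n_iter` (%d)",
                               burn_in, n_iter)
  if (thin < 1) stopf("`thin` must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_config")
}

check_finite_state <- function(state, iter) {
  bad <- !vapply(state, function(v) all(is.finite(unlist(v))), logical(1))
  if (any(bad)) {
    stopf("sampler diverged at iteration %d (non-finite %s)",
          iter, paste(names(state)[bad], collapse = ", "))
  }
}

# Generic chain driver: `step` advances the sampler state given (x, y),
# `collect` extracts the vectors to average. Returns post-burn-in means and
# an optional trace.
run_chain <- function(state, step, x, y, mcmc, trace = FALSE,
                      check_every = 100) {
  keep <- seq(mcmc$burn_in + 1, mcmc$n_iter, by = mcmc$thin)
  beta_sum <- numeric(ncol(x))
  beta_abs_sum <- numeric(ncol(x))
  sigma2_sum <- 0
  n_kept <- 0
  tr <- if (trace) vector("list", length(keep)) else NULL
  ki <- 0
  for (it in seq_len(mcmc$n_iter)) {
    state <- step(state, x, y)
    if (it %% check_every == 0) check_finite_state(state, it)
    if (it > mcmc$burn_in && ((it - mcmc$burn_in - 1) %% mcmc$thin == 0)) {
      n_kept <- n_kept + 1
      beta_sum <- beta_sum + state$beta
      beta_abs_sum <- beta_abs_sum + abs(state$beta)
      sigma2_sum <- sigma2_sum + state$sigma2
      if (trace) {
        ki <- ki + 1
        tr[[ki]] <- c(beta = state$beta, sigma2 = state$sigma2,
                      tau2 = state$tau2 %||% NA_real_)
      }
    }
  }
  check_finite_state(state, mcmc$n_iter)
  list(posterior_mean = beta_sum / n_kept,
       posterior_mean_abs = beta_abs_sum / n_kept,
       sigma2_mean = sigma2_sum / n_kept,
       final_state = state,
       trace = if (trace) do.call(rbind, tr) else NULL)
}
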