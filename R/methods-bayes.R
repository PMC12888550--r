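# Gibbs samplers for the continuous-shrinkage hierarchies: Bayesian lasso,
# horseshoe, horseshoe+, regularized horseshoe.
#
# All four use the same skeleton: an exact multivariate-normal draw of beta
# given the scales (fast_mvn_draw, cost n^2 p), conjugate inverse-gamma
# updates for sigma^2 under a Jeffreys prior, and the inverse-gamma
# parameter-expansion identity for half-Cauchy scales
#   a ~ C+(0, A)  <=>  a^2 | nu ~ IG(1/2, 1/nu), nu ~ IG(1/2, 1/A^2).
# The regularized horseshoe has non-conjugate scale conditionals; its local
# scales use an independence Metropolis-Hastings step with the plain
# horseshoe conditional as proposal, and tau^2, c^2 use 1-D slice sampling on
# the log scale. Scale parameters are clipped to [1e-12, 1e12] to avoid
# overflow under heavy-tailed noise or near-collinear designs.
#
# Selection for all four is by k-means binarization of absolute posterior
# means (these priors never produce exact zeros).

## ---- Bayesian lasso -------------------------------------------------------

blasso_init <- function(p, opts) {
  list(beta = numeric(p), sigma2 = 1, tau2j = rep(1, p), lambda2 = 1)
}

blasso_step <- function(state, x, y, opts) {
  n <- nrow(x)
  p <- ncol(x)
  sig <- sqrt(state$sigma2)
  d <- clip_scale(state$sigma2 * state$tau2j)
  state$beta <- fast_mvn_draw(x / sig, y / sig, d)
  rss <- sum((y - x %*% state$beta)^2)
  state$sigma2 <- clip_scale(rinvgamma(
    1, shape = opts$sigma2_prior[1] + (n + p) / 2,
    scale = opts$sigma2_prior[2] + rss / 2 +
      sum(state$beta^2 / state$tau2j) / 2))
  mu <- sqrt(state$lambda2 * state$sigma2 / pmax(state$beta^2, 1e-24))
  state$tau2j <- clip_scale(1 / rinvgaussian(p, mu, state$lambda2))
  state$lambda2 <- rgamma(1, shape = opts$lambda2_prior[1] + p,
                          rate = opts$lambda2_prior[2] + sum(state$tau2j) / 2)
  state
}

blasso_prior_draw <- function(p, opts) {
  lambda2 <- rgamma(1, opts$lambda2_prior[1], rate = opts$lambda2_prior[2])
  tau2j <- rexp(p, rate = lambda2 / 2)
  sigma2 <- rinvgamma(1, opts$sigma2_prior[1], opts$sigma2_prior[2])
  list(beta = rnorm(p, 0, sqrt(sigma2 * tau2j)), sigma2 = sigma2,
       tau2j = tau2j, lambda2 = lambda2)
}

#' Bayesian lasso Gibbs sampler
#'
#' Scale-mixture representation of the Laplace prior: `beta_j | sigma^2,
#' tau_j^2 ~ N(0, sigma^2 tau_j^2)` with exponential mixing on the
#' per-coefficient variances, a Gamma hyperprior on `lambda^2` and a Jeffreys
#' prior on `sigma^2`. The point estimate is the post-burn-in posterior mean.
#'
#' @param x Standardized design matrix.
#' @param y Centered response.
#' @param mcmc An [mcmc_config()].
#' @param lambda2_prior Shape/rate of the Gamma prior on `lambda^2`
#'   (default c(1, 1), weakly informative on standardized data).
#' @param sigma2_prior Shape/scale of the inverse-gamma prior on `sigma^2`;
#'   the default c(0, 0) is the Jeffreys prior.
#' @return An `sb_fit` with `posterior_mean` as the selection carrier
#'   (k-means rule).
#' @export
fit_blasso <- function(x, y, mcmc = mcmc_config(),
                       lambda2_prior = c(1, 1), sigma2_prior = c(0, 0),
                       trace = FALSE) {
  assert_matrix_response(x, y)
  opts <- list(lambda2_prior = lambda2_prior, sigma2_prior = sigma2_prior)
  tm <- timed(with_local_seed(mcmc$seed, {
    run_chain(blasso_init(ncol(x), opts),
              function(s, x, y) blasso_step(s, x, y, opts), x, y, mcmc,
              trace = trace)
  }))
  res <- tm$value
  new_sb_fit("blasso", res$posterior_mean,
             posterior_mean = res$posterior_mean,
             hyperparams = list(sigma2 = res$sigma2_mean,
                                lambda2 = res$final_state$lambda2),
             runtime_s = tm$elapsed, selection_rule = "kmeans",
             extras = list(posterior_mean_abs = res$posterior_mean_abs,
                           trace = res$trace))
}

## ---- Horseshoe ------------------------------------------------------------

hs_init <- function(p, opts) {
  list(beta = numeric(p), sigma2 = 1, tau2 = opts$tau2_fixed %||% 1,
       lam2 = rep(1, p), nu = rep(1, p), xi = 1)
}

hs_step <- function(state, x, y, opts) {
  n <- nrow(x)
  p <- ncol(x)
  sig <- sqrt(state$sigma2)
  d <- clip_scale(state$tau2 * state$lam2)
  state$beta <- fast_mvn_draw(x / sig, y / sig, d)
  rss <- sum((y - x %*% state$beta)^2)
  state$sigma2 <- draw_sigma2(rss, n, opts$sigma2_prior)
  state$lam2 <- clip_scale(rinvgamma(
    p, 1, 1 / state$nu + state$beta^2 / (2 * state$tau2)))
  state$nu <- rinvgamma(p, 1, 1 + 1 / state$lam2)
  if (is.null(opts$tau2_fixed)) {
    state$tau2 <- clip_scale(rinvgamma(
      1, (p + 1) / 2, 1 / state$xi + sum(state$beta^2 / state$lam2) / 2))
    state$xi <- rinvgamma(1, 1, 1 + 1 / state$tau2)
  }
  state
}

hs_prior_draw <- function(p, opts) {
  nu <- rinvgamma(p, 1 / 2, 1)
  lam2 <- rinvgamma(p, 1 / 2, 1 / nu)
  xi <- rinvgamma(1, 1 / 2, 1)
  tau2 <- rinvgamma(1, 1 / 2, 1 / xi)
  sigma2 <- rinvgamma(1, opts$sigma2_prior[1], opts$sigma2_prior[2])
  list(beta = rnorm(p, 0, sqrt(tau2 * lam2)), sigma2 = sigma2, tau2 = tau2,
       lam2 = lam2, nu = nu, xi = xi)
}

#' Horseshoe Gibbs sampler
#'
#' Global-local shrinkage prior `beta_j ~ N(0, tau^2 lambda_j^2)` with
#' half-Cauchy local scales `lambda_j ~ C+(0, 1)` and global scale
#' `tau ~ C+(0, 1)`, Jeffreys `sigma^2`. Half-Cauchy scales are sampled
#' through the inverse-gamma parameter-expansion identity; beta is drawn
#' exactly with the fast n^2 p conditional sampler.
#'
#' @inheritParams fit_blasso
#' @param tau2_fixed Optionally freeze the global scale at a given value
#'   (used for degenerate-limit checks).
#' @return An `sb_fit` (k-means selection rule).
#' @export
fit_horseshoe <- function(x, y, mcmc = mcmc_config(), sigma2_prior = c(0, 0),
                          tau2_fixed = NULL, trace = FALSE) {
  assert_matrix_response(x, y)
  opts <- list(sigma2_prior = sigma2_prior, tau2_fixed = tau2_fixed)
  tm <- timed(with_local_seed(mcmc$seed, {
    run_chain(hs_init(ncol(x), opts),
              function(s, x, y) hs_step(s, x, y, opts), x, y, mcmc,
              trace = trace)
  }))
  res <- tm$value
  new_sb_fit("horseshoe", res$posterior_mean,
             posterior_mean = res$posterior_mean,
             hyperparams = list(sigma2 = res$sigma2_mean,
                                tau2 = res$final_state$tau2),
             runtime_s = tm$elapsed, selection_rule = "kmeans",
             extras = list(posterior_mean_abs = res$posterior_mean_abs,
                           trace = res$trace))
}

## ---- Horseshoe+ -----------------------------------------------------------

hsp_init <- function(p, opts) {
  list(beta = numeric(p), sigma2 = 1, tau2 = 1, lam2 = rep(1, p),
       nu = rep(1, p), eta2 = rep(1, p), phi = rep(1, p), xi = 1)
}

hsp_step <- function(state, x, y, opts) {
  n <- nrow(x)
  p <- ncol(x)
  sig <- sqrt(state$sigma2)
  d <- clip_scale(state$tau2 * state$lam2)
  state$beta <- fast_mvn_draw(x / sig, y / sig, d)
  rss <- sum((y - x %*% state$beta)^2)
  state$sigma2 <- draw_sigma2(rss, n, opts$sigma2_prior)
  state$lam2 <- clip_scale(rinvgamma(
    p, 1, 1 / state$nu + state$beta^2 / (2 * state$tau2)))
  if (isTRUE(opts$eta_fixed)) {
    # Freezing eta_j = 1 reduces the extra half-Cauchy layer to the plain
    # horseshoe conditionals (nu_j | lam_j^2 ~ IG(1, 1 + 1/lam_j^2)).
    state$nu <- rinvgamma(p, 1, 1 / state$lam2 + 1)
  } else {
    state$nu <- rinvgamma(p, 1, 1 / state$lam2 + 1 / state$eta2)
    state$eta2 <- clip_scale(rinvgamma(p, 1, 1 / state$nu + 1 / state$phi))
    state$phi <- rinvgamma(p, 1, 1 + 1 / state$eta2)
  }
  state$tau2 <- clip_scale(rinvgamma(
    1, (p + 1) / 2, 1 / state$xi + sum(state$beta^2 / state$lam2) / 2))
  state$xi <- rinvgamma(1, 1, 1 + 1 / state$tau2)
  state
}

hsp_prior_draw <- function(p, opts) {
  phi <- rinvgamma(p, 1 / 2, 1)
  eta2 <- rinvgamma(p, 1 / 2, 1 / phi)
  nu <- rinvgamma(p, 1 / 2, 1 / eta2)
  lam2 <- rinvgamma(p, 1 / 2, 1 / nu)
  xi <- rinvgamma(1, 1 / 2, 1)
  tau2 <- rinvgamma(1, 1 / 2, 1 / xi)
  sigma2 <- rinvgamma(1, opts$sigma2_prior[1], opts$sigma2_prior[2])
  list(beta = rnorm(p, 0, sqrt(tau2 * lam2)), sigma2 = sigma2, tau2 = tau2,
       lam2 = lam2, nu = nu, eta2 = eta2, phi = phi, xi = xi)
}

#' Horseshoe+ Gibbs sampler
#'
#' Adds a second half-Cauchy layer to the horseshoe:
#' `lambda_j | eta_j ~ C+(0, eta_j)`, `eta_j ~ C+(0, 1)`, which lets the
#' local prior shape adapt per feature and further lightens shrinkage of
#' large effects. Sampled by nested inverse-gamma parameter expansion.
#'
#' @inheritParams fit_blasso
#' @param eta_fixed If `TRUE`, freezes `eta_j = 1`, reproducing the plain
#'   horseshoe conditionals (reduction check).
#' @return An `sb_fit` (k-means selection rule).
#' @export
fit_horseshoe_plus <- function(x, y, mcmc = mcmc_config(),
                               sigma2_prior = c(0, 0), eta_fixed = FALSE) {
  assert_matrix_response(x, y)
  opts <- list(sigma2_prior = sigma2_prior, eta_fixed = eta_fixed)
  tm <- timed(with_local_seed(mcmc$seed, {
    run_chain(hsp_init(ncol(x), opts),
              function(s, x, y) hsp_step(s, x, y, opts), x, y, mcmc)
  }))
  res <- tm$value
  new_sb_fit("horseshoe_plus", res$posterior_mean,
             posterior_mean = res$posterior_mean,
             hyperparams = list(sigma2 = res$sigma2_mean,
                                tau2 = res$final_state$tau2),
             runtime_s = tm$elapsed, selection_rule = "kmeans",
             extras = list(posterior_mean_abs = res$posterior_mean_abs))
}

## ---- Regularized horseshoe ------------------------------------------------

rhs_reg_scale <- function(lam2, tau2, c2) {
  c2 * lam2 / (c2 + tau2 * lam2)
}

rhs_loglik_scales <- function(beta2, lam2, tau2, c2) {
  v <- clip_scale(tau2 * rhs_reg_scale(lam2, tau2, c2))
  sum(-0.5 * log(v) - beta2 / (2 * v))
}

rhs_init <- function(p, opts) {
  list(beta = numeric(p), sigma2 = 1, tau2 = opts$tau0^2, lam2 = rep(1, p),
       nu = rep(1, p), c2 = 4)
}

rhs_step <- function(state, x, y, opts) {
  n <- nrow(x)
  p <- ncol(x)
  sig <- sqrt(state$sigma2)
  d <- clip_scale(state$tau2 * rhs_reg_scale(state$lam2, state$tau2, state$c2))
  state$beta <- fast_mvn_draw(x / sig, y / sig, d)
  rss <- sum((y - x %*% state$beta)^2)
  state$sigma2 <- draw_sigma2(rss, n, opts$sigma2_prior)
  beta2 <- state$beta^2

  # Local scales: independence MH with the plain-horseshoe IG conditional as
  # proposal; the regularization factor enters only through the acceptance
  # ratio sqrt((c2 + tau2 x') / (c2 + tau2 x)).
  b <- 1 / state$nu + beta2 / (2 * state$tau2)
  prop <- clip_scale(rinvgamma(p, 1, b))
  log_acc <- 0.5 * (log(state$c2 + state$tau2 * prop) -
                    log(state$c2 + state$tau2 * state$lam2))
  accept <- log(runif(p)) < log_acc
  state$lam2[accept] <- prop[accept]
  state$nu <- rinvgamma(p, 1, 1 + 1 / state$lam2)

  # Global scale tau ~ C+(0, tau0) and slab scale c^2 ~ IG(shape, scale):
  # 1-D slice updates on the log scale.
  lam2 <- state$lam2
  c2 <- state$c2
  tau0 <- opts$tau0
  log_f_tau <- function(u) {
    t2 <- exp(u)
    u / 2 - log(tau0^2 + t2) + rhs_loglik_scales(beta2, lam2, t2, c2)
  }
  state$tau2 <- clip_scale(exp(slice_update(log(state$tau2), log_f_tau)))
  tau2 <- state$tau2
  log_f_c <- function(u) {
    cc <- exp(u)
    -opts$c2_prior[1] * u - opts$c2_prior[2] / cc +
      rhs_loglik_scales(beta2, lam2, tau2, cc)
  }
  state$c2 <- clip_scale(exp(slice_update(log(state$c2), log_f_c)))
  state
}

rhs_prior_draw <- function(p, opts) {
  nu <- rinvgamma(p, 1 / 2, 1)
  lam2 <- rinvgamma(p, 1 / 2, 1 / nu)
  tau2 <- (opts$tau0 * tan(pi * runif(1) / 2))^2
  c2 <- rinvgamma(1, opts$c2_prior[1], opts$c2_prior[2])
  sigma2 <- rinvgamma(1, opts$sigma2_prior[1], opts$sigma2_prior[2])
  list(beta = rnorm(p, 0, sqrt(tau2 * rhs_reg_scale(lam2, tau2, c2))),
       sigma2 = sigma2, tau2 = tau2, lam2 = lam2, nu = nu, c2 = c2)
}

#' Regularized horseshoe Gibbs sampler
#'
#' Horseshoe with a finite slab: `beta_j ~ N(0, tau^2 lambda_tilde_j^2)`
#' where `lambda_tilde_j^2 = c^2 lambda_j^2 / (c^2 + tau^2 lambda_j^2)`, so
#' even the largest coefficients are regularized towards a `N(0, c^2)` slab.
#' The global prior is `tau ~ C+(0, tau0)` with `tau0^2 = p0 / (n - p0)`
#' derived from the expected model size `p0`, and `c^2` carries a weakly
#' informative inverse-gamma prior (shape 2, scale 8 by default). Local
#' scales are updated by independence MH against the plain-horseshoe
#' conditional; `tau^2` and `c^2` by slice sampling.
#'
#' @inheritParams fit_blasso
#' @param p0 Expected number of active coefficients (0 < p0 < n).
#' @param c2_prior Shape/scale of the inverse-gamma prior on `c^2`.
#' @return An `sb_fit` (k-means selection rule) with `tau0` recorded in
#'   `hyperparams`.
#' @export
fit_reg_horseshoe <- function(x, y, mcmc = mcmc_config(), p0 = 10,
                              c2_prior = c(2, 8), sigma2_prior = c(0, 0)) {
  assert_matrix_response(x, y)
  n <- nrow(x)
  if (p0 <= 0 || p0 >= n) stopf("`p0` must satisfy 0 < p0 < n (got %g)", p0)
  tau0 <- sqrt(p0 / (n - p0))
  opts <- list(sigma2_prior = sigma2_prior, c2_prior = c2_prior, tau0 = tau0)
  tm <- timed(with_local_seed(mcmc$seed, {
    run_chain(rhs_init(ncol(x), opts),
              function(s, x, y) rhs_step(s, x, y, opts), x, y, mcmc)
  }))
  res <- tm$value
  new_sb_fit("reg_horseshoe", res$posterior_mean,
             posterior_mean = res$posterior_mean,
             hyperparams = list(sigma2 = res$sigma2_mean, tau0 = tau0,
                                tau2 = res$final_state$tau2,
                                c2 = res$final_state$c2),
             runtime_s = tm$elapsed, selection_rule = "kmeans",
             extras = list(posterior_mean_abs = res$posterior_mean_abs))
}
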