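# Unit tests for the shrinkage Gibbs samplers. The full joint-distribution
# (Geweke-style) validation lives in the acceptance suite; here we test the
# conditional sampler algebra, small-problem calibration, reductions and
# determinism.

test_that("fast n^2 p beta draw equals the direct Cholesky route", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    p <- sample(2:15, 1)
    phi <- matrix(rnorm(n * p), n, p)
    alpha <- rnorm(n)
    d <- rexp(p) * 10^runif(p, -3, 3)
    z <- rnorm(p)
    delta <- rnorm(n)
    a <- sparsebench:::fast_mvn_draw(phi, alpha, d, z, delta)
    b <- sparsebench:::direct_mvn_draw(phi, alpha, d, z, delta)
    expect_equal(a, b, tolerance = 1e-8)
  }
})

test_that("Bayesian lasso posterior mean matches quadrature on a p=1 toy", {
  set.seed(22)
  n <- 15
  x <- matrix(rnorm(n), n, 1)
  x <- x / sd(x)
  y <- as.numeric(x * 1.2) + 0.8 * rnorm(n)
  y <- y - mean(y)

  # Oracle: integrate beta analytically given (sigma2, tau2); tau2's
  # exponential-gamma mixture marginal is (1/2) / (1 + tau2/2)^2 for the
  # Gamma(1, 1) hyperprior on lambda^2; integrate (sigma2, tau2) on a grid.
  xtx <- sum(x^2)
  xty <- sum(x * y)
  yty <- sum(y^2)
  post_num <- 0
  post_den <- 0
  s2_grid <- exp(seq(log(0.05), log(20), length.out = 400))
  t2_grid <- exp(seq(log(1e-6), log(400), length.out = 400))
  for (s2 in s2_grid) {
    prec <- xtx / s2 + 1 / (s2 * t2_grid)
    m <- (xty / s2) / prec
    # marginal likelihood of y given scales (beta integrated out)
    logml <- -n / 2 * log(2 * pi * s2) - 0.5 * log(s2 * t2_grid) -
      0.5 * log(prec) - 0.5 * (yty / s2 - m^2 * prec)
    w <- exp(logml) * (1 / s2) * 0.5 / (1 + t2_grid / 2)^2 *
      s2 * t2_grid  # log-grid Jacobians
    post_num <- post_num + sum(w * m)
    post_den <- post_den + sum(w)
  }
  oracle_mean <- post_num / post_den

  fit <- fit_blasso(x, y, mcmc_config(30000, 5000, seed = 2),
                    lambda2_prior = c(1, 1))
  expect_equal(fit$posterior_mean, oracle_mean, tolerance = 5e-3)
})

test_that("samplers are deterministic given the chain seed", {
  toy <- make_toy(40, 6, c(2, rep(0, 5)), seed = 23)
  for (f in list(fit_blasso, fit_horseshoe, fit_horseshoe_plus)) {
    a <- f(toy$x, toy$y, mcmc_config(300, 100, seed = 9))
    b <- f(toy$x, toy$y, mcmc_config(300, 100, seed = 9))
    expect_identical(a$posterior_mean, b$posterior_mean)
  }
  a <- fit_reg_horseshoe(toy$x, toy$y, mcmc_config(300, 100, seed = 9), p0 = 2)
  b <- fit_reg_horseshoe(toy$x, toy$y, mcmc_config(300, 100, seed = 9), p0 = 2)
  expect_identical(a$posterior_mean, b$posterior_mean)
})

test_that("null data yields posterior means within 3 posterior SDs of zero", {
  set.seed(24)
  x <- scale(matrix(rnorm(100 * 5), 100, 5))
  y <- rnorm(100)
  y <- y - mean(y)
  fit <- fit_blasso(x, y, mcmc_config(4000, 1000, seed = 3), trace = TRUE)
  post_sd <- apply(fit$trace[, 1:5], 2, sd)
  expect_true(all(abs(fit$posterior_mean) < 3 * post_sd))
})

test_that("horseshoe recovers a strong signal and shrinks the nulls", {
  toy <- make_toy(200, 50, c(10, rep(0, 49)), sigma = 0.5, seed = 25)
  fit <- fit_horseshoe(toy$x, toy$y, mcmc_config(3000, 1000, seed = 4))
  expect_lt(abs(fit$posterior_mean[1] - 10) / 10, 0.1)
  expect_lt(max(abs(fit$posterior_mean[-1])), 0.1)
  sel <- select_features(fit)
  expect_identical(which(sel$selected == 1), 1L)
})

test_that("freezing the global scale near zero pins beta at zero", {
  toy <- make_toy(50, 8, c(3, rep(0, 7)), seed = 26)
  fit <- fit_horseshoe(toy$x, toy$y, mcmc_config(500, 100, seed = 5),
                       tau2_fixed = 1e-12)
  expect_lt(max(abs(fit$posterior_mean)), 1e-3)
})

test_that("horseshoe+ with frozen eta reproduces the horseshoe conditionals", {
  toy <- make_toy(30, 5, c(1, rep(0, 4)), seed = 27)
  opts_hs <- list(sigma2_prior = c(0, 0), tau2_fixed = NULL)
  opts_hsp <- list(sigma2_prior = c(0, 0), eta_fixed = TRUE)
  s_hs <- sparsebench:::hs_init(5, opts_hs)
  s_hsp <- sparsebench:::hsp_init(5, opts_hsp)
  for (i in 1:20) {
    set.seed(1000 + i)
    s_hs <- sparsebench:::hs_step(s_hs, toy$x, toy$y, opts_hs)
    set.seed(1000 + i)
    s_hsp <- sparsebench:::hsp_step(s_hsp, toy$x, toy$y, opts_hsp)
    expect_equal(s_hs$beta, s_hsp$beta, tolerance = 1e-12)
    expect_equal(s_hs$lam2, s_hsp$lam2, tolerance = 1e-12)
    expect_equal(s_hs$tau2, s_hsp$tau2, tolerance = 1e-12)
  }
})

test_that("horseshoe+ shrinks a strong signal no more than the horseshoe", {
  diffs <- numeric(10)
  for (s in 1:10) {
    toy <- make_toy(60, 10, c(6, rep(0, 9)), sigma = 1, seed = 300 + s)
    hs <- fit_horseshoe(toy$x, toy$y, mcmc_config(1200, 400, seed = s))
    hsp <- fit_horseshoe_plus(toy$x, toy$y, mcmc_config(1200, 400, seed = s))
    diffs[s] <- abs(hsp$posterior_mean[1]) - abs(hs$posterior_mean[1])
  }
  # heavier tails: on average the large effect is shrunk less (or equally)
  expect_gt(mean(diffs), -0.01)
})

test_that("regularized-horseshoe scale algebra matches its closed forms", {
  # tau0^2 = p0 / (n - p0)
  toy <- make_toy(200, 5, rep(0, 5), seed = 28)
  fit <- fit_reg_horseshoe(toy$x, toy$y, mcmc_config(200, 50, seed = 1),
                           p0 = 10)
  expect_equal(fit$hyperparams$tau0^2, 10 / 190, tolerance = 1e-12)
  expect_error(fit_reg_horseshoe(toy$x, toy$y, p0 = 200), "p0")

  lam2 <- c(1e-6, 0.1, 1, 50, 1e6)
  # c -> Inf limit recovers the plain horseshoe scales
  expect_equal(sparsebench:::rhs_reg_scale(lam2, tau2 = 0.5, c2 = 1e14),
               lam2, tolerance = 1e-6)
  # tau2 lam2 >> c2 regime: prior variance tends to c2 (prior SD -> c)
  expect_equal(0.5 * sparsebench:::rhs_reg_scale(1e12, tau2 = 0.5, c2 = 4),
               4, tolerance = 1e-3)
  # regularized scale never exceeds min(lam2, c2/tau2)
  for (t2 in c(0.01, 1, 100)) {
    lt <- sparsebench:::rhs_reg_scale(lam2, t2, c2 = 2)
    expect_true(all(lt <= pmin(lam2, 2 / t2) + 1e-12))
  }
})

test_that("shrinkage factor is non-increasing in the global scale", {
  lam2 <- 2.5
  c2 <- 4
  t2_grid <- exp(seq(-8, 8, length.out = 100))
  vals <- sparsebench:::rhs_reg_scale(lam2, t2_grid, c2)
  expect_true(all(diff(vals) <= 1e-14))
})

test_that("RHS local-scale MH step targets its conditional density", {
  # Other parameters fixed; 20k MH updates of lambda^2 must reproduce the
  # analytic conditional f(x) ~ x^-2 (c2 + tau2 x)^(1/2) exp(-b/x).
  set.seed(29)
  nu <- 0.7
  beta2 <- 0.9
  tau2 <- 0.3
  c2 <- 2.5
  b <- 1 / nu + beta2 / (2 * tau2)
  n_draws <- 20000
  x_cur <- 1
  draws <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    prop <- 1 / rgamma(1, 1, rate = b)
    if (log(runif(1)) < 0.5 * (log(c2 + tau2 * prop) -
                               log(c2 + tau2 * x_cur))) {
      x_cur <- prop
    }
    draws[i] <- x_cur
  }
  grid <- exp(seq(log(1e-4), log(1e4), length.out = 20000))
  dens <- grid^(-2) * sqrt(c2 + tau2 * grid) * exp(-b / grid) * grid
  cdf <- cumsum(dens) / sum(dens)
  emp <- ecdf(draws)(grid)
  expect_lt(max(abs(emp - cdf)), 0.05)
})

test_that("divergent states are reported with an iteration index", {
  toy <- make_toy(20, 3, rep(0, 3), seed = 30)
  state <- sparsebench:::hs_init(3, list(sigma2_prior = c(0, 0)))
  state$beta <- c(NaN, 0, 0)
  expect_error(sparsebench:::check_finite_state(state, 42), "iteration 42")
})
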