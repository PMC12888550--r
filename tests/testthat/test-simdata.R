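test_that("config validation rejects ill-posed settings", {
  expect_error(sim_config(snr = NULL, sigma_fixed = NULL), "exactly one")
  expect_error(sim_config(snr = 1, sigma_fixed = 1), "exactly one")
  expect_error(sim_config(sparsity = 0, snr = 1), "sparsity")
  expect_error(sim_config(sparsity = 1, snr = 1), "sparsity")
  expect_error(sim_config(p = 5, design = "nonlinear", snr = 1,
                          sparsity = 0.5), "p >= 6")
  expect_error(sim_config(rho3 = 1, snr = 1), "rho")
  expect_error(sim_config(n_test = 0, snr = 1), "n_test")
})

test_that("SNR calibration is exact on the realized design", {
  for (seed in 1:5) {
    cfg <- sim_config(n = 100, p = 80, sparsity = 0.1, snr = c(1, 5)[seed %% 2 + 1],
                      seed = seed)
    d <- generate_dataset(cfg)
    snr_emp <- var(as.numeric(d$x_train %*% d$coef$beta)) / d$sigma^2
    expect_equal(snr_emp, cfg$snr, tolerance = 1e-10)
  }
})

test_that("calibrate_noise does the stated arithmetic", {
  x <- matrix(seq_len(20), ncol = 1)
  x <- x * sqrt(5 / var(as.numeric(x)))  # Var(x * 1) = 5 exactly
  expect_equal(calibrate_noise(x, 1, snr = 5), 1, tolerance = 1e-12)
  x2 <- x * sqrt(2 / 5)
  expect_equal(calibrate_noise(x2, 1, snr = 1), sqrt(2), tolerance = 1e-12)
  expect_error(calibrate_noise(matrix(1, 10, 1), 1, snr = 1), "zero")
})

test_that("coefficient regimes have the stated supports, magnitudes, signs", {
  for (seed in 1:10) {
    set.seed(seed)
    cfg <- sim_config(n = 50, p = 1000, sparsity = 0.01, snr = 1, seed = seed)
    co <- make_coefficients(cfg)
    expect_length(co$support, 10)
    expect_setequal(which(co$beta != 0), co$support)
    expect_true(all(abs(co$beta[co$support]) == 1))
    expect_lte(abs(sum(co$beta > 0) - sum(co$beta < 0)), 1)

    cfg1 <- sim_config(n = 50, p = 200, snr = 1, coef_regime = "scenario1",
                       seed = seed)
    set.seed(seed)
    co1 <- make_coefficients(cfg1)
    expect_length(co1$support, 10)
    mags <- sort(abs(co1$beta[co1$support]))
    expect_equal(mags, sort(rep_len(c(1, 0.5, 0.3, 0.2), 10)))

    cfg2 <- sim_config(n = 50, p = 200, snr = 1, coef_regime = "scenario2",
                       seed = seed)
    set.seed(seed)
    co2 <- make_coefficients(cfg2)
    expect_length(co2$support, 30)
    expect_true(all(abs(co2$beta[co2$support]) >= 0.2 &
                      abs(co2$beta[co2$support]) <= 0.7))
    expect_lte(abs(sum(co2$beta > 0) - sum(co2$beta < 0)), 1)
  }
})

test_that("smallest support degenerates gracefully and empty support errors", {
  set.seed(1)
  cfg <- sim_config(n = 50, p = 100, sparsity = 0.01, snr = 1)
  co <- make_coefficients(cfg)
  expect_length(co$support, 1)
  cfg_bad <- sim_config(n = 50, p = 20, sparsity = 0.01, snr = 1)
  expect_error(make_coefficients(cfg_bad), "no active")
})

test_that("binary design draws Bernoulli(0.7) entries", {
  set.seed(2)
  cfg <- sim_config(n = 10000, p = 20, sparsity = 0.1, snr = 1,
                    design = "binary_indep")
  x <- make_design(cfg, 10000)
  expect_true(all(x %in% c(0, 1)))
  se <- sqrt(0.7 * 0.3 / 10000)
  expect_true(all(abs(colMeans(x) - 0.7) < 3 * se))
})

test_that("correlated design reproduces the block correlations", {
  set.seed(3)
  cfg <- sim_config(n = 20000, p = 50, sparsity = 0.1, snr = 1,
                    design = "correlated")
  support <- 1:5
  x <- make_design(cfg, 20000, support = support)
  inact <- setdiff(1:50, support)
  se <- 1 / sqrt(20000)  # correlation SE scale
  expect_lt(abs(cor(x[, inact[1]], x[, inact[2]]) - 0.8), 3 * se * (1 - 0.8^2) * 3)
  expect_lt(abs(cor(x[, 1], x[, 2]) - 0.3), 0.03)
  expect_lt(abs(cor(x[, 1], x[, inact[1]]) - 0.5), 0.03)
})

test_that("block correlation matrices are positive definite after repair", {
  # small blocks: no repair needed, exact targets
  bc <- sparsebench:::block_correlation(60, 10, 0.3, 0.5, 0.8)
  expect_false(bc$repaired)
  expect_gt(min(eigen(bc$sigma, symmetric = TRUE, only.values = TRUE)$values), 0)
  # large active block makes the matrix indefinite; repair stays close
  bc2 <- sparsebench:::block_correlation(200, 80, 0.3, 0.5, 0.8)
  expect_true(bc2$repaired)
  expect_gt(min(eigen(bc2$sigma, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_lte(bc2$max_dev, 0.05)
  expect_equal(diag(bc2$sigma), rep(1, 200), tolerance = 1e-12)
})

test_that("noise families behave as declared", {
  set.seed(4)
  x <- matrix(rnorm(200), 100, 2)
  # null signal: pure noise
  y <- make_response(x, c(0, 0), "gaussian", sigma = 1)
  expect_equal(length(y), 100)
  # large-n variance check
  set.seed(5)
  xl <- matrix(rnorm(50000), 50000, 1)
  yl <- make_response(xl, 2, "gaussian", sigma = 3)
  ratio <- var(yl - 2 * xl[, 1]) / 9
  expect_lt(abs(ratio - 1), 3 * sqrt(2 / 50000))
  # t2 noise: realized SD matches sigma exactly, tails far heavier than
  # any Gaussian sample of that size
  set.seed(6)
  yt <- make_response(xl, 2, "t2", sigma = 3)
  eps <- yt - 2 * xl[, 1]
  expect_equal(sd(eps), 3, tolerance = 1e-12)
  kurt <- mean(eps^4) / mean(eps^2)^2
  expect_gt(kurt, 10)
  expect_error(make_response(x, c(0, 0), "gaussian", sigma = 0), "positive")
})

test_that("nonlinear design has the closed-form mean and fixed support", {
  x1 <- matrix(c(0, 0, 1, 1, 1, 0), 1, 6)
  expect_equal(nonlinear_mean(x1), 1)
  x2 <- matrix(c(0.5, 1, 0, 1, 0, 2), 1, 6)
  expect_equal(nonlinear_mean(x2), 3)
  cfg <- sim_config(n = 50, p = 10, sparsity = 0.1, snr = 2,
                    design = "nonlinear")
  d <- generate_dataset(cfg)
  expect_identical(d$coef$support, 1:6)
  expect_true(all(d$coef$beta == 0))
  mu <- nonlinear_mean(d$x_train)
  expect_equal(var(mu) / d$sigma^2, 2, tolerance = 1e-10)
})

test_that("generation is a pure function of (config, seed)", {
  cfg <- sim_config(n = 60, p = 40, sparsity = 0.1, snr = 1, seed = 9)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  cfg2 <- cfg
  cfg2$seed <- 10L
  d3 <- generate_dataset(cfg2)
  expect_false(identical(d1$coef$support, d3$coef$support))
  # caller's RNG stream is untouched
  set.seed(123)
  u1 <- runif(1)
  set.seed(123)
  invisible(generate_dataset(cfg))
  expect_identical(runif(1), u1)
})

test_that("default benchmark dimensions are n=200, p=1000, n_test=50", {
  cfg <- sim_config(snr = 1)
  expect_identical(c(cfg$n, cfg$p, cfg$n_test), c(200L, 1000L, 50L))
})

test_that("standardization maps train to mean 0 / unit variance and reuses the map", {
  cfg <- sim_config(n = 80, p = 30, sparsity = 0.1, snr = 1, seed = 2)
  d <- standardize_dataset(generate_dataset(cfg))
  expect_equal(unname(colMeans(d$x_train)), rep(0, 30), tolerance = 1e-12)
  expect_equal(unname(apply(d$x_train, 2, sd)), rep(1, 30), tolerance = 1e-12)
  expect_equal(mean(d$y_train), 0, tolerance = 1e-12)
  # test set transformed with the *train* map, not its own
  raw <- generate_dataset(cfg)
  expect_equal(d$x_test,
               sweep(sweep(raw$x_test, 2, d$center), 2, d$scale, "/"),
               tolerance = 1e-12)
})
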