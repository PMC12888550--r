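# Shared fixtures and independent oracles, all built in code at test time.

# Standardized toy regression data.
make_toy <- function(n, p, beta, sigma = 1, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  y <- as.numeric(x %*% beta) + sigma * rnorm(n)
  list(x = x, y = y - mean(y))
}

# Exact 1-D k-means by dynamic programming over sorted values (the classic
# O(k n^2) formulation). Independent oracle for the k-means binarization.
dp_kmeans_1d <- function(v, k) {
  o <- order(v)
  s <- v[o]
  n <- length(s)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  seg_cost <- function(i, j) {
    # within-SS of s[i..j]
    m <- j - i + 1
    sum_ <- cs[j] - if (i > 1) cs[i - 1] else 0
    sum2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    sum2 - sum_^2 / m
  }
  cost <- matrix(Inf, k, n)
  split_at <- matrix(0L, k, n)
  for (j in 1:n) cost[1, j] <- seg_cost(1, j)
  if (k > 1) {
    for (kk in 2:k) {
      for (j in kk:n) {
        for (i in kk:j) {
          cand <- cost[kk - 1, i - 1] + seg_cost(i, j)
          if (cand < cost[kk, j]) {
            cost[kk, j] <- cand
            split_at[kk, j] <- i
          }
        }
      }
    }
  }
  # recover cluster assignment in sorted order
  assign_sorted <- integer(n)
  j <- n
  for (kk in k:1) {
    i <- if (kk == 1) 1L else split_at[kk, j]
    assign_sorted[i:j] <- kk
    j <- i - 1
  }
  cluster <- integer(n)
  cluster[o] <- assign_sorted
  list(cluster = cluster, wcss = cost[k, n])
}

# Multivariate normal log density (chol-based), used by enumeration oracles.
dmvnorm_log <- function(y, mean, sigma) {
  r <- chol(sigma)
  z <- backsolve(r, y - mean, transpose = TRUE)
  -length(y) / 2 * log(2 * pi) - sum(log(diag(r))) - sum(z^2) / 2
}

# Effective sample size from the empirical autocorrelation (initial positive
# sequence estimator).
ess <- function(x) {
  n <- length(x)
  a <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(a <= 0)
  if (length(pos)) a <- a[seq_len(pos[1] - 1)]
  max(1, n / (1 + 2 * sum(a)))
}

# Geweke-style successive-conditional harness: start from a joint prior
# draw, alternate data draw and one Gibbs transition, and compare bounded
# transforms of the collected states against fresh prior draws by KS
# distance. Thresholds are scaled by the chain's effective sample size so
# the comparison is "within Monte-Carlo error" of the autocorrelated chain.
geweke_harness <- function(prior_draw, step, collect, n = 20, p = 5,
                           m_iter = 12000, thin = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  state <- prior_draw()
  n_keep <- m_iter / thin
  succ <- matrix(NA_real_, n_keep, length(collect(state)))
  for (i in seq_len(m_iter)) {
    y <- as.numeric(x %*% state$beta) + sqrt(state$sigma2) * rnorm(n)
    state <- step(state, x, y)
    if (i %% thin == 0) succ[i / thin, ] <- collect(state)
  }
  marg <- t(replicate(n_keep, collect(prior_draw())))
  ks <- vapply(seq_len(ncol(succ)), function(j) {
    suppressWarnings(unname(ks.test(succ[, j], marg[, j])$statistic))
  }, numeric(1))
  bound <- vapply(seq_len(ncol(succ)), function(j) {
    1.36 * sqrt(1 / ess(succ[, j]) + 1 / nrow(marg)) * 1.5
  }, numeric(1))
  list(ks = ks, bound = bound)
}

# Benchmark-scale helper: mean RFSFS metrics over `reps` independently
# generated datasets of one configuration.
rfsfs_metrics <- function(cfg, reps, seed_base = 2000) {
  f <- fd <- fn <- mo <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg$seed <- seed_base + r
    d <- standardize_dataset(generate_dataset(cfg))
    fit <- fit_rfsfs(d$x_train, d$y_train, seed = seed_base + r)
    cc <- confusion_counts(select_features(fit), d$coef$support, cfg$p)
    f[r] <- as.numeric(fscore(cc))
    fd[r] <- fdr(cc)
    fn[r] <- fnr(cc)
    mo[r] <- mspe(fit$beta_hat, d$x_test, d$y_test)
  }
  list(fscore = mean(f), fdr = mean(fd), fnr = mean(fn), mspe_out = mean(mo))
}
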