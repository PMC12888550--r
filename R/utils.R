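# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generation is a pure function of (config,
# seed) and never perturbs user code.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a well-spread child seed from a base seed and one or more integer
# keys, staying inside the signed 32-bit range.
child_seed <- function(seed, ...) {
  keys <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in keys) {
    x <- (x * 48271 + as.double(k) * 9631) %% 2147483647
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_matrix_response <- function(x, y) {
  if (!is.matrix(x)) stopf("`x` must be a numeric matrix")
  if (nrow(x) != length(y)) {
    stopf("`x` has %d rows but `y` has length %d", nrow(x), length(y))
  }
}

# Sample from the inverse-Gaussian IG(mu, lambda) distribution
# (Michael, Schucany & Haas transformation). Vectorised over mu.
rinvgaussian <- function(n, mu, lambda) {
  nu <- rnorm(n)
  z <- nu^2
  x <- mu + (mu^2 * z) / (2 * lambda) -
    (mu / (2 * lambda)) * sqrt(4 * mu * lambda * z + mu^2 * z^2)
  u <- runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

# Single 1-D slice-sampling update for a log-density, stepping-out procedure
# (Neal 2003). Used for non-conjugate scale parameters on the log scale.
slice_update <- function(x0, log_f, w = 1, max_step = 30) {
  y <- log_f(x0) - rexp(1)
  l <- x0 - runif(1) * w
  r <- l + w
  for (i in seq_len(max_step)) {
    if (log_f(l) <= y) break
    l <- l - w
  }
  for (i in seq_len(max_step)) {
    if (log_f(r) <= y) break
    r <- r + w
  }
  repeat {
    x1 <- runif(1, l, r)
    if (log_f(x1) > y) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
    if (r - l < 1e-12) return(x0)
  }
}
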