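# Independent oracles and small fixture builders used across the tests.

# Exact Poisson (Garwood) confidence interval for an observed count x,
# coded through the gamma distribution rather than the package's
# chi-squared path so the two routes stay independent.
garwood_interval <- function(x, level = 0.95) {
  alpha <- 1 - level
  lower <- if (x == 0) 0 else qgamma(alpha / 2, shape = x)
  upper <- qgamma(1 - alpha / 2, shape = x + 1)
  c(lower = lower, upper = upper)
}

# Counts vector of length n with total X placed in group `at`
counts_at <- function(X, at, n = 19) {
  x <- rep(0L, n)
  x[at] <- X
  x
}

# Spread a total as evenly as integers allow across n groups
counts_spread <- function(X, n = 19) {
  base <- X %/% n
  x <- rep(base, n)
  extra <- X - base * n
  if (extra > 0) x[seq_len(extra)] <- x[seq_len(extra)] + 1L
  x
}

# Random stratified-count cases under a fixed seed, for property tests.
# Weights are lognormal (positive, widely varying), denominators likewise,
# and counts sparse Poisson so zero-heavy strata occur often.
random_cases <- function(n_cases, n_groups = 12, seed = 424242) {
  set.seed(seed)
  lapply(seq_len(n_cases), function(i) {
    w <- exp(rnorm(n_groups, 8, 1))
    d <- exp(rnorm(n_groups, 9, 1.5))
    x <- rpois(n_groups, runif(1, 0.05, 3))
    list(w = w, d = d, x = x)
  })
}
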