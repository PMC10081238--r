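# Small in-code fixtures used across test files.

# Null dataset: independent standard-normal markers and outcome.
make_null_dataset <- function(m, n, seed = 1, binary_outcome = FALSE) {
  set.seed(seed)
  y <- if (binary_outcome) rep(c(0, 1), length.out = n) else rnorm(n)
  ewas_dataset(matrix(rnorm(m * n), nrow = m), y)
}

# Random covariate-adjusted fit inputs.
make_fit_inputs <- function(n, n_cov = 2, seed = 1) {
  set.seed(seed)
  list(y = rnorm(n), x = rnorm(n),
       covariates = matrix(rnorm(n * n_cov), nrow = n))
}

# Independent step-up (Benjamini-Hochberg) oracle: direct transcription of
# the definition, adj_(i) = min_{j >= i} min(1, m * p_(j) / j).
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}
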