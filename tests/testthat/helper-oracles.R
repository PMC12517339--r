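# Independent oracles and small fixture builders shared across test files.

# Direct density-ratio oracle for the Bayes factor: full n-dimensional
# multivariate normals, mean 0, covariances Sigma and Sigma + W Sigma Ic Sigma.
# Requires non-singular Sigma; deliberately does NOT use the matrix-inversion
# lemma, so it is independent of the code path it checks.
direct_log_bf_oracle <- function(config, region, W) {
  S <- region$ld
  z <- region$z
  n <- region$n
  Ic <- diag(0, n)
  if (length(config)) diag(Ic)[config] <- 1
  V1 <- S + W * S %*% Ic %*% S
  log_dmvnorm <- function(z, V) {
    ch <- chol(V)
    u <- backsolve(ch, z, transpose = TRUE)
    -0.5 * (length(z) * log(2 * pi)) - sum(log(diag(ch))) - 0.5 * sum(u^2)
  }
  log_dmvnorm(z, V1) - log_dmvnorm(z, S)
}

# Random positive-definite correlation matrix
random_corr <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * (n + 4)), n + 4, n)
  stats::cov2cor(crossprod(A))
}

# Quick region builder
make_region <- function(z, ld, id = "r") {
  n <- length(z)
  region_data(id,
              data.frame(variant_id = paste0(id, "_v", seq_len(n)),
                         chrom = "1", pos = seq_len(n) * 1000L,
                         ref = "A", alt = "G", stringsAsFactors = FALSE),
              z, ld)
}

# Count of agreeing leading significant digits between two numbers
agree_digits <- function(x, y) {
  if (x == y) return(15L)
  for (k in 15:1) if (signif(x, k) == signif(y, k)) return(k)
  0L
}
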