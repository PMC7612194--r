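# Shared fixtures and independent oracles used across the suite.

rand_spd <- function(s, jitter = 1) {
  a <- matrix(rnorm(s * s), s)
  crossprod(a) + diag(jitter, s)
}

# random chordal graph grown by decomposability-preserving edge additions
rand_chordal <- function(s, steps = 3 * s) {
  adj <- matrix(FALSE, s, s)
  for (i in seq_len(steps)) {
    e <- sample.int(s, 2L)
    a2 <- adj
    a2[e[1], e[2]] <- a2[e[2], e[1]] <- TRUE
    if (is_decomposable(a2)) adj <- a2
  }
  adj
}

# adjacency from an integer edge-subset code (upper-triangle bit order)
adj_from_code <- function(code, s) {
  pairs <- which(upper.tri(matrix(0, s, s)), arr.ind = TRUE)
  bits <- as.logical(bitwAnd(code, 2L^(seq_len(nrow(pairs)) - 1L)))
  adj <- matrix(FALSE, s, s)
  adj[pairs[bits, , drop = FALSE]] <- TRUE
  adj | t(adj)
}

# multivariate normal log density (independent oracle; no package code)
dmvnorm_log <- function(x, mean, sigma) {
  k <- length(x)
  ch <- chol(sigma)
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -k / 2 * log(2 * pi) - sum(log(diag(ch))) - sum(z^2) / 2
}

# beta-binomial pmf of the model size under gamma_kj ~ Ber(o), o ~ Beta(a, b)
betabinom_pmf <- function(k, p, a, b) {
  exp(lchoose(p, k) + lbeta(a + k, b + p - k) - lbeta(a, b))
}

# batch-means Monte Carlo standard error for a (possibly autocorrelated) chain
mcse_batch <- function(x, n_batch = 30L) {
  m <- length(x) %/% n_batch
  bm <- colMeans(matrix(x[seq_len(m * n_batch)], nrow = m))
  stats::sd(bm) / sqrt(n_batch)
}

# tiny deterministic dataset
toy_data <- function(n = 40L, s = 4L, p = 8L, seed = 99L) {
  set.seed(seed)
  list(Y = matrix(rnorm(n * s), n), X = matrix(rnorm(n * p), n))
}
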