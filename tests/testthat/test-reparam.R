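# Covariance reparametrisation, transformed priors and posterior draws.

test_that("decompose/reconstruct round-trips and matches hand results", {
  expect_equal(decompose_covariance(diag(3))$sigma2, rep(1, 3))
  expect_true(all(decompose_covariance(diag(3))$rho == 0))

  r <- 0.6
  rc <- decompose_covariance(matrix(c(1, r, r, 1), 2))
  expect_equal(rc$sigma2, c(1, 1 - r^2))
  expect_equal(rc$rho[2, 1], r)
  expect_equal(reconstruct_covariance(rc), matrix(c(1, r, r, 1), 2))

  set.seed(1)
  for (s in c(5, 20, 50)) {
    C <- rand_spd(s)
    rc <- decompose_covariance(C)
    expect_lt(max(abs(reconstruct_covariance(rc) - C)), 1e-10 * max(abs(C)))
  }
  expect_error(decompose_covariance(matrix(c(1, 2, 2, 1), 2)), "positive-definite")
})

test_that("sparse reconstruction realises precision zeros without completion", {
  a <- matrix(FALSE, 3, 3)
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- TRUE
  rc <- structure(list(sigma2 = c(1, 0.5, 0.8),
                       rho = rbind(0, c(0.4, 0, 0), c(0, -0.3, 0)),
                       order = 1:3), class = "sur_reparam")
  C <- reconstruct_covariance(rc)
  K <- solve(C)
  expect_lt(abs(K[1, 3]), 1e-12)
  # all-zero rho gives a diagonal covariance
  rc0 <- structure(list(sigma2 = c(2, 3), rho = matrix(0, 2, 2), order = 1:2),
                   class = "sur_reparam")
  expect_equal(reconstruct_covariance(rc0), diag(c(2, 3)))
})

test_that("dense transformed prior matches the scalar case and IW moments", {
  # s = 1: plain inverse gamma
  rc1 <- structure(list(sigma2 = 2.3, rho = matrix(0, 1, 1), order = 1L),
                   class = "sur_reparam")
  expect_equal(log_prior_dense(rc1, nu = 4, tau = 1.5),
               qtlsur:::.dinvgamma_log(2.3, 2, 0.75))
  expect_error(log_prior_dense(rc1, nu = -1, tau = 1), "nu")

  # Monte-Carlo: reconstructed draws match the inverse-Wishart mean tau I/(nu-s-1)
  set.seed(3)
  s <- 3; nu <- s + 4; tau <- 2
  jt <- dense_jt(s)
  m <- matrix(0, s, s)
  nrep <- 4000
  for (i in seq_len(nrep))
    m <- m + reconstruct_covariance(qtlsur:::.sample_reparam(jt, diag(tau, s), 0, nu))
  m <- m / nrep
  expect_lt(max(abs(m - diag(tau / (nu - s - 1), s))), 0.1)
})

test_that("sparse prior reduces to dense on the complete graph and factorises on the empty graph", {
  set.seed(4)
  s <- 5; nu <- s + 3; tau <- 1.3
  jt <- dense_jt(s)
  rc <- decompose_covariance(rand_spd(s), jt = jt)
  expect_equal(log_prior_sparse(rc, jt, nu, tau), log_prior_dense(rc, nu, tau),
               tolerance = 1e-12)

  jt0 <- junction_tree(matrix(FALSE, s, s))
  rc0 <- structure(list(sigma2 = runif(s, 0.5, 2), rho = matrix(0, s, s),
                        order = 1:s), class = "sur_reparam")
  expect_equal(log_prior_sparse(rc0, jt0, nu, tau),
               sum(qtlsur:::.dinvgamma_log(rc0$sigma2, (nu - s + 1) / 2, tau / 2)))
  # support mismatch is an error
  rc_bad <- rc0; rc_bad$rho[2, 1] <- 0.5
  expect_error(log_prior_sparse(rc_bad, jt0, nu, tau), "support")
})

test_that("sparse prior on the 3-chain equals the clique/separator factorisation", {
  # clique {1,2} and {2,3} transformed inverse-Wishart densities divided by
  # the separator {2} marginal, an independent brute-force factorisation
  a <- matrix(FALSE, 3, 3)
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- TRUE
  jt <- junction_tree(a)
  set.seed(8)
  nu <- 6; tau <- 1.7
  rc <- qtlsur:::.sample_reparam(jt, diag(tau, 3), 0, nu)
  lp <- log_prior_sparse(rc, jt, nu, tau)
  C <- reconstruct_covariance(rc)
  dig <- qtlsur:::.dinvgamma_log
  dn <- function(x, v) -0.5 * log(2 * pi * v) - x^2 / (2 * v)
  # clique terms under their own 2-dim transformed parametrisations (df nu - 1)
  cl1 <- dig(rc$sigma2[1], (nu - 2) / 2, tau / 2) +
    dig(rc$sigma2[2], (nu - 1) / 2, tau / 2) +
    dn(rc$rho[2, 1], rc$sigma2[2] / tau)
  cl2 <- dig(C[2, 2], (nu - 2) / 2, tau / 2) +
    dig(rc$sigma2[3], (nu - 1) / 2, tau / 2) +
    dn(rc$rho[3, 2], rc$sigma2[3] / tau)
  sep <- dig(C[2, 2], (nu - 2) / 2, tau / 2)
  expect_equal(lp, cl1 + cl2 - sep, tolerance = 1e-10)
})

test_that("posterior conditional draws reduce to textbook conjugacy and prior at n = 0", {
  # n = 0 reduces exactly to the prior draw
  jt <- junction_tree(rand_chordal(4))
  set.seed(11)
  d1 <- sample_cov_conditional(matrix(0, 0, 4), jt, nu = 6, tau = 2)
  set.seed(11)
  d2 <- qtlsur:::.sample_reparam(jt, diag(2, 4), 0, 6)
  expect_identical(d1, d2)

  # s = 1: sigma^2 ~ IGa((n + nu)/2, (tau + u'u)/2)
  set.seed(12)
  u <- matrix(rnorm(30), 30, 1)
  jt1 <- junction_tree(matrix(FALSE, 1, 1))
  set.seed(13)
  d <- sample_cov_conditional(u, jt1, nu = 1, tau = 0.5)
  set.seed(13)
  expect_equal(d$sigma2, 1 / rgamma(1, (30 + 1) / 2,
                                    rate = (0.5 + sum(u^2)) / 2),
               tolerance = 1e-12)

  # dense Gibbs self-consistency: long-run mean of reconstructed C matches
  # the conjugate inverse-Wishart posterior mean
  set.seed(14)
  n <- 200; s <- 5; nu <- s + 3; tau <- 1
  U <- matrix(rnorm(n * s), n) %*% chol(rand_spd(s) / s)
  jtd <- dense_jt(s)
  m <- matrix(0, s, s)
  nrep <- 600
  for (i in seq_len(nrep))
    m <- m + reconstruct_covariance(sample_cov_conditional(U, jtd, nu, tau))
  m <- m / nrep
  post <- (diag(tau, s) + crossprod(U)) / (n + nu - s - 1)
  expect_lt(max(abs(m - post) / (abs(post) + 0.05)), 0.1)
})

test_that("compiled covariance draw matches the pure-R reference stream for stream-identical shapes", {
  set.seed(21)
  jt <- junction_tree(rand_chordal(5))
  U <- matrix(rnorm(40 * 5), 40)
  Mt <- crossprod(U) + diag(1.5, 5)
  set.seed(22)
  a <- qtlsur:::.sample_reparam(jt, Mt, 40, 8)
  set.seed(22)
  b <- qtlsur:::.sample_reparam_r(jt, Mt, 40, 8)
  expect_equal(a$sigma2, b$sigma2, tolerance = 1e-12)
  expect_equal(a$rho, b$rho, tolerance = 1e-12)
})

test_that("collapsed covariance evidence matches quadrature, direct form and is ordering-invariant", {
  set.seed(7)
  n <- 12; s <- 5
  U <- matrix(rnorm(n * s), n)
  a5 <- matrix(FALSE, 5, 5)
  a5[1, 2] <- a5[2, 3] <- a5[1, 3] <- a5[3, 4] <- a5[4, 5] <- a5[3, 5] <- TRUE
  a5 <- a5 | t(a5)
  jt5 <- junction_tree(a5)
  nu <- 9; tau <- 1.7
  Mt <- crossprod(U) + diag(tau, s)
  ml <- qtlsur:::.cov_marglik(jt5, Mt, n, nu, tau)

  # direct per-node evaluation under the perfect elimination ordering
  preds <- qtlsur:::.pred_sets(jt5)
  direct <- 0
  for (k in 1:s) {
    idx <- preds[[k]]; d <- length(idx); aa <- (nu - s + 1 + d) / 2
    if (d) {
      Mi <- Mt[idx, idx, drop = FALSE]; mm <- Mt[idx, k]
      sol <- solve(Mi, mm)
      bb <- (Mt[k, k] - sum(mm * sol)) / 2
      ld <- as.numeric(determinant(Mi)$modulus)
    } else {
      bb <- Mt[k, k] / 2; ld <- 0
    }
    direct <- direct + (-(n / 2) * log(2 * pi) + (d / 2) * log(tau) - ld / 2 +
                          aa * log(tau / 2) - lgamma(aa) + lgamma(aa + n / 2) -
                          (aa + n / 2) * log(bb))
  }
  expect_equal(ml, direct, tolerance = 1e-10)

  # quadrature oracle at s = 1
  u1 <- U[, 1, drop = FALSE]
  jt1 <- junction_tree(matrix(FALSE, 1, 1))
  ml1 <- qtlsur:::.cov_marglik(jt1, crossprod(u1) + tau, n, 3, tau)
  num <- integrate(function(v) sapply(v, function(x)
    exp(sum(dnorm(u1, 0, sqrt(x), log = TRUE)) +
          qtlsur:::.dinvgamma_log(x, 3 / 2, tau / 2))), 0, Inf)$value
  expect_equal(ml1, log(num), tolerance = 1e-6)

  # prior normalisation and relabelling invariance
  expect_equal(qtlsur:::.cov_marglik(jt5, diag(tau, 5), 0, nu, tau), 0,
               tolerance = 1e-12)
  perm <- c(3, 1, 5, 2, 4)
  jtp <- junction_tree(a5[perm, perm])
  Mtp <- crossprod(U[, perm]) + diag(tau, 5)
  expect_equal(qtlsur:::.cov_marglik(jtp, Mtp, n, nu, tau), ml,
               tolerance = 1e-8)
})

test_that("compiled block evidence matches the pure-R reference", {
  set.seed(25)
  U <- matrix(rnorm(60), 12, 5)
  Mt <- crossprod(U) + diag(0.8, 5)
  for (blk in list(1L, c(2L, 4L), c(1L, 3L, 5L), 1:5)) {
    expect_equal(qtlsur:::.cpp_block_evidence(Mt, blk, 12, 8, 0.8, 5L),
                 qtlsur:::.block_evidence(Mt[blk, blk, drop = FALSE],
                                          12, 8, 0.8, 5),
                 tolerance = 1e-12)
  }
})

test_that("tau update targets its exact gamma full conditional", {
  set.seed(31)
  jt <- junction_tree(rand_chordal(4))
  rc <- qtlsur:::.sample_reparam(jt, diag(1, 4), 0, 7)
  nu <- 7; a_tau <- 2; b_tau <- 1
  # exact conditional: the transformed prior is Gamma-conjugate in tau
  preds <- qtlsur:::.pred_sets(jt)
  sh <- a_tau; ra <- b_tau
  for (k in 1:4) {
    d <- length(preds[[k]])
    sh <- sh + (nu - 4 + 1 + d) / 2 + d / 2
    ra <- ra + (1 + sum(rc$rho[k, ]^2)) / (2 * rc$sigma2[k])
  }
  tau <- 1; draws <- numeric(4000)
  for (i in seq_along(draws)) {
    tau <- update_tau(rc, jt, tau, nu, a_tau, b_tau, step = 0.8)$tau
    draws[i] <- tau
  }
  expect_lt(abs(mean(draws[-(1:200)]) - sh / ra), 4 * mcse_batch(draws[-(1:200)]) + 0.02)

  # dense case: the conditional is invariant to relabelling the responses
  jtd <- dense_jt(4)
  rcd <- decompose_covariance(rand_spd(4), jt = jtd)
  l1 <- qtlsur:::.tau_loglik(rcd, jtd, 2.5, nu)
  perm <- c(2, 4, 1, 3)
  Cp <- reconstruct_covariance(rcd)[perm, perm]
  rcp <- decompose_covariance(Cp, jt = jtd)
  l2 <- qtlsur:::.tau_loglik(rcp, jtd, 2.5, nu)
  expect_equal(l1, l2, tolerance = 1e-8)
})
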