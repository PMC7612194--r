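# Selection state: index sets, coefficient full conditional, gamma moves and
# hyperparameter updates.

test_that("index sets follow the perfect elimination ordering", {
  # dense, s = 3, k = 2
  jt <- dense_jt(3)
  is2 <- index_sets(jt, 2)
  expect_identical(is2$L, 1L)
  expect_identical(is2$M, 3L)
  expect_identical(is2$H[["3"]], 1L)

  # empty graph: all sets empty
  jt0 <- junction_tree(matrix(FALSE, 3, 3))
  for (k in 1:3) {
    is0 <- index_sets(jt0, k)
    expect_length(is0$L, 0L)
    expect_length(is0$M, 0L)
  }

  # chain 1-2-3, k = 2: L = {1}, M = {3}, H(2,3) empty (1 not in prime {2,3})
  a <- matrix(FALSE, 3, 3)
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- TRUE
  jtc <- junction_tree(a)
  isc <- index_sets(jtc, 2)
  expect_identical(isc$L, 1L)
  expect_identical(isc$M, 3L)
  expect_length(isc$H[["3"]], 0L)
})

test_that("factorised likelihood equals the joint matrix-normal density and is ordering-invariant", {
  set.seed(11)
  n <- 10; p <- 3; s <- 3
  X <- matrix(rnorm(n * p), n)
  C <- rand_spd(s)
  Y <- matrix(rnorm(n * s), n)
  gamma <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
                  s, p, byrow = TRUE)
  beta <- matrix(0, s, p); beta[gamma] <- rnorm(sum(gamma))
  jt <- dense_jt(s)
  rc <- decompose_covariance(C, jt = jt)
  ll <- log_likelihood_factorised(Y, X, beta, rc, jt)
  mu <- as.vector(tcrossprod(X, beta))
  ll_joint <- dmvnorm_log(as.vector(Y), mu, kronecker(C, diag(n)))
  expect_equal(ll, ll_joint, tolerance = 1e-8)

  # rho = 0, sigma2 = 1: independent regressions
  rc0 <- structure(list(sigma2 = rep(1, s), rho = matrix(0, s, s), order = 1:s),
                   class = "sur_reparam")
  ll0 <- log_likelihood_factorised(Y, X, beta, rc0, junction_tree(matrix(FALSE, s, s)))
  U <- Y - tcrossprod(X, beta)
  expect_equal(ll0, sum(dnorm(U, log = TRUE)), tolerance = 1e-10)

  # response reordering leaves the dense-case likelihood unchanged
  perm <- c(3, 1, 2)
  rcp <- decompose_covariance(C[perm, perm])
  llp <- log_likelihood_factorised(Y[, perm], X, beta[perm, ], rcp, dense_jt(s))
  expect_equal(llp, ll, tolerance = 1e-8)
})

test_that("coefficient full conditional equals brute-force Gaussian conditioning", {
  set.seed(19)
  for (rep in 1:6) {
    n <- sample(8:12, 1); p <- sample(3:4, 1); s <- sample(2:3, 1)
    X <- matrix(rnorm(n * p), n)
    C <- rand_spd(s)
    Y <- matrix(rnorm(n * s), n)
    gamma <- matrix(runif(s * p) < 0.6, s, p)
    gamma[, 1] <- TRUE
    beta <- matrix(0, s, p); beta[gamma] <- rnorm(sum(gamma))
    w <- runif(1, 0.3, 2)
    jt <- dense_jt(s)
    rc <- decompose_covariance(C, jt = jt)
    K <- solve(C)
    for (k in seq_len(s)) {
      sel <- which(gamma[k, ])
      Xk <- X[, sel, drop = FALSE]
      P <- K[k, k] * crossprod(Xk) + diag(1 / w, length(sel))
      h <- 0
      for (l in seq_len(s)) {
        rl <- Y[, l] - if (l == k) 0 else
          X[, gamma[l, ], drop = FALSE] %*% beta[l, gamma[l, ]]
        h <- h + K[k, l] * crossprod(Xk, rl)
      }
      mu_oracle <- solve(P, h)
      # mean and covariance recovered from repeated conditional draws is
      # overkill; instead verify via the deterministic location by fixing the
      # Gaussian noise to zero through a two-draw average trick is fragile --
      # use the internal deterministic pieces directly
      U <- Y - tcrossprod(X, beta)
      preds <- qtlsur:::.pred_sets(jt); succ <- qtlsur:::.succ_sets(jt)
      F_ <- Y - U; E <- U
      for (m in seq_len(s)) {
        idx <- preds[[m]]
        if (length(idx)) E[, m] <- U[, m] - U[, idx, drop = FALSE] %*% rc$rho[m, idx]
      }
      yt <- qtlsur:::.ytilde(k, E, F_, rc$rho, rc$sigma2, succ[[k]])
      ck <- qtlsur:::.ck_mult(k, rc$rho, rc$sigma2, succ[[k]])
      Wk <- ck * crossprod(Xk); diag(Wk) <- diag(Wk) + 1 / w
      expect_lt(max(abs(Wk - P)), 1e-8)
      expect_lt(max(abs(solve(Wk, crossprod(Xk, yt)) - mu_oracle)), 1e-8)
    }
  }
})

test_that("sample_beta_conditional draws from the stated conditional and handles the null model", {
  set.seed(23)
  n <- 200; p <- 3
  X <- matrix(rnorm(n * p), n)
  Y <- matrix(rnorm(n * 2), n)
  gamma <- rbind(c(TRUE, TRUE, FALSE), c(FALSE, FALSE, FALSE))
  beta <- matrix(0, 2, p); beta[1, 1:2] <- c(1, -1)
  jt <- dense_jt(2)
  rc <- decompose_covariance(rand_spd(2), jt = jt)
  expect_length(sample_beta_conditional(2, Y, X, beta, gamma, rc, jt, w = 1), 0L)
  # empirical mean of many draws approaches the conditional mean
  draws <- replicate(800, sample_beta_conditional(1, Y, X, beta, gamma, rc, jt, w = 1))
  U <- Y - tcrossprod(X, beta)
  preds <- qtlsur:::.pred_sets(jt); succ <- qtlsur:::.succ_sets(jt)
  F_ <- Y - U; E <- U
  for (m in 1:2) {
    idx <- preds[[m]]
    if (length(idx)) E[, m] <- U[, m] - U[, idx, drop = FALSE] %*% rc$rho[m, idx]
  }
  yt <- qtlsur:::.ytilde(1, E, F_, rc$rho, rc$sigma2, succ[[1]])
  ck <- qtlsur:::.ck_mult(1, rc$rho, rc$sigma2, succ[[1]])
  Xs <- X[, 1:2]
  Wk <- ck * crossprod(Xs); diag(Wk) <- diag(Wk) + 1
  mu <- solve(Wk, crossprod(Xs, yt))
  expect_lt(max(abs(rowMeans(draws) - mu)), 4 * sqrt(max(diag(solve(Wk))) / 800))
})

test_that("gamma proposal moves have exact ratios and swap preserves size", {
  set.seed(31)
  p <- 6
  g <- c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  # empirical proposal frequencies against the stated kernel
  nrep <- 20000
  tab <- new.env()
  for (i in seq_len(nrep)) {
    pr <- propose_gamma(g)
    key <- paste(which(pr$gamma_star), collapse = ",")
    tab[[key]] <- c(tab[[key]], pr$log_proposal_ratio)
    if (pr$move == "swap") expect_identical(sum(pr$gamma_star), sum(g))
  }
  # an add target: probability 0.4 / 4; its stated reverse/forward ratio
  add_key <- "1,2,4"
  expect_equal(length(tab[[add_key]]) / nrep, 0.4 / 4, tolerance = 0.02)
  expect_equal(unique(tab[[add_key]]), log((0.4 / 3) / (0.4 / 4)))
  # a delete target: probability 0.4 / 2
  del_key <- "4"
  expect_equal(length(tab[[del_key]]) / nrep, 0.4 / 2, tolerance = 0.02)
  expect_equal(unique(tab[[del_key]]), log((0.4 / 5) / (0.4 / 2)))
  # null model: only add moves, reverse is a delete
  pr0 <- propose_gamma(rep(FALSE, p))
  expect_identical(pr0$move, "add")
  expect_equal(pr0$log_proposal_ratio, log((0.4 / 1) / (1 / p)))
})

test_that("hotspot prior mass follows the Bernoulli factorisation", {
  o <- c(0.2, 0.05)
  pi_j <- c(1, 2, 0.5)
  g <- rbind(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE))
  pr <- outer(o, pi_j)
  expect_equal(log_prior_gamma(g, o, pi_j),
               log(pr[1, 1]) + log(pr[2, 2]) + sum(log(1 - pr[cbind(c(2, 1, 1, 2), c(1, 2, 3, 3))])))
  expect_equal(log_prior_gamma(matrix(FALSE, 2, 3), o, pi_j), sum(log(1 - pr)))
  expect_error(log_prior_gamma(g, c(0.9, 0.9), c(2, 1, 1)), "constraint")

  # doubling pi_j doubles the inclusion odds of predictor j (the odds factor
  # q/(1-q) doubles exactly in the sparse limit q -> 0)
  g1 <- rbind(c(TRUE, FALSE, FALSE))
  o_small <- 1e-4
  base <- log_prior_gamma(g1, o_small, c(1, 1, 1)) -
    log_prior_gamma(rbind(rep(FALSE, 3)), o_small, c(1, 1, 1))
  dbl <- log_prior_gamma(g1, o_small, c(2, 1, 1)) -
    log_prior_gamma(rbind(rep(FALSE, 3)), o_small, c(2, 1, 1))
  expect_equal(exp(dbl - base), 2, tolerance = 1e-3)

  # integrating o under its Beta prior recovers the beta-binomial mass
  p <- 6; a_o <- 1.5; b_o <- 7
  g_row <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  num <- integrate(function(o) sapply(o, function(ok)
    exp(log_prior_gamma(rbind(g_row), ok, rep(1, p)) +
          dbeta(ok, a_o, b_o, log = TRUE))), 0, 1)$value
  closed <- betabinom_pmf(2, p, a_o, b_o) / choose(p, 2)
  expect_equal(num, closed, tolerance = 1e-5)
})

test_that("hotspot hyperparameter updates behave as conjugate or likelihood-driven MH", {
  set.seed(41)
  s <- 4; p <- 20
  gamma <- matrix(runif(s * p) < 0.15, s, p)
  o <- rep(0.1, s); pi_j <- rep(1, p)
  # beta-binomial variant: proposal is the exact conditional, acceptance 1
  acc <- replicate(50, update_hotspot_params(gamma, o, pi_j, 2, 18,
                                             hotspot = FALSE)$acc_o)
  expect_true(all(acc == 1))

  # all-zero predictor column pulls pi towards its prior mean
  g0 <- matrix(FALSE, s, p)
  pj <- rep(2, p); ok <- rep(0.05, s)
  for (i in 1:400) {
    up <- update_hotspot_params(g0, ok, pj, 2, 18, a_pi = 0.5, b_pi = 0.5,
                                hotspot = TRUE, step_pi = 0.6)
    ok <- up$o; pj <- up$pi_j
  }
  expect_lt(mean(pj), 1.5)  # prior mean is 1

  # a saturated hotspot column drives its propensity above 1
  gh <- matrix(FALSE, s, p); gh[, 1] <- TRUE
  pj <- rep(1, p); ok <- rep(0.1, s)
  mh <- 0
  for (i in 1:400) {
    up <- update_hotspot_params(gh, ok, pj, 2, 18, hotspot = TRUE, step_pi = 0.4)
    ok <- up$o; pj <- up$pi_j
    if (i > 100) mh <- mh + pj[1] / 300
  }
  expect_gt(mh, 1)
})

test_that("slab variance update is the stated conjugate draw", {
  set.seed(51)
  g0 <- matrix(FALSE, 2, 3)
  set.seed(52); w0 <- update_w(matrix(0, 2, 3), g0, 0.1, 0.1)
  set.seed(52); expect_identical(w0, 1 / rgamma(1, 0.1, rate = 0.1))

  g1 <- g0; g1[1, 2] <- TRUE
  b1 <- matrix(0, 2, 3); b1[1, 2] <- 2
  set.seed(53); w1 <- update_w(b1, g1, 0.1, 0.1)
  set.seed(53); expect_identical(w1, 1 / rgamma(1, 0.6, rate = 2.1))

  # long-run mean matches the inverse-gamma posterior mean
  draws <- replicate(4000, update_w(b1, g1, 3, 2))
  expect_equal(mean(draws), (2 + 2) / (3 + 0.5 - 1), tolerance = 0.1)
})

test_that("hotspot beta hyperparameters reproduce the requested model-size moments", {
  p <- 300
  ab <- hotspot_beta_params(p, 2, 2)
  a <- ab[["a_o"]]; b <- ab[["b_o"]]
  expect_equal(p * a / (a + b), 2, tolerance = 1e-10)
  expect_equal(p^2 * a * b / ((a + b)^2 * (a + b + 1)), 2, tolerance = 1e-10)
})
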