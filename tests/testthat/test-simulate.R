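# Synthetic-data generators: structural constants, graph families, G-Wishart
# support, SNR targeting and seed determinism.

test_that("banded-Toeplitz scenarios reproduce their structural constants", {
  counts <- c(19L, 37L, 54L)
  for (sc in 1:3) {
    tz <- make_toeplitz_scenario(sc, seed = 2)
    expect_identical(sum(tz$precision[upper.tri(tz$precision)] != 0), counts[sc])
    expect_identical(sum(tz$B != 0), 120L)
    expect_true(all(abs(tz$B[tz$B != 0]) < 2))
    expect_true(all(eigen(tz$precision, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
    expect_identical(dim(tz$Y), c(150L, 20L))
    expect_identical(dim(tz$X), c(150L, 30L))
  }
  # bitwise seed determinism
  expect_identical(make_toeplitz_scenario(2, seed = 7),
                   make_toeplitz_scenario(2, seed = 7))
})

test_that("graph families have the stated structure", {
  g <- make_graph("block_diagonal", 30, n_blocks = 3)
  expect_identical(sum(g$adjacency) / 2, 135)   # 3 * choose(10, 2)
  expect_true(is_decomposable(g$adjacency))

  gd <- make_graph("decomposable", 30)
  expect_true(is_decomposable(gd$adjacency))
  expect_silent(junction_tree(gd$adjacency))
  expect_gt(length(gd$cliques), 2L)

  gn <- make_graph("non_decomposable", 30)
  expect_false(is_decomposable(gn$adjacency))
  expect_error(junction_tree(gn$adjacency), "chordless")
})

test_that("G-Wishart draws have the exact support of the graph", {
  set.seed(3)
  g <- make_graph("decomposable", 12)
  gw <- sample_precision_gwishart(g$adjacency, seed = 4)
  off <- !g$adjacency & !diag(TRUE, 12)
  expect_true(all(gw$precision[off] == 0))
  expect_true(all(gw$precision[g$adjacency] != 0))
  expect_true(all(eigen(gw$precision, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  expect_true(gw$decomposable)

  # empty graph: diagonal, positive
  e <- sample_precision_gwishart(matrix(FALSE, 5, 5), seed = 5)
  expect_true(all(e$precision[upper.tri(e$precision)] == 0))
  expect_true(all(diag(e$precision) > 0))

  # complete graph: a dense Wishart draw
  cg <- matrix(TRUE, 4, 4); diag(cg) <- FALSE
  f <- sample_precision_gwishart(cg, seed = 6)
  expect_true(all(f$precision != 0))

  # non-decomposable: approximate draw, exact zeros, PD
  gn <- make_graph("non_decomposable", 12)
  gwn <- sample_precision_gwishart(gn$adjacency, seed = 7)
  offn <- !gn$adjacency & !diag(TRUE, 12)
  expect_true(all(gwn$precision[offn] == 0))
  expect_true(all(eigen(gwn$precision, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  expect_false(gwn$decomposable)
  expect_error(sample_precision_gwishart(cg, scale = matrix(c(1, 2, 2, 1), 2)))
})

test_that("association patterns encode the four predictor groups", {
  g <- make_graph("block_diagonal", 30, n_blocks = 3)
  pat <- make_gamma_pattern(30, 300, g, seed = 1)
  tg <- pat$gamma
  grp <- pat$groups
  # hotspots hit every response
  for (j in grp$column[grp$type == "hotspot"])
    expect_identical(sum(tg[, j]), 30L)
  # per-prime predictors hit exactly their clique
  primes <- g$cliques
  jp <- grp$column[grp$type == "prime"]
  for (i in seq_along(jp))
    expect_identical(which(tg[, jp[i]]), as.integer(primes[[i]]))
  # spanning predictors touch several components
  for (j in grp$column[grp$type == "span"])
    expect_gte(sum(tg[, j]), 2L)
  # all other predictors are null
  expect_true(all(colSums(tg[, -grp$column]) == 0))
})

test_that("signal-to-noise summaries follow their definitions", {
  set.seed(8)
  n <- 50
  X <- matrix(rnorm(n * 3), n)
  # s = 1, unit variance: SNR_beta = sum((x beta)^2) / (n - 1)
  beta <- matrix(c(2, 0, 0), 1, 3)
  gamma <- beta != 0
  expect_equal(snr_beta(X, beta, gamma, 1),
               sum((X[, 1] * 2)^2) / (n - 1))
  # doubling beta quadruples SNR_beta
  expect_equal(snr_beta(X, 2 * beta, gamma, 1),
               4 * snr_beta(X, beta, gamma, 1))
  # rho = 0 gives SNR_C = 0
  U <- matrix(rnorm(n * 4), n)
  expect_equal(snr_c(U, matrix(0, 4, 4), rep(1, 4)), 0)
})

test_that("genotype-like predictors look like LD-structured dosages", {
  X1 <- make_genotype_like_predictors(4000, 1, seed = 10)
  expect_true(all(X1 %in% 0:2))
  f_hat <- mean(X1) / 2
  expect_true(f_hat > 0.03 && f_hat < 0.55)

  set.seed(11)
  X <- make_genotype_like_predictors(600, 40, block_size = 10, ar = 0.9)
  cc <- cor(X)
  adj_pairs <- cbind(1:39, 2:40)
  same_block <- (adj_pairs[, 1] - 1) %/% 10 == (adj_pairs[, 2] - 1) %/% 10
  expect_gt(mean(abs(cc[adj_pairs[same_block, ]])), 0.5)
  expect_identical(make_genotype_like_predictors(50, 20, seed = 3),
                   make_genotype_like_predictors(50, 20, seed = 3))
})

test_that("QTL scenarios hit the SNR window, are seed-reproducible and self-score perfectly", {
  sc <- simulate_qtl_scenario(n = 100, s = 12, p = 60,
                              graph_kind = "decomposable", r = 0.6,
                              target_snr_beta = 15, seed = 21)
  expect_lt(abs(sc$snr_beta - 15) / 15, 0.1)
  expect_identical(dim(sc$Y), c(100L, 12L))
  sc2 <- simulate_qtl_scenario(n = 100, s = 12, p = 60,
                               graph_kind = "decomposable", r = 0.6,
                               target_snr_beta = 15, seed = 21)
  expect_identical(sc, sc2)

  # truth round-trips through the evaluators with perfect scores
  r <- roc_tpr_fpr(sc$adjacency + 0, sc$adjacency + 0, threshold = 0.5,
                   what = "edges")
  expect_equal(r$tpr, 1); expect_equal(r$fpr, 0)
  ra <- roc_tpr_fpr(sc$gamma + 0, sc$gamma + 0, threshold = 0.5)
  expect_equal(ra$tpr, 1); expect_equal(ra$fpr, 0)

  # forcing beta to zero kills the predictor signal
  expect_equal(snr_beta(sc$X, 0 * sc$beta, sc$gamma, sc$sigma2), 0)
})

test_that("generated residuals reproduce the target covariance at large n", {
  set.seed(31)
  s <- 8
  g <- make_graph("block_diagonal", s, n_blocks = 2)
  gw <- sample_precision_gwishart(g$adjacency, seed = 32)
  n <- 5000
  E <- matrix(rnorm(n * s), n) %*% chol(gw$C)
  emp <- crossprod(E) / n
  expect_lt(norm(emp - gw$C, "F") / norm(gw$C, "F"), 0.05)
})

test_that("residual-dependence SNR increases with the scale correlation r", {
  set.seed(41)
  snr_at <- function(r) median(sapply(1:4, function(i)
    simulate_qtl_scenario(n = 60, s = 12, p = 40, graph_kind = "block_diagonal",
                          r = r, target_snr_beta = 5,
                          seed = 100 + 13 * i + round(100 * r))$snr_c))
  v <- c(snr_at(0.3), snr_at(0.6), snr_at(0.9))
  expect_true(all(diff(v) > 0))
})
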