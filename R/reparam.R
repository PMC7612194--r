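# Covariance reparametrisation C <-> (sigma^2, rho): sequential Schur
# complement variances and regression-on-earlier-residuals coefficients under
# a (perfect elimination) ordering.  In the sparse case rho_k is supported on
# the earlier-ordered neighbours of k only, which realises the hyper
# inverse-Wishart conditional independences without any completion step.

# Cholesky with a small diagonal jitter retry; used everywhere a Schur
# complement is needed so that near-singular submatrices degrade gracefully.
.chol_safe <- function(a) {
  r <- tryCatch(chol(a), error = function(e) NULL)
  if (is.null(r)) {
    jit <- 1e-10 * sum(diag(a)) / nrow(a)
    warning("Cholesky failed; adding jitter ", signif(jit, 3), call. = FALSE)
    r <- chol(a + diag(jit, nrow(a)))
  }
  r
}

.chol_solve <- function(r, b) backsolve(r, backsolve(r, b, transpose = TRUE))

#' Decompose a covariance matrix into (sigma^2, rho)
#'
#' Under the node ordering `order`, `sigma2[k]` is the Schur-complement
#' residual variance of response `k` given its predecessors and `rho[k, ]`
#' holds the regression coefficients of response `k` on those predecessors.
#' If a junction tree is supplied the predecessor set of `k` is restricted to
#' earlier-ordered nodes in the same prime component (the ordering is then
#' taken from the tree), giving exact zeros elsewhere in `rho`.
#'
#' @param C Symmetric positive-definite covariance matrix.
#' @param order Node ordering (ignored when `jt` is given).
#' @param jt Optional `sur_jt` for the sparse case.
#' @return Object of class `sur_reparam`: list with `sigma2` (length s),
#'   `rho` (s x s, row k supported on the predecessors of k), `order`.
#' @export
decompose_covariance <- function(C, order = seq_len(nrow(C)), jt = NULL) {
  s <- nrow(C)
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8)))
    stop("C must be symmetric", call. = FALSE)
  if (inherits(tryCatch(chol(C), error = function(e) e), "error"))
    stop("C must be positive-definite", call. = FALSE)
  if (!is.null(jt)) {
    order <- jt$order
    preds <- .pred_sets(jt)
  } else {
    preds <- vector("list", s)
    for (i in seq_along(order)) preds[[order[i]]] <- order[seq_len(i - 1L)]
  }
  sigma2 <- numeric(s)
  rho <- matrix(0, s, s)
  for (k in seq_len(s)) {
    idx <- preds[[k]]
    if (!length(idx)) {
      sigma2[k] <- C[k, k]
    } else {
      r <- .chol_safe(C[idx, idx, drop = FALSE])
      ck <- C[idx, k]
      sol <- .chol_solve(r, ck)
      sigma2[k] <- C[k, k] - sum(ck * sol)
      rho[k, idx] <- sol
    }
  }
  structure(list(sigma2 = sigma2, rho = rho, order = order),
            class = "sur_reparam")
}

#' Reconstruct a covariance matrix from (sigma^2, rho)
#'
#' Exact inverse of [decompose_covariance()] under the same ordering.  Zeros
#' in `rho` translate into zeros of the precision matrix between the
#' corresponding node pairs, so a sparse reparametrisation reconstructs the
#' graph-constrained covariance without an explicit completion operation.
#'
#' @param rc A `sur_reparam` object.
#' @return Symmetric positive-definite matrix.
#' @export
reconstruct_covariance <- function(rc) {
  s <- length(rc$sigma2)
  order <- rc$order
  C <- matrix(0, s, s)
  for (i in seq_along(order)) {
    k <- order[i]
    prevn <- order[seq_len(i - 1L)]
    rhok <- rc$rho[k, prevn]
    if (i > 1L) {
      cvec <- C[prevn, prevn, drop = FALSE] %*% rhok
      C[prevn, k] <- cvec
      C[k, prevn] <- cvec
      C[k, k] <- rc$sigma2[k] + sum(rhok * cvec)
    } else {
      C[k, k] <- rc$sigma2[k]
    }
  }
  C
}

# density helpers -----------------------------------------------------------

.dinvgamma_log <- function(x, a, b) a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x

#' Log density of the transformed dense covariance prior
#'
#' The inverse-Wishart prior `C ~ IW(nu, tau I_s)` maps to independent
#' `sigma2_k ~ IGa((nu - s + k)/2, tau/2)` and
#' `rho_k | sigma2_k ~ N(0, (sigma2_k / tau) I_{k-1})` under any fixed
#' ordering.
#'
#' @param rc A `sur_reparam` object (ordering taken from it).
#' @param nu Degrees of freedom, must exceed `s - 1`.
#' @param tau Scale, `M = tau I_s`.
#' @export
log_prior_dense <- function(rc, nu, tau) {
  s <- length(rc$sigma2)
  if (nu <= s - 1) stop("nu must exceed s - 1", call. = FALSE)
  out <- 0
  for (i in seq_len(s)) {
    k <- rc$order[i]
    d <- i - 1L
    a <- (nu - s + i) / 2
    out <- out + .dinvgamma_log(rc$sigma2[k], a, tau / 2)
    if (d > 0L) {
      rhok <- rc$rho[k, rc$order[seq_len(d)]]
      out <- out - d / 2 * log(2 * pi * rc$sigma2[k] / tau) -
        tau * sum(rhok^2) / (2 * rc$sigma2[k])
    }
  }
  out
}

#' Log density of the transformed sparse covariance prior
#'
#' The hyper inverse-Wishart prior `C ~ HIW_G(nu, tau I_s)` on a decomposable
#' graph maps, under a perfect elimination ordering of the junction tree, to
#' `sigma2_k ~ IGa((nu - s + 1 + d_k)/2, tau/2)` and
#' `rho_k | sigma2_k ~ N(0, (sigma2_k / tau) I_{d_k})`, where `d_k` is the
#' number of earlier-ordered nodes in the same prime component
#' (`d_k = t - 1 + |S_q|`).  With the complete graph this reduces exactly to
#' [log_prior_dense()].
#'
#' @param rc A `sur_reparam` object whose support matches `jt`.
#' @param jt A `sur_jt` object.
#' @inheritParams log_prior_dense
#' @export
log_prior_sparse <- function(rc, jt, nu, tau) {
  s <- length(rc$sigma2)
  if (nu <= s - 1) stop("nu must exceed s - 1", call. = FALSE)
  preds <- .pred_sets(jt)
  out <- 0
  for (k in seq_len(s)) {
    idx <- preds[[k]]
    off <- setdiff(which(rc$rho[k, ] != 0), idx)
    if (length(off))
      stop("rho support does not match the junction tree (response ", k, ")",
           call. = FALSE)
    d <- length(idx)
    a <- (nu - s + 1 + d) / 2
    out <- out + .dinvgamma_log(rc$sigma2[k], a, tau / 2)
    if (d > 0L) {
      rhok <- rc$rho[k, idx]
      out <- out - d / 2 * log(2 * pi * rc$sigma2[k] / tau) -
        tau * sum(rhok^2) / (2 * rc$sigma2[k])
    }
  }
  out
}

#' Sample (sigma^2, rho) from the posterior full conditional
#'
#' Draws, independently across responses, `sigma2_k` from its inverse-gamma
#' full conditional and `rho_k | sigma2_k` from its Gaussian full conditional
#' given the residual matrix `U = Y - fitted means`, using only within-prime
#' submatrices of `M~ = tau I + U'U`.  With an empty data matrix (`n = 0`)
#' this is exactly a draw from the transformed prior.
#'
#' @param U n x s residual matrix (may have zero rows).
#' @param jt A `sur_jt` (use [dense_jt()] for the dense model).
#' @param nu,tau Prior degrees of freedom and scale.
#' @return A `sur_reparam` object.
#' @export
sample_cov_conditional <- function(U, jt, nu, tau) {
  s <- jt$s
  if (ncol(U) != s) stop("U must have s columns", call. = FALSE)
  Mt <- crossprod(U)
  diag(Mt) <- diag(Mt) + tau
  .sample_reparam(jt, Mt, nrow(U), nu)
}

# Core sampler shared by prior draws (Mt = prior scale matrix M, n = 0) and
# posterior draws (Mt = tau I + U'U).  `Mt` must be SPD.
.sample_reparam <- function(jt, Mt, n, nu) {
  d <- .cpp_sample_reparam(Mt, .pred_sets(jt), n, nu)
  structure(list(sigma2 = drop(d$sigma2), rho = d$rho, order = jt$order),
            class = "sur_reparam")
}

# pure-R reference implementation (oracle in tests)
.sample_reparam_r <- function(jt, Mt, n, nu) {
  s <- jt$s
  preds <- .pred_sets(jt)
  sigma2 <- numeric(s)
  rho <- matrix(0, s, s)
  for (k in seq_len(s)) {
    idx <- preds[[k]]
    d <- length(idx)
    a <- (n + nu - s + 1 + d) / 2
    if (d == 0L) {
      b <- Mt[k, k] / 2
      sigma2[k] <- 1 / stats::rgamma(1L, a, rate = b)
    } else {
      r <- chol(Mt[idx, idx, drop = FALSE])
      mk <- Mt[idx, k]
      sol <- .chol_solve(r, mk)
      b <- (Mt[k, k] - sum(mk * sol)) / 2
      if (b <= 0) stop("non-positive conditional scale: M~ not positive-definite",
                       call. = FALSE)
      sigma2[k] <- 1 / stats::rgamma(1L, a, rate = b)
      rho[k, idx] <- sol + sqrt(sigma2[k]) * backsolve(r, stats::rnorm(d))
    }
  }
  structure(list(sigma2 = sigma2, rho = rho, order = jt$order),
            class = "sur_reparam")
}

#' Sample a covariance matrix from the hyper inverse-Wishart distribution
#'
#' Draws `C ~ HIW_G(nu, M)` on a decomposable graph via the transformed
#' representation (prior draws of `sigma^2` and `rho` with a general scale
#' matrix `M`) followed by reconstruction.  With the complete graph this is a
#' plain inverse-Wishart draw.
#'
#' @param jt A `sur_jt` object.
#' @param nu Degrees of freedom (> s - 1).
#' @param M Scale matrix (SPD).
#' @return List with `C`, `precision` and the `sur_reparam` draw.
#' @export
sample_hiw <- function(jt, nu, M) {
  s <- jt$s
  if (nu <= s - 1) stop("nu must exceed s - 1", call. = FALSE)
  rc <- .sample_reparam(jt, M, 0L, nu)
  C <- reconstruct_covariance(rc)
  K <- .chol_solve(.chol_safe(C), diag(s))
  # structural zeros: make them exact
  K[!jt$adjacency & !diag(TRUE, s)] <- 0
  list(C = C, precision = (K + t(K)) / 2, reparam = rc)
}

# Collapsed (marginal over sigma^2 and rho) log evidence of the residual
# matrix under graph `jt`:  log integral prod_k N(u_k | U_L rho_k, sigma2_k I)
# d HIW-transformed prior.  Factorises over cliques minus separators; each
# block term comes from a single Cholesky factor of the corresponding block of
# M~ = tau I + U'U.  `cache` (an environment) memoises block terms within a
# sweep.  Ordering-invariant.
.cov_marglik <- function(jt, Mt, n, nu, tau, cache = NULL) {
  s <- jt$s
  tot <- 0
  blocks <- c(jt$primes, jt$separators[-1L])
  sign_ <- c(rep(1, length(jt$primes)), rep(-1, length(jt$separators) - 1L))
  for (i in seq_along(blocks)) {
    a <- blocks[[i]]
    if (!length(a)) next
    key <- paste(a, collapse = ",")
    f <- if (!is.null(cache)) cache[[key]] else NULL
    if (is.null(f)) {
      f <- .cpp_block_evidence(Mt, a, n, nu, tau, s)
      if (!is.null(cache)) cache[[key]] <- f
    }
    tot <- tot + sign_[i] * f
  }
  tot
}

# Evidence contribution of one complete block A:  sum over nodes of A (in any
# internal order) of the normal-inverse-gamma marginal terms, all read off one
# Cholesky factor of Mt[A, A].
.block_evidence <- function(Mta, n, nu, tau, s) {
  c_ <- nrow(Mta)
  r <- if (c_ == 1L) matrix(sqrt(Mta), 1L, 1L) else chol(Mta)
  lr <- log(diag(r))
  i <- seq_len(c_)
  a <- (nu - s + i) / 2
  sum(-(n / 2) * log(2 * pi) + ((i - 1) / 2) * log(tau) -
        (cumsum(lr) - lr) + a * log(tau / 2) - lgamma(a) +
        lgamma(a + n / 2) - (a + n / 2) * (2 * lr - log(2)))
}

#' Metropolis-Hastings update of the covariance scale tau
#'
#' Random-walk on `log(tau)` targeting the `Ga(a_tau, b_tau)` prior times the
#' transformed (hyper) inverse-Wishart density of the current
#' `(sigma^2, rho)`.  The proposal scale is adapted towards 0.44 acceptance by
#' the caller during burn-in.
#'
#' @param rc Current `sur_reparam`.
#' @param jt Current `sur_jt`.
#' @param tau Current value.
#' @param nu Degrees of freedom.
#' @param a_tau,b_tau Gamma prior (shape, rate).
#' @param step Proposal standard deviation on the log scale.
#' @return List with `tau` and `accepted`.
#' @export
update_tau <- function(rc, jt, tau, nu, a_tau = 0.1, b_tau = 0.1, step = 0.5) {
  # the transformed prior is Gamma-form in tau: two sufficient statistics
  s <- jt$s
  earlier <- outer(jt$pos, jt$pos, ">")   # earlier[l, k]: pos_l < pos_k
  d <- colSums(jt$adjacency & t(earlier))
  shape_k <- sum((nu - s + 1 + d) / 2 + d / 2) + a_tau - 1
  rate_k <- sum((1 + rowSums(rc$rho^2)) / (2 * rc$sigma2)) + b_tau
  tau_star <- tau * exp(step * stats::rnorm(1L))
  log_acc <- shape_k * (log(tau_star) - log(tau)) -
    rate_k * (tau_star - tau) + log(tau_star) - log(tau)
  acc <- is.finite(log_acc) && log(stats::runif(1L)) < log_acc
  list(tau = if (acc) tau_star else tau, accepted = acc)
}

# log p(sigma^2, rho | tau, J), dropping tau-free constants
.tau_loglik <- function(rc, jt, tau, nu) {
  s <- jt$s
  preds <- .pred_sets(jt)
  out <- 0
  for (k in seq_len(s)) {
    idx <- preds[[k]]
    d <- length(idx)
    a <- (nu - s + 1 + d) / 2
    out <- out + a * log(tau / 2) - tau / (2 * rc$sigma2[k])
    if (d > 0L) {
      rhok <- rc$rho[k, idx]
      out <- out + d / 2 * log(tau) - tau * sum(rhok^2) / (2 * rc$sigma2[k])
    }
  }
  out
}
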