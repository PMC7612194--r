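# Variable-selection state: spike-and-slab coefficients, binary inclusion
# indicators with hotspot / beta-binomial priors, the coefficient full
# conditional with its residual-feedback terms, and hyperparameter updates.

#' Index sets for the coefficient full conditional
#'
#' Under the perfect elimination ordering of the junction tree:
#' `L(k)` are the earlier-ordered nodes sharing a prime component with `k`
#' (the support of `rho_k`), `M(k)` the later-ordered ones (responses whose
#' own residual regressions feed back on `k`), and `H(k, m)` for `m` in
#' `M(k)` the nodes earlier than `m`, other than `k`, sharing a prime with
#' `m`.  In the dense model these reduce to all earlier / later responses.
#'
#' @param jt A `sur_jt` object ([dense_jt()] gives the dense reduction).
#' @param k Response index.
#' @return List with integer vectors `L`, `M` and a list `H` indexed by the
#'   elements of `M` (as character names).
#' @export
index_sets <- function(jt, k) {
  pos <- jt$pos
  nb <- which(jt$adjacency[, k])
  L <- nb[pos[nb] < pos[k]]
  M <- nb[pos[nb] > pos[k]]
  H <- lapply(M, function(m) {
    nbm <- which(jt$adjacency[, m])
    nbm <- nbm[pos[nbm] < pos[m]]
    nbm[nbm != k]
  })
  names(H) <- as.character(M)
  list(L = L, M = M, H = H)
}

#' Factorised SUR log likelihood
#'
#' Evaluates `sum_k log N(y_k | X_{gamma k} beta_{gamma k} + U_(k-1) rho_k,
#' sigma2_k I_n)` where the residual matrix `U` is rebuilt from the current
#' coefficients and `rho_k` is supported on the earlier-ordered same-prime
#' responses.  Equals the joint matrix-normal log density of the
#' reconstructed covariance for any valid ordering.
#'
#' @param Y n x s response matrix.
#' @param X n x p predictor matrix.
#' @param beta s x p coefficient matrix (zeros off the selected support).
#' @param rc `sur_reparam` covariance state.
#' @param jt `sur_jt` graph state.
#' @export
log_likelihood_factorised <- function(Y, X, beta, rc, jt) {
  n <- nrow(Y)
  s <- ncol(Y)
  U <- Y - tcrossprod(X, beta)  # n x s residuals  (X %*% t(beta))
  preds <- .pred_sets(jt)
  out <- 0
  for (k in seq_len(s)) {
    idx <- preds[[k]]
    mu <- if (length(idx)) U[, idx, drop = FALSE] %*% rc$rho[k, idx] else 0
    e <- U[, k] - mu
    out <- out - n / 2 * log(2 * pi * rc$sigma2[k]) -
      sum(e * e) / (2 * rc$sigma2[k])
  }
  out
}

# Assemble the working response ytilde_k of the coefficient full conditional
# from the innovation matrix E (columns e_m = u_m - U_L(m) rho_m) and the
# fitted-value matrix F (columns X_{gamma k} beta_k):
#   ytilde_k = (e_k + f_k) / sigma2_k
#              - sum_{m in M(k)} (rho_mk / sigma2_m) (e_m - rho_mk f_k)
.ytilde <- function(k, E, F_, rho, sigma2, succ_k) {
  yt <- (E[, k] + F_[, k]) / sigma2[k]
  for (m in succ_k) {
    yt <- yt - (rho[m, k] / sigma2[m]) * (E[, m] - rho[m, k] * F_[, k])
  }
  yt
}

# Precision multiplier of X'X in the coefficient full conditional:
#   c_k = 1/sigma2_k + sum_{m in M(k)} rho_mk^2 / sigma2_m
.ck_mult <- function(k, rho, sigma2, succ_k) {
  ck <- 1 / sigma2[k]
  if (length(succ_k)) ck <- ck + sum(rho[succ_k, k]^2 / sigma2[succ_k])
  ck
}

#' Sample the non-zero coefficients of one response from their full
#' conditional
#'
#' Draws `beta_{gamma k} ~ N(W_k^{-1} X_{gamma k}' ytilde_k, W_k^{-1})` with
#' `W_k = X'X (1/sigma2_k + sum_m rho_mk^2 / sigma2_m) + w^{-1} I`, where the
#' working response `ytilde_k` corrects the own residual for earlier
#' same-prime residual regressions and removes the feedback of response `k`'s
#' residual on the later-ordered same-prime responses.  An empty selection
#' returns a zero-length vector.
#'
#' @param k Response index.
#' @param Y,X Data matrices.
#' @param beta Current s x p coefficient matrix.
#' @param gamma Current s x p logical inclusion matrix.
#' @param rc `sur_reparam` state.
#' @param jt `sur_jt` state.
#' @param w Slab variance.
#' @return Numeric vector of length `sum(gamma[k, ])`.
#' @export
sample_beta_conditional <- function(k, Y, X, beta, gamma, rc, jt, w) {
  sel <- which(gamma[k, ])
  if (!length(sel)) return(numeric(0))
  U <- Y - tcrossprod(X, beta)
  preds <- .pred_sets(jt)
  succ <- .succ_sets(jt)
  s <- ncol(Y)
  F_ <- Y - U
  E <- U
  for (m in seq_len(s)) {
    idx <- preds[[m]]
    if (length(idx)) E[, m] <- U[, m] - U[, idx, drop = FALSE] %*% rc$rho[m, idx]
  }
  yt <- .ytilde(k, E, F_, rc$rho, rc$sigma2, succ[[k]])
  ck <- .ck_mult(k, rc$rho, rc$sigma2, succ[[k]])
  Xs <- X[, sel, drop = FALSE]
  Wk <- ck * crossprod(Xs)
  diag(Wk) <- diag(Wk) + 1 / w
  r <- .chol_safe(Wk)
  mu <- .chol_solve(r, crossprod(Xs, yt))
  drop(mu + backsolve(r, stats::rnorm(length(sel))))
}

# Collapsed log evidence of one response's selection:  log of the marginal
# (over beta_k) of the Gaussian factors that involve beta_k, up to terms free
# of gamma_k.  `h = X_gamma' ytilde`, `Wchol = chol(W_k)`.
.gamma_evidence <- function(d, w, Wchol, h) {
  if (d == 0L) return(0)
  z <- backsolve(Wchol, h, transpose = TRUE)
  -d / 2 * log(w) - sum(log(diag(Wchol))) + sum(z * z) / 2
}

#' Propose a local move on one response's inclusion vector
#'
#' Add / delete / swap moves with probabilities 0.4 / 0.4 / 0.2 (renormalised
#' at the boundaries where a move type is impossible).  The exact log
#' proposal ratio is returned so the move can be used in Metropolis-Hastings
#' acceptance; swap moves preserve the model size and are symmetric.
#'
#' @param gamma_k Logical vector of length p.
#' @return List with `gamma_star`, `log_proposal_ratio`, `move`.
#' @export
propose_gamma <- function(gamma_k) {
  p <- length(gamma_k)
  n1 <- sum(gamma_k)
  probs <- .move_probs(n1, p)
  move <- sample(c("add", "delete", "swap"), 1L, prob = probs)
  g <- gamma_k
  if (move == "add") {
    j <- .sample1(which(!gamma_k))
    g[j] <- TRUE
    lr <- log(.move_probs(n1 + 1L, p)[2L] / (n1 + 1)) -
      log(probs[1L] / (p - n1))
  } else if (move == "delete") {
    j <- .sample1(which(gamma_k))
    g[j] <- FALSE
    lr <- log(.move_probs(n1 - 1L, p)[1L] / (p - n1 + 1)) -
      log(probs[2L] / n1)
  } else {
    j0 <- .sample1(which(gamma_k))
    j1 <- .sample1(which(!gamma_k))
    g[j0] <- FALSE
    g[j1] <- TRUE
    lr <- 0
  }
  list(gamma_star = g, log_proposal_ratio = lr, move = move)
}

.move_probs <- function(n1, p) {
  if (n1 == 0L) c(1, 0, 0)
  else if (n1 == p) c(0, 1, 0)
  else c(0.4, 0.4, 0.2)
}

.sample1 <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

#' Log prior mass of the inclusion matrix under the hotspot prior
#'
#' `gamma_kj ~ Ber(o_k pi_j)` independently; the beta-binomial variant is the
#' special case `pi_j = 1`.
#'
#' @param gamma s x p logical matrix (or one row).
#' @param o Length-s response sparsity levels.
#' @param pi_j Length-p predictor propensities.
#' @export
log_prior_gamma <- function(gamma, o, pi_j) {
  gamma <- rbind(gamma)
  pr <- outer(o, pi_j)
  if (any(pr > 1))
    stop("constraint o_k * pi_j <= 1 violated", call. = FALSE)
  sum(log(pr)[gamma]) + sum(log1p(-pr)[!gamma])
}

# Row-k version used inside the sweep (o scalar).
.log_prior_gamma_row <- function(gamma_k, o_k, pi_j) {
  pr <- o_k * pi_j
  sum(log(pr[gamma_k])) + sum(log1p(-pr[!gamma_k]))
}

#' Update the hotspot hyperparameters
#'
#' Per-response sparsity levels `o_k` are updated by an independence
#' Metropolis-Hastings step proposing from `Beta(a_o + |gamma_k|, b_o + p -
#' |gamma_k|)` (the exact conjugate full conditional when `pi_j = 1`, so the
#' move is always accepted in the beta-binomial variant); per-predictor
#' propensities `pi_j` use a log-scale random-walk against their gamma prior,
#' all columns in parallel.  Proposals violating `o_k pi_j <= 1` are rejected
#' outright.
#'
#' @param gamma s x p logical matrix.
#' @param o,pi_j Current values.
#' @param a_o,b_o Beta prior for `o_k`.
#' @param a_pi,b_pi Gamma prior (shape, rate) for `pi_j`.
#' @param hotspot If `FALSE`, `pi_j` is held at 1 (beta-binomial variant).
#' @param step_pi Log-scale proposal sd for `pi_j`.
#' @return List with `o`, `pi_j`, `acc_o`, `acc_pi` (acceptance fractions).
#' @export
update_hotspot_params <- function(gamma, o, pi_j, a_o, b_o,
                                  a_pi = 0.5, b_pi = 0.5,
                                  hotspot = TRUE, step_pi = 0.4) {
  s <- nrow(gamma)
  p <- ncol(gamma)
  n1k <- rowSums(gamma)
  # independence proposal from the pi = 1 conjugate full conditional,
  # accepted against the hotspot likelihood (always accepted when pi = 1)
  o_star <- stats::rbeta(s, a_o + n1k, b_o + p - n1k)
  la <- .o_target_vec(o_star, gamma, n1k, pi_j, a_o, b_o) -
    .o_target_vec(o, gamma, n1k, pi_j, a_o, b_o) +
    stats::dbeta(o, a_o + n1k, b_o + p - n1k, log = TRUE) -
    stats::dbeta(o_star, a_o + n1k, b_o + p - n1k, log = TRUE)
  if (hotspot) la[o_star * max(pi_j) > 1] <- -Inf
  acc <- is.finite(la) & log(stats::runif(s)) < la
  o[acc] <- o_star[acc]
  acc_o <- mean(acc)
  acc_pi <- 0
  if (hotspot) {
    pi_star <- pi_j * exp(step_pi * stats::rnorm(p))
    ok <- pi_star * max(o) <= 1
    n1j <- colSums(gamma)
    lp_cur <- .pi_target(pi_j, n1j, gamma, o, a_pi, b_pi)
    lp_new <- .pi_target(pi_star, n1j, gamma, o, a_pi, b_pi)
    la <- lp_new - lp_cur + log(pi_star) - log(pi_j)
    acc <- ok & is.finite(la) & log(stats::runif(p)) < la
    pi_j[acc] <- pi_star[acc]
    acc_pi <- mean(acc)
  }
  list(o = o, pi_j = pi_j, acc_o = acc_o, acc_pi = acc_pi)
}

# vectorised over k: log Beta prior + Bernoulli likelihood of each row
.o_target_vec <- function(o, gamma, n1k, pi_j, a_o, b_o) {
  bad <- o <= 0 | o >= 1
  o_ <- pmin(pmax(o, 1e-300), 1 - 1e-12)
  pr <- outer(o_, pi_j)            # s x p
  pr[pr >= 1] <- 1 - 1e-12
  out <- (a_o - 1) * log(o_) + (b_o - 1) * log1p(-o_) +
    n1k * 0 + rowSums(log(pr) * gamma + log1p(-pr) * !gamma)
  out[bad] <- -Inf
  out
}

# vectorised over j: gamma prior + Bernoulli likelihood of column j
.pi_target <- function(pi_j, n1j, gamma, o, a_pi, b_pi) {
  bad <- pi_j <= 0
  pr <- outer(o, pi_j) # s x p
  pr[pr >= 1] <- 1 - 1e-12
  ll <- colSums(log1p(-pr) * !gamma) + n1j * log(pmax(pi_j, 1e-300))
  out <- (a_pi - 1) * log(pmax(pi_j, 1e-300)) - b_pi * pi_j + ll
  out[bad] <- -Inf
  out
}

#' Conjugate update of the slab variance
#'
#' `w ~ IGa(a_w + |gamma|/2, b_w + sum beta^2 / 2)` over all included
#' coefficients across responses.
#'
#' @param beta,gamma Current state.
#' @param a_w,b_w Inverse-gamma prior.
#' @export
update_w <- function(beta, gamma, a_w = 0.1, b_w = 0.1) {
  ng <- sum(gamma)
  ssq <- sum(beta[gamma]^2)
  1 / stats::rgamma(1L, a_w + ng / 2, rate = b_w + ssq / 2)
}

#' Default hotspot hyperparameters from a target prior model size
#'
#' Chooses `(a_o, b_o)` so that the prior expectation and variance of the
#' model size `p * o_k` per response match `mean_size` and `var_size`
#' (defaults 2 and 2, a strongly sparse prior).
#'
#' @param p Number of predictors.
#' @param mean_size,var_size Prior moments of the per-response model size.
#' @return Named vector with `a_o`, `b_o`.
#' @export
hotspot_beta_params <- function(p, mean_size = 2, var_size = 2) {
  mu <- mean_size / p
  v <- var_size / p^2
  ab <- mu * (1 - mu) / v - 1
  c(a_o = mu * ab, b_o = (1 - mu) * ab)
}
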