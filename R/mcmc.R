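# MCMC engine: one sweep = joint {graph, sigma^2, rho} update (collapsed over
# the reparametrised covariance), per-response joint {gamma_k, beta_k} updates
# (collapsed over the coefficients), then the hyperparameter updates for
# o_k, pi_j, w, tau and eta.  Both collapsed acceptances use marginal
# likelihoods only: the proposal and target densities of the implicitly
# marginalised parameters cancel and are never evaluated.
#
# Chain state lives in an environment so that the inner loops update the
# residual / innovation matrices in place.

#' Run configuration for the SUR sampler
#'
#' @param n_iter Total sweeps.
#' @param burnin Burn-in sweeps (default 20% of `n_iter`).
#' @param thin Thinning interval for scalar diagnostics.
#' @param seed Integer seed; a run is fully reproducible given the seed.
#' @param covariance `"sparse"` (decomposable-graph hyper inverse-Wishart) or
#'   `"dense"` (inverse-Wishart).
#' @param gamma_prior `"hotspot"` (`gamma_kj ~ Ber(o_k pi_j)`) or
#'   `"betabinomial"` (`pi_j` fixed at 1).
#' @param n_chains Size of the tempered ensemble (1 = plain chain).  Only the
#'   unit-temperature chain contributes to posterior summaries.
#' @param graph_moves Collapsed single-edge graph updates per sweep.
#' @param standardise Centre and scale responses and predictors.
#' @param nu Inverse-Wishart degrees of freedom (default `s + 2`).
#' @param prior_model_size,prior_model_size_var Prior mean and variance of
#'   the per-response model size, used to derive `(a_o, b_o)` when not given.
#' @param a_o,b_o Beta prior on the response sparsity `o_k` (override).
#' @param a_pi,b_pi Gamma prior (shape, rate) on the propensity `pi_j`.
#' @param a_w,b_w Inverse-gamma prior on the slab variance `w`.
#' @param a_tau,b_tau Gamma prior on the covariance scale `tau`.
#' @param a_eta,b_eta Beta prior on the edge probability `eta`.
#' @param temperature_ratio Initial geometric spacing of the ladder.
#' @param adapt Adapt proposal scales (and the ladder) during burn-in;
#'   adaptation is frozen afterwards.
#' @param beta_refresh Gibbs-refresh the coefficients from their full
#'   conditional after each accept/reject of the selection move.
#' @param max_model_size Optional cap on per-response model size.
#' @param prior_only Run with the likelihood switched off (data treated as
#'   empty); used for prior-calibration checks.
#' @param full_trace Keep every post-burn-in inclusion matrix (memory heavy;
#'   intended for cross-checks on small problems).
#' @return A list of class `sur_config`.
#' @export
sur_config <- function(n_iter = 25000L, burnin = NULL, thin = 10L, seed = 1L,
                       covariance = c("sparse", "dense"),
                       gamma_prior = c("hotspot", "betabinomial"),
                       n_chains = 2L, graph_moves = 5L, standardise = TRUE,
                       nu = NULL,
                       prior_model_size = 2, prior_model_size_var = 2,
                       a_o = NULL, b_o = NULL,
                       a_pi = 0.5, b_pi = 0.5,
                       a_w = 0.1, b_w = 0.1,
                       a_tau = 0.1, b_tau = 0.1,
                       a_eta = 1, b_eta = 1,
                       temperature_ratio = 1.5,
                       adapt = TRUE, beta_refresh = TRUE,
                       max_model_size = Inf,
                       prior_only = FALSE, full_trace = FALSE) {
  if (is.null(burnin)) burnin <- as.integer(ceiling(n_iter * 0.2))
  stopifnot(burnin < n_iter, n_chains >= 1L, graph_moves >= 0L)
  structure(list(
    n_iter = as.integer(n_iter), burnin = as.integer(burnin),
    thin = as.integer(thin), seed = as.integer(seed),
    covariance = match.arg(covariance),
    gamma_prior = match.arg(gamma_prior),
    n_chains = as.integer(n_chains), graph_moves = as.integer(graph_moves),
    standardise = standardise, nu = nu,
    prior_model_size = prior_model_size,
    prior_model_size_var = prior_model_size_var,
    a_o = a_o, b_o = b_o, a_pi = a_pi, b_pi = b_pi,
    a_w = a_w, b_w = b_w, a_tau = a_tau, b_tau = b_tau,
    a_eta = a_eta, b_eta = b_eta,
    temperature_ratio = temperature_ratio,
    adapt = adapt, beta_refresh = beta_refresh,
    max_model_size = max_model_size,
    prior_only = prior_only, full_trace = full_trace
  ), class = "sur_config")
}

# fresh chain state (an environment: updated in place by the sweep)
.init_state <- function(n, s, p, Y, jt0, a_o, b_o) {
  e <- new.env(parent = emptyenv())
  e$jt <- jt0
  e$sigma2 <- rep(1, s)
  e$rho <- matrix(0, s, s)
  e$sel <- rep(list(integer(0)), s)    # selected predictor indices per response
  e$bvals <- rep(list(numeric(0)), s)  # coefficients on the selected support
  e$o <- rep(a_o / (a_o + b_o), s)
  e$pi_j <- rep(1, p)
  e$w <- 1; e$tau <- 1; e$eta <- 0.5
  e$U <- Y + 0        # raw residuals
  e$E <- Y + 0        # innovations u_k - U_L rho_k
  e$F_ <- matrix(0, n, s)
  e$preds <- .pred_sets(jt0)
  e$succ <- .succ_sets(jt0)
  e
}

.state_gamma <- function(st, s, p) {
  g <- matrix(FALSE, s, p)
  for (k in seq_len(s)) g[k, st$sel[[k]]] <- TRUE
  g
}

.state_beta <- function(st, s, p) {
  b <- matrix(0, s, p)
  for (k in seq_len(s)) b[k, st$sel[[k]]] <- st$bvals[[k]]
  b
}

#' Fit the sparse SUR model by MCMC
#'
#' Runs the full sampler: collapsed graph / covariance updates, collapsed
#' per-response selection updates with coefficient draws from their exact
#' full conditionals, and hyperparameter sweeps.  Returns running posterior
#' means of the inclusion indicators (mPIP), of the graph edges (mEPIP) and
#' of the hotspot parameters, plus thinned scalar diagnostics.
#'
#' @param Y n x s numeric response matrix (no missing values).
#' @param X n x p numeric predictor matrix (shared across responses).
#' @param config A [sur_config()] object.
#' @return Object of class `sur_fit` with elements `mpip` (s x p), `mepip`
#'   (s x s, unit diagonal), `o_mean`, `pi_mean`, `diagnostics` (data frame of
#'   thinned scalars), `accept` (acceptance fractions), `state` (final cold
#'   chain state), `hyper`, `config`, `labels`, `elapsed`.
#' @export
run_chain <- function(Y, X, config = sur_config()) {
  t0 <- proc.time()[["elapsed"]]
  stopifnot(inherits(config, "sur_config"))
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (anyNA(Y) || anyNA(X))
    stop("missing values are not supported; complete data are assumed",
         call. = FALSE)
  if (nrow(Y) != nrow(X))
    stop(sprintf("sample-count mismatch: Y has %d rows, X has %d",
                 nrow(Y), nrow(X)), call. = FALSE)
  labels <- list(response = colnames(Y), predictor = colnames(X))
  s <- ncol(Y); p <- ncol(X)
  if (config$prior_only) {
    Y <- matrix(0, 0L, s); X <- matrix(0, 0L, p)
  } else if (config$standardise) {
    Y <- scale(Y); X <- scale(X)
    bad <- !is.finite(colSums(X))
    if (any(bad)) stop("constant predictor column(s): ",
                       paste(which(bad), collapse = ", "), call. = FALSE)
    attributes(Y)[c("scaled:center", "scaled:scale")] <- NULL
    attributes(X)[c("scaled:center", "scaled:scale")] <- NULL
  }
  n <- nrow(Y)
  nu <- if (is.null(config$nu)) s + 2 else config$nu
  if (nu <= s - 1) stop("nu must exceed s - 1", call. = FALSE)
  if (is.null(config$a_o) || is.null(config$b_o)) {
    ab <- hotspot_beta_params(p, config$prior_model_size,
                              config$prior_model_size_var)
    a_o <- if (is.null(config$a_o)) ab[["a_o"]] else config$a_o
    b_o <- if (is.null(config$b_o)) ab[["b_o"]] else config$b_o
  } else {
    a_o <- config$a_o; b_o <- config$b_o
  }
  hotspot <- config$gamma_prior == "hotspot"
  sparse <- config$covariance == "sparse"
  XtX <- if (p <= 3000L) crossprod(X) else NULL
  m_edges <- s * (s - 1L) / 2
  set.seed(config$seed)

  jt0 <- if (sparse) junction_tree(matrix(FALSE, s, s)) else dense_jt(s)
  nch <- config$n_chains
  chains <- lapply(seq_len(nch), function(i) .init_state(n, s, p, Y, jt0, a_o, b_o))
  log_ratio <- log(config$temperature_ratio)
  inv_temp <- config$temperature_ratio^-(seq_len(nch) - 1L)

  step_tau <- 0.5; step_pi <- 0.4
  acc <- c(graph = 0, graph_n = 0, gamma = 0, gamma_n = 0,
           tau = 0, tau_n = 0, o = 0, o_n = 0, pi = 0, pi_n = 0,
           swap = 0, swap_n = 0)
  win <- c(tau = 0, tau_n = 0, pi = 0, pi_n = 0, swap = 0, swap_n = 0)

  mpip_acc <- matrix(0, s, p)
  mepip_acc <- matrix(0, s, s)
  o_acc <- numeric(s); pi_acc <- numeric(p); n_acc <- 0L
  trace_gamma <- if (config$full_trace)
    vector("list", config$n_iter - config$burnin)
  diag_rows <- vector("list", config$n_iter %/% config$thin + 1L)
  n_diag <- 0L

  for (iter in seq_len(config$n_iter)) {
    adapting <- config$adapt && iter <= config$burnin
    for (ci in seq_len(nch)) {
      st <- chains[[ci]]
      invT <- inv_temp[ci]
      cold <- ci == 1L

      ## --- joint {J, sigma^2, rho} update ------------------------------
      UtU <- crossprod(st$U) * invT
      Mt <- UtU; diag(Mt) <- diag(Mt) + st$tau
      n_eff <- n * invT
      if (sparse) {
        adj <- st$jt$adjacency | FALSE   # fresh copy: mutated in place below
        n_acc_graph <- .cpp_graph_updates(adj, Mt, n_eff, nu, st$tau, st$eta,
                                          config$graph_moves)
        if (n_acc_graph > 0L) st$jt <- junction_tree(adj)
        if (cold) {
          acc["graph"] <- acc["graph"] + n_acc_graph
          acc["graph_n"] <- acc["graph_n"] + config$graph_moves
        }
        st$eta <- stats::rbeta(1L, config$a_eta + st$jt$n_edges,
                               config$b_eta + m_edges - st$jt$n_edges)
      }
      st$preds <- .pred_sets(st$jt)
      st$succ <- .succ_sets(st$jt)
      rc <- .cpp_sample_reparam(Mt, st$preds, n_eff, nu)
      st$sigma2 <- drop(rc$sigma2); st$rho <- rc$rho
      for (mm in seq_len(s)) {
        idx <- st$preds[[mm]]
        st$E[, mm] <- if (length(idx))
          st$U[, mm] - st$U[, idx, drop = FALSE] %*% st$rho[mm, idx]
        else st$U[, mm]
      }

      ## --- per-response joint {gamma_k, beta_k} updates ----------------
      if (!is.null(XtX)) {
        n_acc_g <- .cpp_gamma_sweep(st$U, st$E, st$F_, st$sel, st$bvals,
                                    X, XtX, st$rho, st$sigma2,
                                    st$preds, st$succ, st$o, st$pi_j,
                                    st$w, invT, config$max_model_size,
                                    config$beta_refresh)
      } else {
        n_acc_g <- 0L
        for (k in seq_len(s))
          n_acc_g <- n_acc_g +
            .gamma_beta_update(st, k, X, XtX, Y, n, p, invT, config, cold)
      }
      if (cold) {
        acc["gamma"] <- acc["gamma"] + n_acc_g
        acc["gamma_n"] <- acc["gamma_n"] + s
      }

      ## --- hyperparameters --------------------------------------------
      hp <- .cpp_hotspot_update(st$sel, p, st$o, st$pi_j, a_o, b_o,
                                config$a_pi, config$b_pi, hotspot, step_pi)
      st$o <- hp$o; st$pi_j <- hp$pi_j
      ng <- sum(lengths(st$sel))
      ssq <- sum(unlist(st$bvals, use.names = FALSE)^2)
      st$w <- 1 / stats::rgamma(1L, config$a_w + ng / 2,
                                rate = config$b_w + ssq / 2)
      rc_cur <- structure(list(sigma2 = st$sigma2, rho = st$rho,
                               order = st$jt$order), class = "sur_reparam")
      tu <- update_tau(rc_cur, st$jt, st$tau, nu, config$a_tau, config$b_tau,
                       step = step_tau)
      st$tau <- tu$tau
      if (cold) {
        acc["o"] <- acc["o"] + hp$acc_o; acc["o_n"] <- acc["o_n"] + 1
        acc["pi"] <- acc["pi"] + hp$acc_pi; acc["pi_n"] <- acc["pi_n"] + 1
        acc["tau"] <- acc["tau"] + tu$accepted; acc["tau_n"] <- acc["tau_n"] + 1
        win["tau"] <- win["tau"] + tu$accepted; win["tau_n"] <- win["tau_n"] + 1
        win["pi"] <- win["pi"] + hp$acc_pi; win["pi_n"] <- win["pi_n"] + 1
      }
    }

    ## --- between-chain exchange --------------------------------------
    if (nch > 1L) {
      ci <- sample.int(nch - 1L, 1L)
      ll_a <- .state_loglik(chains[[ci]])
      ll_b <- .state_loglik(chains[[ci + 1L]])
      la <- (inv_temp[ci] - inv_temp[ci + 1L]) * (ll_b - ll_a)
      sw <- is.finite(la) && log(stats::runif(1L)) < la
      if (sw) {
        tmp <- chains[[ci]]; chains[[ci]] <- chains[[ci + 1L]]
        chains[[ci + 1L]] <- tmp
      }
      acc["swap"] <- acc["swap"] + sw; acc["swap_n"] <- acc["swap_n"] + 1
      win["swap"] <- win["swap"] + sw; win["swap_n"] <- win["swap_n"] + 1
    }

    ## --- adaptation (burn-in only; frozen afterwards) -----------------
    if (adapting && iter %% 50L == 0L) {
      if (win["tau_n"] > 0)
        step_tau <- step_tau * exp(0.5 * (win["tau"] / win["tau_n"] - 0.44))
      if (win["pi_n"] > 0)
        step_pi <- step_pi * exp(0.5 * (win["pi"] / win["pi_n"] - 0.25))
      if (nch > 1L && win["swap_n"] > 0) {
        log_ratio <- max(0.01, log_ratio +
                           0.5 * (win["swap"] / win["swap_n"] - 0.25) *
                           log_ratio)
        inv_temp <- exp(-log_ratio * (seq_len(nch) - 1L))
      }
      win[] <- 0
    }

    ## --- accumulate & diagnostics (cold chain) ------------------------
    st <- chains[[1L]]
    if (iter > config$burnin) {
      js <- unlist(st$sel, use.names = FALSE)
      if (length(js)) {
        cells <- rep.int(seq_len(s), lengths(st$sel)) + (js - 1L) * s
        mpip_acc[cells] <- mpip_acc[cells] + 1
      }
      mepip_acc <- mepip_acc + st$jt$adjacency
      o_acc <- o_acc + st$o; pi_acc <- pi_acc + st$pi_j
      n_acc <- n_acc + 1L
      if (config$full_trace) trace_gamma[[n_acc]] <- .state_gamma(st, s, p)
    }
    if (iter %% config$thin == 0L) {
      ll <- .state_loglik(st)
      if (!is.finite(ll)) {
        dump <- file.path(tempdir(), sprintf("sur_state_dump_%d.rds", iter))
        saveRDS(as.list(st), dump)
        stop("non-finite log likelihood at iteration ", iter,
             "; state dumped to ", dump, call. = FALSE)
      }
      n_diag <- n_diag + 1L
      diag_rows[[n_diag]] <- data.frame(
        iteration = iter, loglik = ll, n_gamma = sum(lengths(st$sel)),
        n_edges = st$jt$n_edges, w = st$w, tau = st$tau, eta = st$eta)
    }
  }

  st <- chains[[1L]]
  mepip <- mepip_acc / max(n_acc, 1L)
  diag(mepip) <- 1
  rates <- c(graph = unname(acc["graph"] / max(acc["graph_n"], 1)),
             gamma = unname(acc["gamma"] / max(acc["gamma_n"], 1)),
             tau = unname(acc["tau"] / max(acc["tau_n"], 1)),
             o = unname(acc["o"] / max(acc["o_n"], 1)),
             pi = unname(acc["pi"] / max(acc["pi_n"], 1)),
             swap = unname(acc["swap"] / max(acc["swap_n"], 1)))
  out <- list(
    mpip = mpip_acc / max(n_acc, 1L),
    mepip = mepip,
    o_mean = o_acc / max(n_acc, 1L),
    pi_mean = pi_acc / max(n_acc, 1L),
    diagnostics = do.call(rbind, diag_rows[seq_len(n_diag)]),
    accept = rates,
    state = list(gamma = .state_gamma(st, s, p), beta = .state_beta(st, s, p),
                 adjacency = st$jt$adjacency, sigma2 = st$sigma2,
                 rho = st$rho, o = st$o, pi_j = st$pi_j,
                 w = st$w, tau = st$tau, eta = st$eta),
    hyper = list(nu = nu, a_o = a_o, b_o = b_o),
    config = config,
    labels = labels,
    elapsed = proc.time()[["elapsed"]] - t0
  )
  if (config$full_trace) out$trace_gamma <- trace_gamma[seq_len(n_acc)]
  class(out) <- "sur_fit"
  out
}

#' @export
print.sur_fit <- function(x, ...) {
  cat(sprintf("sur_fit: %d x %d mPIP, %d post-burn-in sweeps, %.1fs\n",
              nrow(x$mpip), ncol(x$mpip),
              x$config$n_iter - x$config$burnin, x$elapsed))
  cat(sprintf("  associations with mPIP >= 0.5: %d; edges with mEPIP >= 0.5: %d\n",
              sum(x$mpip >= 0.5), sum(x$mepip[upper.tri(x$mepip)] >= 0.5)))
  invisible(x)
}

# One collapsed {gamma_k, beta_k} Metropolis-Hastings update, mutating the
# state environment.  Returns 1 if the selection move was accepted, else 0.
# The acceptance ratio is built from collapsed evidences and priors only:
# neither the proposed coefficients nor their density is ever evaluated.
.gamma_beta_update <- function(st, k, X, XtX, Y, n, p, invT, config, cold) {
  succ_k <- st$succ[[k]]
  sigma2 <- st$sigma2; rho <- st$rho
  if (length(succ_k)) {
    w1 <- rho[succ_k, k] / sigma2[succ_k]
    yt <- (st$E[, k] + st$F_[, k]) / sigma2[k] -
      st$E[, succ_k, drop = FALSE] %*% w1 +
      st$F_[, k] * sum(w1 * rho[succ_k, k])
    ck <- 1 / sigma2[k] + sum(rho[succ_k, k]^2 / sigma2[succ_k])
  } else {
    yt <- (st$E[, k] + st$F_[, k]) / sigma2[k]
    ck <- 1 / sigma2[k]
  }
  yt <- yt * invT
  ck <- ck * invT
  cur_sel <- st$sel[[k]]
  cur <- .gamma_fit(cur_sel, ck, XtX, X, yt, st$w)
  gk <- logical(p); gk[cur_sel] <- TRUE
  prop <- propose_gamma(gk)
  new_sel <- which(prop$gamma_star)
  accepted <- FALSE
  if (length(new_sel) <= config$max_model_size) {
    new <- .gamma_fit(new_sel, ck, XtX, X, yt, st$w)
    la <- new$ev - cur$ev + prop$log_proposal_ratio +
      .log_prior_gamma_row(prop$gamma_star, st$o[k], st$pi_j) -
      .log_prior_gamma_row(gk, st$o[k], st$pi_j)
    if (is.finite(la) && log(stats::runif(1L)) < la) accepted <- TRUE
  }
  if (accepted) {
    fit <- new; sel <- new_sel
  } else {
    fit <- cur; sel <- cur_sel
  }
  if (accepted || config$beta_refresh) {
    beta_k <- if (length(sel))
      fit$mu + backsolve(fit$chol, stats::rnorm(length(sel))) else numeric(0)
    .set_beta_row(st, k, sel, beta_k, X)
  }
  as.integer(accepted)
}

# collapsed evidence + sampling ingredients for one selection vector
.gamma_fit <- function(sel, ck, XtX, X, yt, w) {
  d <- length(sel)
  if (d == 0L) return(list(ev = 0, chol = NULL, mu = numeric(0)))
  Wk <- if (is.null(XtX)) ck * crossprod(X[, sel, drop = FALSE])
        else ck * XtX[sel, sel, drop = FALSE]
  diag(Wk) <- diag(Wk) + 1 / w
  r <- chol(Wk)
  h <- crossprod(X[, sel, drop = FALSE], yt)
  z <- backsolve(r, h, transpose = TRUE)
  list(ev = -d / 2 * log(w) - sum(log(diag(r))) + sum(z * z) / 2,
       chol = r, mu = drop(backsolve(r, z)))
}

# Write the new coefficients of response k and refresh the fitted values,
# raw residuals and innovations in place: a change `delta` in the fitted
# column k lowers u_k by delta and raises e_m by rho_mk * delta for the
# later-ordered same-prime responses m.
.set_beta_row <- function(st, k, sel, beta_k, X) {
  st$sel[[k]] <- sel
  st$bvals[[k]] <- beta_k
  f_new <- if (length(sel)) drop(X[, sel, drop = FALSE] %*% beta_k) else 0
  delta <- f_new - st$F_[, k]
  st$F_[, k] <- f_new
  st$U[, k] <- st$U[, k] - delta
  idx <- st$preds[[k]]
  st$E[, k] <- if (length(idx))
    st$U[, k] - st$U[, idx, drop = FALSE] %*% st$rho[k, idx] else st$U[, k]
  succ_k <- st$succ[[k]]
  if (length(succ_k))
    st$E[, succ_k] <- st$E[, succ_k, drop = FALSE] +
      tcrossprod(delta, st$rho[succ_k, k])
  invisible(st)
}

# full factorised log likelihood of a chain state (unit temperature)
.state_loglik <- function(st) {
  n <- nrow(st$U)
  if (n == 0L) return(0)
  s <- ncol(st$U)
  sum(-n / 2 * log(2 * pi * st$sigma2) -
        colSums(st$E^2) / (2 * st$sigma2))
}
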