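# Decomposable-graph state machine: chordality testing (maximum cardinality
# search), junction trees, perfect elimination orderings, graph moves and the
# edge-count graph prior.
#
# Node indices are 0-free: everything here is 1-based, matching how nodes are
# labelled in all user-facing reports.

#' Validate and coerce an adjacency matrix
#'
#' @param adj Square matrix (logical or 0/1 numeric), symmetric with empty
#'   diagonal.
#' @return Logical adjacency matrix.
#' @keywords internal
.as_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop("adjacency must be a square matrix", call. = FALSE)
  storage.mode(adj) <- "logical"
  adj[is.na(adj)] <- FALSE
  if (any(diag(adj)))
    stop("adjacency must have an empty diagonal", call. = FALSE)
  if (!isTRUE(all(adj == t(adj))))
    stop("adjacency must be symmetric", call. = FALSE)
  dimnames(adj) <- NULL
  adj
}

# Maximum cardinality search with lowest-index tie-breaking; deterministic
# given the adjacency.  Returns the visit order (a candidate perfect
# elimination ordering read left to right).
.mcs_order <- function(adj) {
  .mcs_full(adj)$order
}

# compiled single-pass MCS (see src/kernels.cpp); .mcs_full_r is the pure-R
# reference used as an oracle in the tests
.mcs_full <- function(adj) .cpp_mcs(adj)

# Single-pass maximum cardinality search: visit order, per-position earlier
# neighbourhoods and their sizes (lambda), the chordality check and, for
# chordal graphs, the maximal cliques (a candidate {v} + earlier neighbours
# is maximal exactly when the next position's lambda does not grow by one).
.mcs_full_r <- function(adj) {
  s <- nrow(adj)
  wt <- numeric(s)
  ord <- integer(s)
  lambda <- integer(s)
  mv <- vector("list", s)
  done <- logical(s)
  fail <- NULL
  for (i in seq_len(s)) {
    v <- which.max(wt) # lowest index among maxima
    ord[i] <- v
    done[v] <- TRUE
    wt[v] <- -Inf
    nb <- which(adj[, v])
    e <- nb[done[nb]]
    e <- e[e != v]
    lambda[i] <- length(e)
    mv[[i]] <- e
    later <- nb[!done[nb]]
    wt[later] <- wt[later] + 1
    if (is.null(fail) && length(e) > 1L) {
      # perfect-elimination check: all earlier neighbours of v must be
      # adjacent to the most recently visited one
      u <- e[which.max(match(e, ord[seq_len(i - 1L)]))]
      rest <- e[e != u]
      bad <- rest[!adj[rest, u]]
      if (length(bad)) fail <- list(v = v, u = u, w = bad[[1L]])
    }
  }
  out <- list(order = ord, lambda = lambda, mv = mv, ok = is.null(fail),
              fail = fail)
  if (out$ok) {
    last <- c(lambda[-1L] <= lambda[-s], TRUE)
    out$cliques <- lapply(which(last), function(i) sort(c(ord[i], mv[[i]])))
  }
  out
}

# Check that `ord` is a perfect elimination ordering: each node's
# earlier-ordered neighbours must contain a single "maximal" one adjacent to
# all the others.  On failure returns the offending triple (v, u, w) with
# u, w earlier neighbours of v and u -- w missing.
.check_peo <- function(adj, ord) {
  s <- length(ord)
  pos <- integer(s)
  pos[ord] <- seq_len(s)
  for (i in seq_len(s)[-1]) {
    v <- ord[i]
    e <- which(adj[, v])
    e <- e[pos[e] < i]
    if (length(e) > 1L) {
      u <- e[which.max(pos[e])]
      rest <- e[e != u]
      bad <- rest[!adj[rest, u]]
      if (length(bad))
        return(list(ok = FALSE, v = v, u = u, w = bad[[1L]]))
    }
  }
  list(ok = TRUE)
}

# Certificate of non-chordality: a chordless cycle of length >= 4 through v,
# built from the failing MCS triple (v, u, w) by a shortest u--w path that
# avoids the rest of v's closed neighbourhood.
.chordless_cycle <- function(adj, v, u, w) {
  s <- nrow(adj)
  banned <- logical(s)
  banned[v] <- TRUE
  nb_v <- which(adj[, v])
  banned[nb_v] <- TRUE
  banned[c(u, w)] <- FALSE
  # BFS from u to w in the allowed subgraph
  prev <- integer(s)
  seen <- logical(s)
  seen[u] <- TRUE
  frontier <- u
  while (length(frontier) && !seen[w]) {
    nxt <- integer(0)
    for (x in frontier) {
      for (y in which(adj[, x])) {
        if (!seen[y] && !banned[y]) {
          seen[y] <- TRUE
          prev[y] <- x
          nxt <- c(nxt, y)
        }
      }
    }
    frontier <- nxt
  }
  if (!seen[w]) return(c(v, u, w)) # fallback; should not happen for MCS failures
  path <- w
  while (path[[1L]] != u) path <- c(prev[path[[1L]]], path)
  c(v, path)
}

#' Test whether a graph is decomposable (chordal)
#'
#' @param adj Symmetric logical/0-1 adjacency matrix with empty diagonal.
#' @return `TRUE` or `FALSE`.
#' @export
is_decomposable <- function(adj) {
  adj <- .as_adjacency(adj)
  .mcs_full(adj)$ok
}

# Order cliques by Prim's maximum-weight spanning tree on intersection sizes.
# The visiting order satisfies the running-intersection property; components
# of a disconnected graph are joined through empty separators.
.prim_clique_tree <- function(cliques, s) {
  q <- length(cliques)
  if (q == 1L)
    return(list(order = 1L, parent = 0L))
  memb <- matrix(FALSE, q, s)
  for (i in seq_len(q)) memb[i, cliques[[i]]] <- TRUE
  w <- tcrossprod(memb) # |C_i intersect C_j|
  diag(w) <- -1
  in_tree <- logical(q)
  in_tree[1L] <- TRUE
  ord <- integer(q)
  par <- integer(q)
  ord[1L] <- 1L
  best <- w[, 1L]
  best_par <- rep(1L, q)
  for (i in 2:q) {
    cand <- which(!in_tree)
    nxt <- cand[which.max(best[cand])]
    ord[i] <- nxt
    par[i] <- best_par[nxt]
    in_tree[nxt] <- TRUE
    upd <- which(!in_tree & w[, nxt] > best)
    best[upd] <- w[upd, nxt]
    best_par[upd] <- nxt
  }
  list(order = ord, parent = par) # parent[i] indexes into `ord` positions? no: clique ids
}

#' Build the junction tree of a decomposable graph
#'
#' Prime components (maximal cliques) are found by maximum cardinality search
#' with lowest-index tie-breaking and arranged along a maximum-weight spanning
#' tree of clique intersections, which guarantees the running-intersection
#' property.  A disconnected graph is represented as a forest joined through
#' empty separators, so `Q` counts primes across all components.
#'
#' @param adj Symmetric logical/0-1 adjacency matrix with empty diagonal.
#' @return An object of class `sur_jt` with elements `adjacency`, `primes`
#'   (ordered list `P_1..P_Q`), `separators` (`S_q = P_q` intersected with the
#'   history; `S_1` is empty), `residuals` (`R_q = P_q \ S_q`), `parent`
#'   (index of the prime each prime attaches to, 0 for the first),
#'   `order` (a perfect elimination ordering of the nodes), `pos` (its
#'   inverse), `q_of` (prime-residual index of each node), `n_edges`.
#' @export
junction_tree <- function(adj) {
  adj <- .as_adjacency(adj)
  mcs <- .mcs_full(adj)
  if (!mcs$ok) {
    cyc <- .chordless_cycle(adj, mcs$fail$v, mcs$fail$u, mcs$fail$w)
    stop(sprintf(
      "graph is not decomposable: chordless cycle (%s)",
      paste(cyc, collapse = "-")), call. = FALSE)
  }
  .junction_tree_chordal(adj, mcs)
}

# internal constructor: takes a successful .mcs_full() result
.junction_tree_chordal <- function(adj, mcs) {
  s <- nrow(adj)
  cliques <- mcs$cliques
  tr <- .prim_clique_tree(cliques, s)
  primes <- cliques[tr$order]
  qn <- length(primes)
  parent_of_pos <- integer(qn)
  if (qn > 1L) {
    # map clique ids back to positions in the prime order
    posq <- integer(qn)
    posq[tr$order] <- seq_len(qn)
    parent_of_pos[2:qn] <- posq[tr$parent[2:qn]]
  }
  separators <- vector("list", qn)
  residuals <- vector("list", qn)
  separators[[1L]] <- integer(0)
  residuals[[1L]] <- primes[[1L]]
  seen <- logical(s)
  seen[primes[[1L]]] <- TRUE
  if (qn > 1L) {
    for (q in 2:qn) {
      p <- primes[[q]]
      separators[[q]] <- p[seen[p]]
      residuals[[q]] <- p[!seen[p]]
      seen[p] <- TRUE
    }
  }
  node_order <- unlist(residuals, use.names = FALSE)
  pos <- integer(s)
  pos[node_order] <- seq_len(s)
  q_of <- integer(s)
  for (q in seq_len(qn)) q_of[residuals[[q]]] <- q
  structure(list(
    adjacency = adj,
    primes = primes,
    separators = separators,
    residuals = residuals,
    parent = parent_of_pos,
    order = node_order,
    pos = pos,
    q_of = q_of,
    n_edges = sum(adj) %/% 2L,
    s = s
  ), class = "sur_jt")
}

#' @export
print.sur_jt <- function(x, ...) {
  cat(sprintf("Junction tree: %d nodes, %d edges, %d prime component(s)\n",
              x$s, x$n_edges, length(x$primes)))
  invisible(x)
}

#' Perfect elimination ordering of a junction tree
#'
#' Lists the nodes of the first prime, then the residuals `R_2..R_Q` in prime
#' order (the order of nodes within a residual is immaterial for the model;
#' this implementation sorts by node index).  For every node the prime-residual
#' index `q` and the within-residual index `t = xi(k) - |H_q|` are returned.
#'
#' @param jt A `sur_jt` object from [junction_tree()].
#' @return List with `order` (node ids by position), `pos` (position of each
#'   node), `q` (prime-residual index per node) and `t` (within-residual index
#'   per node).
#' @export
perfect_elimination_order <- function(jt) {
  stopifnot(inherits(jt, "sur_jt"))
  h_sizes <- cumsum(c(0L, vapply(jt$residuals, length, integer(1))))
  tt <- jt$pos - h_sizes[jt$q_of]
  list(order = jt$order, pos = jt$pos, q = jt$q_of, t = tt)
}

# Earlier-ordered neighbours of each node under the junction tree's perfect
# elimination ordering.  For a decomposable graph these are exactly the
# earlier nodes sharing a prime with k, i.e. the support of rho_k.
.pred_sets <- function(jt) {
  s <- jt$s
  adj <- jt$adjacency
  pos <- jt$pos
  out <- vector("list", s)
  for (k in seq_len(s)) {
    nb <- which(adj[, k])
    out[[k]] <- nb[pos[nb] < pos[k]]
  }
  out
}

# Later-ordered neighbours (the feedback set M in the coefficient update).
.succ_sets <- function(jt) {
  s <- jt$s
  adj <- jt$adjacency
  pos <- jt$pos
  out <- vector("list", s)
  for (k in seq_len(s)) {
    nb <- which(adj[, k])
    out[[k]] <- nb[pos[nb] > pos[k]]
  }
  out
}

#' Junction tree of the complete (dense) graph
#'
#' Convenience state for the dense-covariance model: a single prime containing
#' all nodes, ordered `1..s`.
#'
#' @param s Number of nodes.
#' @export
dense_jt <- function(s) {
  adj <- matrix(TRUE, s, s)
  diag(adj) <- FALSE
  .junction_tree_chordal(adj, .mcs_full(adj))
}

#' Log prior density of a graph given the edge probability
#'
#' The prior on the graph is proportional to a Binomial law on the edge count
#' `|J|` out of the `s(s-1)/2` possible edges, restricted (renormalised) to
#' decomposable graphs: `log p = log C(m, |J|) + |J| log(eta) +
#' (m - |J|) log(1 - eta)` up to the normalising constant over decomposable
#' graphs.  Because the binomial coefficient grows towards `m/2` edges while
#' decomposability prunes dense graphs unevenly, the renormalised prior
#' favours sparse structures.
#'
#' @param jt A `sur_jt` object (or anything with `n_edges` and `s`).
#' @param eta Edge-inclusion probability in (0,1).
#' @return Unnormalised log prior density.
#' @export
log_graph_prior <- function(jt, eta) {
  if (!is.numeric(eta) || length(eta) != 1L || is.na(eta) ||
      eta <= 0 || eta >= 1)
    stop("eta must be a single number in (0,1)", call. = FALSE)
  m <- jt$s * (jt$s - 1L) / 2
  lchoose(m, jt$n_edges) + jt$n_edges * log(eta) +
    (m - jt$n_edges) * log1p(-eta)
}

#' Gibbs update for the edge-probability hyperparameter
#'
#' Conjugate draw `eta ~ Beta(a_eta + |J|, b_eta + s(s-1)/2 - |J|)`.
#'
#' @param jt A `sur_jt` object.
#' @param a_eta,b_eta Beta prior hyperparameters.
#' @export
gibbs_update_eta <- function(jt, a_eta = 1, b_eta = 1) {
  m <- jt$s * (jt$s - 1L) / 2
  stats::rbeta(1L, a_eta + jt$n_edges, b_eta + m - jt$n_edges)
}

#' Propose a graph move
#'
#' Proposes the connection or disconnection of two node subsets; the
#' subset-selection distribution used here concentrates on singletons, i.e. a
#' uniformly chosen node pair whose edge is toggled.  A toggle that would
#' break decomposability is never emitted: the function returns `NULL`, which
#' callers treat as a (valid) stay-where-you-are proposal.  Because the pair
#' is uniform over all `s(s-1)/2` pairs in both directions, the kernel is
#' symmetric and the log proposal ratio is exactly 0; the reverse move (the
#' same pair) always has positive probability.
#'
#' @param jt Current `sur_jt` state.
#' @return `NULL` (blocked move) or a list with the proposed `jt`,
#'   `log_proposal_ratio` (always 0 for this kernel), the toggled `edge` and
#'   `added` (`TRUE` for a connect move).
#' @export
propose_graph_move <- function(jt) {
  s <- jt$s
  pair <- sample.int(s, 2L)
  i <- pair[[1L]]; j <- pair[[2L]]
  adj2 <- jt$adjacency
  added <- !adj2[i, j]
  adj2[i, j] <- added
  adj2[j, i] <- added
  mcs <- .mcs_full(adj2)
  if (!mcs$ok) return(NULL)
  list(jt = .junction_tree_chordal(adj2, mcs),
       log_proposal_ratio = 0,
       edge = c(min(i, j), max(i, j)),
       added = added)
}

#' Export a graph as an edge list
#'
#' @param adj Adjacency (or symmetric probability) matrix.
#' @param prob Optional matrix of edge probabilities conforming with `adj`.
#' @param labels Optional node labels (defaults to 1-based indices).
#' @return `data.frame` with columns `node1`, `node2`, `probability`.
#' @export
graph_edge_list <- function(adj, prob = NULL, labels = NULL) {
  adj <- .as_adjacency(adj)
  s <- nrow(adj)
  if (is.null(labels)) labels <- as.character(seq_len(s))
  idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  p <- if (is.null(prob)) rep(1, nrow(idx)) else prob[idx]
  data.frame(node1 = labels[idx[, 1L]], node2 = labels[idx[, 2L]],
             probability = p, stringsAsFactors = FALSE)
}

# Enumerate all decomposable graphs on s nodes (small s only); returns a
# logical vector over the 2^m edge subsets plus the edge count of each.
# Used by calibration tests as a brute-force oracle.
.enumerate_decomposable <- function(s) {
  pairs <- which(upper.tri(matrix(0, s, s)), arr.ind = TRUE)
  m <- nrow(pairs)
  n_graph <- 2L^m
  dec <- logical(n_graph)
  n_edge <- integer(n_graph)
  for (g in seq_len(n_graph) - 1L) {
    bits <- as.logical(bitwAnd(g, 2L^(seq_len(m) - 1L)))
    adj <- matrix(FALSE, s, s)
    adj[pairs[bits, , drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    dec[g + 1L] <- .mcs_full(adj)$ok
    n_edge[g + 1L] <- sum(bits)
  }
  list(decomposable = dec, n_edges = n_edge, m = m)
}
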