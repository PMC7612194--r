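// Numeric kernels for the MCMC sweep.  These mirror the reference R
// implementations in R/ (which remain the documented module surface and the
// oracle in tests); the C++ versions exist because the sampler visits them
// hundreds of thousands of times per run.  All randomness comes from R's RNG
// so runs are reproducible from the R-level seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// uniform integer in [0, n)
static inline int runif_int(int n) {
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// ---------------------------------------------------------------------------
// Maximum cardinality search with lowest-index tie-breaking: visit order,
// per-position earlier neighbourhoods, chordality flag (+ failing triple) and
// for chordal graphs the maximal cliques (Tarjan-Yannakakis rule).
// [[Rcpp::export(name = ".cpp_mcs")]]
List cpp_mcs(const LogicalMatrix& adj) {
  const int s = adj.nrow();
  std::vector<double> wt(s, 0.0);
  std::vector<bool> done(s, false);
  std::vector<int> ord(s), lambda(s), pos(s, -1);
  std::vector<std::vector<int>> mv(s);
  bool ok = true;
  int fv = 0, fu = 0, fw = 0;
  for (int i = 0; i < s; ++i) {
    int v = 0;
    double best = -1.0;
    for (int j = 0; j < s; ++j)
      if (!done[j] && wt[j] > best) { best = wt[j]; v = j; }
    ord[i] = v;
    pos[v] = i;
    done[v] = true;
    std::vector<int>& e = mv[i];
    for (int j = 0; j < s; ++j) {
      if (!adj(j, v) || j == v) continue;
      if (done[j]) e.push_back(j); else wt[j] += 1.0;
    }
    lambda[i] = (int)e.size();
    if (ok && lambda[i] > 1) {
      int u = e[0];
      for (size_t t = 1; t < e.size(); ++t)
        if (pos[e[t]] > pos[u]) u = e[t];
      for (size_t t = 0; t < e.size(); ++t) {
        if (e[t] != u && !adj(e[t], u)) { ok = false; fv = v; fu = u; fw = e[t]; break; }
      }
    }
  }
  List out = List::create(
    _["order"] = IntegerVector(ord.begin(), ord.end()),
    _["lambda"] = IntegerVector(lambda.begin(), lambda.end()),
    _["ok"] = ok);
  if (!ok) {
    out["fail"] = List::create(_["v"] = fv + 1, _["u"] = fu + 1, _["w"] = fw + 1);
  } else {
    List cl;
    for (int i = 0; i < s; ++i) {
      bool last = (i == s - 1) || (lambda[i + 1] <= lambda[i]);
      if (!last) continue;
      std::vector<int> k(mv[i]);
      k.push_back(ord[i]);
      std::sort(k.begin(), k.end());
      IntegerVector kk(k.begin(), k.end());
      cl.push_back(kk + 1);
    }
    out["cliques"] = cl;
  }
  // order to 1-based
  out["order"] = as<IntegerVector>(out["order"]) + 1;
  return out;
}

// ---------------------------------------------------------------------------
// Evidence contribution of one complete block A of Mt (1-based indices):
// the normal-inverse-gamma marginal terms of its nodes read off one Cholesky
// factor.  Matches .block_evidence() in R/reparam.R.
// [[Rcpp::export(name = ".cpp_block_evidence")]]
double cpp_block_evidence(const arma::mat& Mt, const IntegerVector& block,
                          double n, double nu, double tau, int s) {
  const int c = block.size();
  arma::uvec idx(c);
  for (int i = 0; i < c; ++i) idx[i] = block[i] - 1;
  arma::mat R = arma::chol(Mt.submat(idx, idx));
  double tot = 0.0, cumlr = 0.0;
  const double l2pi = std::log(2.0 * M_PI), ltau = std::log(tau),
               ltau2 = std::log(tau / 2.0);
  for (int i = 0; i < c; ++i) {
    double lr = std::log(R(i, i));
    double a = (nu - s + i + 1) / 2.0;
    tot += -(n / 2.0) * l2pi + (i / 2.0) * ltau - cumlr + a * ltau2 -
           R::lgammafn(a) + R::lgammafn(a + n / 2.0) -
           (a + n / 2.0) * (2.0 * lr - std::log(2.0));
    cumlr += lr;
  }
  return tot;
}

// ---------------------------------------------------------------------------
// Draw (sigma^2, rho) from the transformed full conditional given
// Mt = tau I + U'U (or a prior scale matrix with n = 0).  preds holds the
// 1-based earlier same-prime neighbour sets.  Matches .sample_reparam().
// [[Rcpp::export(name = ".cpp_sample_reparam")]]
List cpp_sample_reparam(const arma::mat& Mt, const List& preds,
                        double n, double nu) {
  const int s = Mt.n_rows;
  arma::vec sigma2(s);
  arma::mat rho(s, s, arma::fill::zeros);
  for (int k = 0; k < s; ++k) {
    IntegerVector pk = preds[k];
    const int d = pk.size();
    const double a = (n + nu - s + 1 + d) / 2.0;
    if (d == 0) {
      double b = Mt(k, k) / 2.0;
      sigma2[k] = 1.0 / R::rgamma(a, 1.0 / b);
    } else {
      arma::uvec idx(d);
      for (int i = 0; i < d; ++i) idx[i] = pk[i] - 1;
      arma::mat R = arma::chol(Mt.submat(idx, idx));
      arma::vec mk(d);
      for (int i = 0; i < d; ++i) mk[i] = Mt(idx[i], k);
      arma::vec sol = arma::solve(arma::trimatu(R),
                                  arma::solve(arma::trimatl(R.t()), mk));
      double b = (Mt(k, k) - arma::dot(mk, sol)) / 2.0;
      if (b <= 0) stop("non-positive conditional scale: M~ not positive-definite");
      sigma2[k] = 1.0 / R::rgamma(a, 1.0 / b);
      arma::vec z(d);
      for (int i = 0; i < d; ++i) z[i] = norm_rand();
      arma::vec draw = sol + std::sqrt(sigma2[k]) * arma::solve(arma::trimatu(R), z);
      for (int i = 0; i < d; ++i) rho(k, idx[i]) = draw[i];
    }
  }
  return List::create(_["sigma2"] = sigma2, _["rho"] = rho);
}

// ---------------------------------------------------------------------------
// helpers for the selection sweep

struct GammaFit {
  double ev;
  arma::mat R;   // Cholesky of W_k
  arma::vec mu;
};

static void gamma_fit(const arma::mat& XtX, const arma::mat& X,
                      const std::vector<int>& sel, double ck,
                      const arma::vec& yt, double w, GammaFit& out) {
  const int d = (int)sel.size();
  if (d == 0) { out.ev = 0.0; out.R.reset(); out.mu.reset(); return; }
  arma::mat Wk(d, d);
  arma::vec h(d);
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double v = ck * XtX(sel[j], sel[i]);
      Wk(j, i) = v;
      Wk(i, j) = v;
    }
    Wk(i, i) += 1.0 / w;
    h[i] = arma::dot(X.col(sel[i]), yt);
  }
  out.R = arma::chol(Wk);
  arma::vec z = arma::solve(arma::trimatl(out.R.t()), h);
  out.ev = -d / 2.0 * std::log(w) - arma::sum(arma::log(out.R.diag())) +
           arma::dot(z, z) / 2.0;
  out.mu = arma::solve(arma::trimatu(out.R), z);
}

// log Bernoulli prior of an inclusion row given o_k and pi_j, over selected
// set only plus complement term; computed incrementally by the caller via
// the full evaluation of changed entries.
static inline double cell_logodds(double o, double pij) {
  double pr = o * pij;
  if (pr >= 1.0) pr = 1.0 - 1e-12;
  return std::log(pr) - std::log1p(-pr);
}

// ---------------------------------------------------------------------------
// One full pass of collapsed {gamma_k, beta_k} updates over all responses,
// mutating U, E, F (n x s), sel / bvals (1-based index vectors) in place.
// Matches .gamma_beta_update() + .set_beta_row() in R/mcmc.R; the acceptance
// ratio uses collapsed evidences and priors only.
// [[Rcpp::export(name = ".cpp_gamma_sweep")]]
int cpp_gamma_sweep(NumericMatrix U_, NumericMatrix E_, NumericMatrix F_,
                    List sel, List bvals,
                    NumericMatrix X_, NumericMatrix XtX_,
                    const arma::mat& rho, const arma::vec& sigma2,
                    const List& preds, const List& succ,
                    const arma::vec& o, const arma::vec& pi_j,
                    double w, double invT, double max_size,
                    bool beta_refresh) {
  // no-copy views: U, E, F are mutated through to the caller's state
  arma::mat U(U_.begin(), U_.nrow(), U_.ncol(), false, true);
  arma::mat E(E_.begin(), E_.nrow(), E_.ncol(), false, true);
  arma::mat F(F_.begin(), F_.nrow(), F_.ncol(), false, true);
  const arma::mat X(X_.begin(), X_.nrow(), X_.ncol(), false, true);
  const arma::mat XtX(XtX_.begin(), XtX_.nrow(), XtX_.ncol(), false, true);
  const int s = U.n_cols, p = X.n_cols, nn = U.n_rows;
  int n_accept = 0;
  GammaFit cur, prop;
  arma::vec yt(nn), delta(nn), f_new(nn);
  std::vector<char> in_sel(p, 0);
  std::vector<int> cur_sel, new_sel;
  cur_sel.reserve(64); new_sel.reserve(64);
  const double llw = std::log(w);
  for (int k = 0; k < s; ++k) {
    const IntegerVector sk = succ[k];
    // working response and precision multiplier
    yt = E.col(k);
    yt += F.col(k);
    yt /= sigma2[k];
    double ck = 1.0 / sigma2[k];
    double fsum = 0.0;
    for (int t = 0; t < sk.size(); ++t) {
      const int m = sk[t] - 1;
      const double r = rho(m, k);
      yt -= (r / sigma2[m]) * E.col(m);
      fsum += r * r / sigma2[m];
    }
    if (fsum > 0.0) yt += fsum * F.col(k);
    ck += fsum;
    if (invT != 1.0) { yt *= invT; ck *= invT; }
    const IntegerVector cur_sel_r = sel[k];
    const int n1 = cur_sel_r.size();
    cur_sel.assign(cur_sel_r.begin(), cur_sel_r.end());
    for (auto& v : cur_sel) v -= 1;
    gamma_fit(XtX, X, cur_sel, ck, yt, w, cur);

    // propose add / delete / swap (0.4 / 0.4 / 0.2, renormalised at bounds)
    new_sel = cur_sel;
    double log_q = 0.0, dprior = 0.0;
    for (int v : cur_sel) in_sel[v] = 1;
    auto rand_zero = [&]() { // uniform over excluded columns
      int r = runif_int(p - n1), seen = 0;
      for (int j = 0; j < p; ++j) if (!in_sel[j]) { if (seen == r) return j; ++seen; }
      return p - 1;
    };
    const double u_mv = unif_rand();
    const double p_add = (n1 == 0) ? 1.0 : (n1 == p ? 0.0 : 0.4);
    const double p_del = (n1 == 0) ? 0.0 : (n1 == p ? 1.0 : 0.4);
    if (u_mv < p_add) { // add
      int j = rand_zero();
      new_sel.push_back(j);
      std::sort(new_sel.begin(), new_sel.end());
      double p_del_new = (n1 + 1 == p) ? 1.0 : 0.4;
      log_q = std::log(p_del_new / (n1 + 1.0)) - std::log(p_add / (p - n1));
      dprior = cell_logodds(o[k], pi_j[j]);
    } else if (u_mv < p_add + p_del) { // delete
      int t = runif_int(n1);
      int j = new_sel[t];
      new_sel.erase(new_sel.begin() + t);
      double p_add_new = (n1 - 1 == 0) ? 1.0 : 0.4;
      log_q = std::log(p_add_new / (double)(p - n1 + 1)) - std::log(p_del / n1);
      dprior = -cell_logodds(o[k], pi_j[j]);
    } else { // swap (symmetric)
      int t = runif_int(n1);
      int j0 = new_sel[t];
      int j1 = rand_zero();
      new_sel[t] = j1;
      std::sort(new_sel.begin(), new_sel.end());
      dprior = cell_logodds(o[k], pi_j[j1]) - cell_logodds(o[k], pi_j[j0]);
    }
    for (int v : cur_sel) in_sel[v] = 0;

    bool accepted = false;
    if ((double)new_sel.size() <= max_size) {
      gamma_fit(XtX, X, new_sel, ck, yt, w, prop);
      double la = prop.ev - cur.ev + log_q + dprior;
      if (std::isfinite(la) && std::log(unif_rand()) < la) accepted = true;
    }
    const GammaFit& fit = accepted ? prop : cur;
    const std::vector<int>& fsel = accepted ? new_sel : cur_sel;
    if (accepted) ++n_accept;
    if (accepted || beta_refresh) {
      const int d = (int)fsel.size();
      arma::vec beta_k(d);
      if (d > 0) {
        arma::vec z(d);
        for (int i = 0; i < d; ++i) z[i] = norm_rand();
        beta_k = fit.mu + arma::solve(arma::trimatu(fit.R), z);
      }
      // refresh fitted values, residuals and innovations
      f_new.zeros();
      for (int i = 0; i < d; ++i) f_new += beta_k[i] * X.col(fsel[i]);
      delta = f_new - F.col(k);
      F.col(k) = f_new;
      U.col(k) -= delta;
      const IntegerVector pk = preds[k];
      yt = U.col(k); // reuse buffer for the innovation
      for (int t = 0; t < pk.size(); ++t)
        yt -= rho(k, pk[t] - 1) * U.col(pk[t] - 1);
      E.col(k) = yt;
      for (int t = 0; t < sk.size(); ++t) {
        int m = sk[t] - 1;
        E.col(m) += rho(m, k) * delta;
      }
      IntegerVector out_sel(d);
      NumericVector out_b(d);
      for (int i = 0; i < d; ++i) { out_sel[i] = fsel[i] + 1; out_b[i] = beta_k[i]; }
      sel[k] = out_sel;
      bvals[k] = out_b;
    }
  }
  (void)llw;
  return n_accept;
}

// ---------------------------------------------------------------------------
// internal MCS for the graph-update loop: chordality + maximal cliques +
// separators (Tarjan-Yannakakis clique order; the separator multiset is
// invariant across junction trees of the graph).
struct McsOut {
  bool ok = false;
  std::vector<std::vector<int>> cliques, seps;
};

static void mcs_blocks(const std::vector<char>& adj, int s, McsOut& out) {
  std::vector<double> wt(s, 0.0);
  std::vector<char> done(s, 0);
  std::vector<int> ord(s), lambda(s), pos(s, -1);
  std::vector<std::vector<int>> mv(s);
  out.ok = true;
  for (int i = 0; i < s; ++i) {
    int v = 0; double best = -1.0;
    for (int j = 0; j < s; ++j)
      if (!done[j] && wt[j] > best) { best = wt[j]; v = j; }
    ord[i] = v; pos[v] = i; done[v] = 1;
    std::vector<int>& e = mv[i];
    for (int j = 0; j < s; ++j) {
      if (j == v || !adj[j + s * v]) continue;
      if (done[j]) e.push_back(j); else wt[j] += 1.0;
    }
    lambda[i] = (int)e.size();
    if (out.ok && lambda[i] > 1) {
      int u = e[0];
      for (size_t t = 1; t < e.size(); ++t) if (pos[e[t]] > pos[u]) u = e[t];
      for (size_t t = 0; t < e.size(); ++t)
        if (e[t] != u && !adj[e[t] + s * u]) { out.ok = false; break; }
    }
  }
  if (!out.ok) return;
  out.cliques.clear(); out.seps.clear();
  std::vector<char> seen(s, 0);
  for (int i = 0; i < s; ++i) {
    bool last = (i == s - 1) || (lambda[i + 1] <= lambda[i]);
    if (!last) continue;
    std::vector<int> k(mv[i]); k.push_back(ord[i]);
    if (!out.cliques.empty()) {
      std::vector<int> sq;
      for (int v : k) if (seen[v]) sq.push_back(v);
      if (!sq.empty()) out.seps.push_back(sq);
    }
    for (int v : k) seen[v] = 1;
    out.cliques.push_back(k);
  }
}

static double block_ev(const arma::mat& Mt, const std::vector<int>& a,
                       double n, double nu, double tau, int s) {
  const int c = (int)a.size();
  arma::uvec idx(c);
  for (int i = 0; i < c; ++i) idx[i] = a[i];
  arma::mat R = arma::chol(Mt.submat(idx, idx));
  double tot = 0.0, cumlr = 0.0;
  const double l2pi = std::log(2.0 * M_PI), ltau = std::log(tau),
               ltau2 = std::log(tau / 2.0);
  for (int i = 0; i < c; ++i) {
    double lr = std::log(R(i, i));
    double aa = (nu - s + i + 1) / 2.0;
    tot += -(n / 2.0) * l2pi + (i / 2.0) * ltau - cumlr + aa * ltau2 -
           R::lgammafn(aa) + R::lgammafn(aa + n / 2.0) -
           (aa + n / 2.0) * (2.0 * lr - std::log(2.0));
    cumlr += lr;
  }
  return tot;
}

static double graph_marglik(const arma::mat& Mt, const McsOut& m,
                            double n, double nu, double tau, int s) {
  double tot = 0.0;
  for (const auto& c : m.cliques) tot += block_ev(Mt, c, n, nu, tau, s);
  for (const auto& sp : m.seps) tot -= block_ev(Mt, sp, n, nu, tau, s);
  return tot;
}

// ---------------------------------------------------------------------------
// `n_moves` collapsed single-edge Metropolis-Hastings graph updates: uniform
// node-pair toggles (toggles breaking decomposability act as stay proposals,
// keeping the kernel symmetric), accepted against the collapsed covariance
// evidence times the Binomial edge prior at the current eta.  Mutates the
// adjacency in place; returns the acceptance count.
// [[Rcpp::export(name = ".cpp_graph_updates")]]
int cpp_graph_updates(LogicalMatrix adj_, const arma::mat& Mt,
                      double n, double nu, double tau, double eta,
                      int n_moves) {
  const int s = adj_.nrow();
  std::vector<char> adj(s * s);
  int n_edge = 0;
  for (int j = 0; j < s; ++j)
    for (int i = 0; i < s; ++i) {
      adj[i + s * j] = (char)adj_(i, j);
      if (adj_(i, j) && i < j) ++n_edge;
    }
  const double m_edges = s * (s - 1) / 2.0;
  const double leta = std::log(eta) - std::log1p(-eta);
  McsOut cur, prop;
  mcs_blocks(adj, s, cur);
  double cur_ml = graph_marglik(Mt, cur, n, nu, tau, s);
  int n_accept = 0;
  for (int it = 0; it < n_moves; ++it) {
    int i = runif_int(s), j = runif_int(s - 1);
    if (j >= i) ++j;
    const bool added = !adj[i + s * j];
    adj[i + s * j] = adj[j + s * i] = (char)added;
    mcs_blocks(adj, s, prop);
    if (!prop.ok) { // stay proposal
      adj[i + s * j] = adj[j + s * i] = (char)!added;
      continue;
    }
    const int e_new = n_edge + (added ? 1 : -1);
    double new_ml = graph_marglik(Mt, prop, n, nu, tau, s);
    double la = new_ml - cur_ml + (added ? leta : -leta) +
      R::lchoose(m_edges, e_new) - R::lchoose(m_edges, n_edge);
    if (std::isfinite(la) && std::log(unif_rand()) < la) {
      cur_ml = new_ml; n_edge = e_new; ++n_accept;
    } else {
      adj[i + s * j] = adj[j + s * i] = (char)!added;
    }
  }
  for (int j = 0; j < s; ++j)
    for (int i = 0; i < s; ++i) adj_(i, j) = (bool)adj[i + s * j];
  return n_accept;
}

// ---------------------------------------------------------------------------
// Hotspot hyperparameter updates, mirroring update_hotspot_params() in R
// with the identical RNG consumption order (so the two implementations can
// be compared draw-for-draw under a fixed seed).
// [[Rcpp::export(name = ".cpp_hotspot_update")]]
List cpp_hotspot_update(const List& sel, int p, NumericVector o,
                        NumericVector pi_j, double a_o, double b_o,
                        double a_pi, double b_pi, bool hotspot,
                        double step_pi) {
  const int s = o.size();
  std::vector<std::vector<int>> sl(s);
  NumericVector n1k(s);
  std::vector<double> n1j(p, 0.0);
  for (int k = 0; k < s; ++k) {
    IntegerVector sk = sel[k];
    sl[k].assign(sk.begin(), sk.end());
    for (auto& v : sl[k]) { v -= 1; n1j[v] += 1.0; }
    n1k[k] = sk.size();
  }
  double pimax = *std::max_element(pi_j.begin(), pi_j.end());
  // o update: independence proposal from the pi = 1 conjugate conditional
  NumericVector o_star(s);
  for (int k = 0; k < s; ++k)
    o_star[k] = R::rbeta(a_o + n1k[k], b_o + p - n1k[k]);
  auto o_target = [&](double ok, int k) {
    if (ok <= 0.0 || ok >= 1.0) return -std::numeric_limits<double>::infinity();
    double t = (a_o - 1) * std::log(ok) + (b_o - 1) * std::log1p(-ok);
    for (int j = 0; j < p; ++j) {
      double pr = ok * pi_j[j];
      if (pr >= 1.0) pr = 1.0 - 1e-12;
      t += std::log1p(-pr);
    }
    for (int j : sl[k]) {
      double pr = ok * pi_j[j];
      if (pr >= 1.0) pr = 1.0 - 1e-12;
      t += std::log(pr) - std::log1p(-pr);
    }
    return t;
  };
  int acc_o = 0;
  std::vector<double> la_o(s);
  for (int k = 0; k < s; ++k) {
    double la = o_target(o_star[k], k) - o_target(o[k], k) +
      R::dbeta(o[k], a_o + n1k[k], b_o + p - n1k[k], 1) -
      R::dbeta(o_star[k], a_o + n1k[k], b_o + p - n1k[k], 1);
    if (hotspot && o_star[k] * pimax > 1.0)
      la = -std::numeric_limits<double>::infinity();
    la_o[k] = la;
  }
  for (int k = 0; k < s; ++k) {
    if (std::isfinite(la_o[k]) && std::log(unif_rand()) < la_o[k]) {
      o[k] = o_star[k]; ++acc_o;
    }
  }
  double acc_pi = 0.0;
  if (hotspot) {
    double omax = *std::max_element(o.begin(), o.end());
    NumericVector pi_star(p);
    for (int j = 0; j < p; ++j)
      pi_star[j] = pi_j[j] * std::exp(step_pi * norm_rand());
    // column log-likelihood terms of current and proposed propensities
    std::vector<double> lp_cur(p, 0.0), lp_new(p, 0.0);
    for (int j = 0; j < p; ++j) {
      double pj = std::max((double)pi_j[j], 1e-300),
             qj = std::max((double)pi_star[j], 1e-300);
      lp_cur[j] = (a_pi - 1) * std::log(pj) - b_pi * pj + n1j[j] * std::log(pj);
      lp_new[j] = (a_pi - 1) * std::log(qj) - b_pi * qj + n1j[j] * std::log(qj);
    }
    for (int k = 0; k < s; ++k) {
      std::vector<char> in_sel(p, 0);
      for (int j : sl[k]) in_sel[j] = 1;
      for (int j = 0; j < p; ++j) {
        if (in_sel[j]) continue;
        double pr = o[k] * pi_j[j];
        if (pr >= 1.0) pr = 1.0 - 1e-12;
        lp_cur[j] += std::log1p(-pr);
        pr = o[k] * pi_star[j];
        if (pr >= 1.0) pr = 1.0 - 1e-12;
        lp_new[j] += std::log1p(-pr);
      }
    }
    int na = 0;
    for (int j = 0; j < p; ++j) {
      bool ok = pi_star[j] * omax <= 1.0 && pi_star[j] > 0;
      double la = lp_new[j] - lp_cur[j] +
        std::log(std::max((double)pi_star[j], 1e-300)) - std::log(pi_j[j]);
      if (ok && std::isfinite(la) && std::log(unif_rand()) < la) {
        pi_j[j] = pi_star[j]; ++na;
      }
    }
    acc_pi = na / (double)p;
  }
  return List::create(_["o"] = o, _["pi_j"] = pi_j,
                      _["acc_o"] = acc_o / (double)s, _["acc_pi"] = acc_pi);
}
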