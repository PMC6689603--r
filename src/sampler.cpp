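// Metropolis-coupled MCMC core. The move set, priors and likelihood
// mirror the R reference implementations in R/mcmc_moves.R and
// R/mcmc_state.R; the R versions remain the specification that the unit
// tests exercise, while runs execute here. Randomness comes from R's
// RNG, so runs are reproducible under set.seed().

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

double mk_groups_loglik_raw(const int* parent, int nn, int ntip,
                            const double* brlen, const List& groups,
                            const double* rates, int ncat, bool correct);

namespace {

struct Chain {
  std::vector<int> parent;      // 0-based, root = -1
  std::vector<double> age;
  std::vector<char> sa;         // per tip
  std::vector<double> rel;      // nn x npart, column-major
  std::vector<double> sigma, alpha, rates_mat;  // rates: ncat x npart
  double c, d, v, s;
  double lp;                    // total unheated log posterior
  std::vector<double> ll;       // per-partition log likelihood
};

struct Model {
  // dimensions
  int ntip, nn, npart, ncat, nalpha;
  bool prior_only, mkv_correct, cond_sampling;
  double removal_prob, rho;
  // priors
  std::vector<char> fossil_mask;          // per tip (non-extant)
  std::vector<int> fossil_idx;            // 0-based tips with windows
  std::vector<double> fossil_min, fossil_max;
  double tip_window_const;
  int n_extant;
  double root_offset, root_rate;
  double c_shape, c_rate, sigma_rate, alpha_rate, d_rate;
  std::vector<int> calib_tips;            // 0-based; empty if none
  double calib_mean, calib_sd;
  // constraints: 0-based tip sets
  std::vector<std::vector<int>> constraints;
  // move tuning
  double root_window, tip_window, mult_rel, mult_scalar, mult_tree, win_unit;
  // likelihood data
  List part_groups;                       // per partition: list of groups
};

int runif_index(int n) {
  int i = (int)(unif_rand() * n);
  return i >= n ? n - 1 : i;
}

// unit-mean discrete gamma, category means over equal-probability bins
void discrete_gamma(double alpha, int ncat, double* out) {
  if (ncat == 1) { out[0] = 1.0; return; }
  double scale = 1.0 / alpha;
  for (int i = 0; i < ncat; ++i) {
    double a = (i == 0) ? 0.0
      : R::pgamma(R::qgamma((double)i / ncat, alpha, scale, 1, 0),
                  alpha + 1.0, scale, 1, 0);
    double b = (i == ncat - 1) ? 1.0
      : R::pgamma(R::qgamma((double)(i + 1) / ncat, alpha, scale, 1, 0),
                  alpha + 1.0, scale, 1, 0);
    out[i] = (b - a) * ncat;
  }
}

void update_rates_mat(const Model& M, Chain& ch) {
  ch.rates_mat.resize((size_t)M.ncat * M.npart);
  if (M.nalpha == 1) {
    std::vector<double> r(M.ncat);
    discrete_gamma(ch.alpha[0], M.ncat, r.data());
    for (int j = 0; j < M.npart; ++j)
      std::copy(r.begin(), r.end(), ch.rates_mat.begin() + (size_t)j * M.ncat);
  } else {
    for (int j = 0; j < M.npart; ++j)
      discrete_gamma(ch.alpha[j], M.ncat, ch.rates_mat.data() + (size_t)j * M.ncat);
  }
}

int find_root(const Chain& ch) {
  for (int i = 0; i < (int)ch.parent.size(); ++i)
    if (ch.parent[i] < 0) return i;
  return -1;
}

// --- prior ---------------------------------------------------------------

double lp_prior(const Model& M, const Chain& ch) {
  const double d = ch.d, v = ch.v, s = ch.s, c = ch.c;
  if (d <= 0 || v < 0 || v >= 1 || s < 0 || s >= 1 || c <= 0) return R_NegInf;
  for (int j = 0; j < M.npart; ++j) if (ch.sigma[j] <= 0) return R_NegInf;
  for (int j = 0; j < M.nalpha; ++j) if (ch.alpha[j] <= 0) return R_NegInf;
  const double r = M.removal_prob, rho = M.rho;
  double lambda = d / (1 - v), psi, mu;
  if (s == 0) { psi = 0.0; mu = v * lambda; }
  else { psi = v * lambda * s / (1 - s + r * s); mu = psi * (1 - s) / s; }
  const int ntip = M.ntip, nn = M.nn;
  int n_sa = 0, n_fossil_tip = 0;
  for (int i = 0; i < ntip; ++i) {
    if (ch.sa[i]) ++n_sa;
    else if (M.fossil_mask[i]) ++n_fossil_tip;
  }
  if ((n_sa + n_fossil_tip > 0) && psi == 0) return R_NegInf;
  if (n_sa > 0 && r >= 1) return R_NegInf;
  double c1 = std::sqrt((lambda - mu - psi) * (lambda - mu - psi) +
                        4 * lambda * psi);
  double c2 = -(lambda - mu - 2 * lambda * rho - psi) / c1;
  auto log_q = [&](double t) {
    double x = -c1 * t;
    return std::log(4.0) + x -
      2.0 * std::log(std::exp(x) * (1 - c2) + (1 + c2));
  };
  auto p0 = [&](double t) {
    double e = std::exp(-c1 * t);
    return (lambda + mu + psi +
            c1 * (e * (1 - c2) - (1 + c2)) / (e * (1 - c2) + (1 + c2))) /
           (2 * lambda);
  };
  int root = find_root(ch);
  std::vector<char> birth(nn, 0);
  for (int i = ntip; i < nn; ++i) birth[i] = 1;
  birth[root] = 0;
  for (int i = 0; i < ntip; ++i) if (ch.sa[i]) birth[ch.parent[i]] = 0;
  double lp = 2.0 * log_q(ch.age[root]) + M.n_extant * std::log(rho);
  double llam = std::log(lambda);
  for (int i = ntip; i < nn; ++i)
    if (birth[i]) lp += llam + log_q(ch.age[i]);
  if (n_fossil_tip > 0) {
    double lpsi = std::log(psi);
    for (int i = 0; i < ntip; ++i)
      if (M.fossil_mask[i] && !ch.sa[i])
        lp += lpsi + std::log(r + (1 - r) * p0(ch.age[i])) - log_q(ch.age[i]);
  }
  if (n_sa > 0) lp += n_sa * (std::log(psi) + std::log1p(-r));
  if (M.cond_sampling) {
    double z = p0(ch.age[root]);
    lp -= std::log1p(-z * z);
  }
  double troot = ch.age[root];
  if (troot < M.root_offset) return R_NegInf;
  lp += std::log(M.root_rate) - M.root_rate * (troot - M.root_offset);
  for (size_t w = 0; w < M.fossil_idx.size(); ++w) {
    double ta = ch.age[M.fossil_idx[w]];
    if (ta < M.fossil_min[w] || ta > M.fossil_max[w]) return R_NegInf;
  }
  lp += M.tip_window_const;
  for (int i = 0; i < nn; ++i) {
    int p = ch.parent[i];
    if (p < 0) continue;
    double dur = ch.age[p] - ch.age[i];
    if (dur <= 0) continue;
    for (int j = 0; j < M.npart; ++j) {
      double shp = dur * c / ch.sigma[j];
      lp += R::dgamma(ch.rel[i + (size_t)j * nn], shp, 1.0 / shp, 1);
    }
  }
  lp += R::dgamma(c, M.c_shape, 1.0 / M.c_rate, 1);
  for (int j = 0; j < M.npart; ++j)
    lp += R::dexp(ch.sigma[j], 1.0 / M.sigma_rate, 1);
  for (int j = 0; j < M.nalpha; ++j)
    lp += R::dexp(ch.alpha[j], 1.0 / M.alpha_rate, 1);
  lp += R::dexp(d, 1.0 / M.d_rate, 1);
  if (!M.calib_tips.empty()) {
    std::vector<int> cnt(nn, 0);
    int m = (int)M.calib_tips.size();
    for (int w = 0; w < m; ++w) {
      int i = M.calib_tips[w];
      while (i >= 0) { ++cnt[i]; i = ch.parent[i]; }
    }
    int mrca = root, i = M.calib_tips[0];
    while (i >= 0) {
      if (cnt[i] == m) { mrca = i; break; }
      i = ch.parent[i];
    }
    lp += R::dnorm(ch.age[mrca], M.calib_mean, M.calib_sd, 1);
  }
  return lp;
}

// --- likelihood ----------------------------------------------------------

double ll_partition(const Model& M, const Chain& ch, int j) {
  std::vector<double> brlen(M.nn, 0.0);
  for (int i = 0; i < M.nn; ++i) {
    int p = ch.parent[i];
    if (p < 0) continue;
    brlen[i] = (ch.age[p] - ch.age[i]) * ch.c * ch.rel[i + (size_t)j * M.nn];
    if (brlen[i] < 0) brlen[i] = 0;
  }
  List groups = M.part_groups[j];
  return mk_groups_loglik_raw(ch.parent.data(), M.nn, M.ntip, brlen.data(),
                              groups, ch.rates_mat.data() + (size_t)j * M.ncat,
                              M.ncat, M.mkv_correct);
}

bool update_ll(const Model& M, Chain& ch, int which) {
  // which: -1 all partitions, otherwise one partition index
  if (M.prior_only) return true;
  if (which < 0) {
    for (int j = 0; j < M.npart; ++j) {
      ch.ll[j] = ll_partition(M, ch, j);
      if (!std::isfinite(ch.ll[j])) return false;
    }
  } else {
    ch.ll[which] = ll_partition(M, ch, which);
    if (!std::isfinite(ch.ll[which])) return false;
  }
  return true;
}

// --- constraints ---------------------------------------------------------

bool constraints_ok(const Model& M, const Chain& ch) {
  if (M.constraints.empty()) return true;
  const int nn = M.nn, ntip = M.ntip;
  // postorder
  std::vector<std::vector<int>> kids(nn);
  int root = -1;
  for (int i = 0; i < nn; ++i) {
    if (ch.parent[i] < 0) root = i;
    else kids[ch.parent[i]].push_back(i);
  }
  std::vector<int> ord; ord.reserve(nn);
  std::vector<int> stack{root};
  while (!stack.empty()) {
    int nd = stack.back(); stack.pop_back();
    ord.push_back(nd);
    for (int c : kids[nd]) stack.push_back(c);
  }
  std::reverse(ord.begin(), ord.end());
  std::vector<int> marked(nn), total(nn);
  for (const auto& cl : M.constraints) {
    std::fill(marked.begin(), marked.end(), 0);
    std::fill(total.begin(), total.end(), 0);
    for (int i : cl) marked[i] = 1;
    for (int i = 0; i < ntip; ++i) total[i] = 1;
    bool ok = false;
    int m = (int)cl.size();
    for (int nd : ord) {
      int p = ch.parent[nd];
      if (p >= 0) { marked[p] += marked[nd]; total[p] += total[nd]; }
      if (nd >= ntip && marked[nd] == m && total[nd] == m) { ok = true; break; }
    }
    if (!ok) return false;
  }
  return true;
}

// --- moves ---------------------------------------------------------------
// each returns false for generation-time rejection; otherwise fills
// log_hr and ll_which (-2 none, -1 all, >=0 one partition)

void children_of(const Chain& ch, int nd, int& a, int& b) {
  a = b = -1;
  for (int i = 0; i < (int)ch.parent.size(); ++i)
    if (ch.parent[i] == nd) { if (a < 0) a = i; else { b = i; break; } }
}

bool is_sa_parent(const Chain& ch, const Model& M, int nd) {
  for (int i = 0; i < M.ntip; ++i)
    if (ch.sa[i] && ch.parent[i] == nd) return true;
  return false;
}

// two-scale multiplier: occasional 4x-wider strides let the chain jump
// across low-density valleys (mixture kernels keep log m as the correct
// Hastings term)
double mult_factor(double tun) {
  if (unif_rand() < 0.2) tun *= 4.0;
  return std::exp(tun * (unif_rand() - 0.5));
}

bool mv_node_age(const Model& M, Chain& ch, double& log_hr, int& ll_which) {
  std::vector<int> elig;
  for (int nd = M.ntip; nd < M.nn; ++nd)
    if (!is_sa_parent(ch, M, nd)) elig.push_back(nd);
  if (elig.empty()) return false;
  int nd = elig[runif_index((int)elig.size())];
  int k1, k2; children_of(ch, nd, k1, k2);
  double lb = std::max(ch.age[k1], ch.age[k2]);
  int p = ch.parent[nd];
  double t2;
  if (p < 0) {
    t2 = ch.age[nd] + R::runif(-M.root_window, M.root_window);
    if (t2 < lb) return false;
  } else {
    double ub = ch.age[p];
    if (ub <= lb) return false;
    t2 = R::runif(lb, ub);
  }
  ch.age[nd] = t2;
  log_hr = 0; ll_which = -1;
  return true;
}

bool scale_free_internals(const Model& M, Chain& ch, double m) {
  for (int nd = M.ntip; nd < M.nn; ++nd)
    if (!is_sa_parent(ch, M, nd)) ch.age[nd] *= m;
  for (int i = 0; i < M.nn; ++i) {
    int p = ch.parent[i];
    if (p >= 0 && ch.age[p] < ch.age[i]) return false;
  }
  return true;
}

int count_free_internals(const Model& M, Chain& ch) {
  int nf = 0;
  for (int nd = M.ntip; nd < M.nn; ++nd)
    if (!is_sa_parent(ch, M, nd)) ++nf;
  return nf;
}

bool mv_tree_scale(const Model& M, Chain& ch, double& log_hr, int& ll_which) {
  double m = mult_factor(M.mult_tree);
  int nf = count_free_internals(M, ch);
  if (!scale_free_internals(M, ch, m)) return false;
  log_hr = nf * std::log(m); ll_which = -1;
  return true;
}

bool mv_time_rate_rescale(const Model& M, Chain& ch, double& log_hr,
                          int& ll_which) {
  double m = mult_factor(M.mult_tree);
  int nf = count_free_internals(M, ch);
  if (!scale_free_internals(M, ch, m)) return false;
  ch.c /= m;
  log_hr = (nf - 1) * std::log(m); ll_which = -1;
  return true;
}

bool mv_tip_age(const Model& M, Chain& ch, double& log_hr, int& ll_which) {
  if (M.fossil_idx.empty()) return false;
  int w = runif_index((int)M.fossil_idx.size());
  int f = M.fossil_idx[w];
  double lo = M.fossil_min[w], hi = M.fossil_max[w];
  if (hi <= lo) return false;
  double win = std::min(M.tip_window, hi - lo);
  double t2 = ch.age[f] + R::runif(-win, win);
  if (t2 < lo || t2 > hi) return false;
  int p = ch.parent[f];
  if (!ch.sa[f]) {
    if (t2 > ch.age[p]) return false;
    ch.age[f] = t2;
  } else {
    int k1, k2; children_of(ch, p, k1, k2);
    int sib = (k1 == f) ? k2 : k1;
    if (t2 < ch.age[sib]) return false;
    int gp = ch.parent[p];
    if (gp >= 0 && t2 > ch.age[gp]) return false;
    ch.age[f] = t2;
    ch.age[p] = t2;
  }
  log_hr = 0; ll_which = -1;
  return true;
}

bool mv_nni(const Model& M, Chain& ch, double& log_hr, int& ll_which) {
  std::vector<int> cand;
  for (int nd = M.ntip; nd < M.nn; ++nd)
    if (ch.parent[nd] >= 0) cand.push_back(nd);
  if (cand.empty()) return false;
  int cc = cand[runif_index((int)cand.size())];
  int p = ch.parent[cc];
  int k1, k2; children_of(ch, p, k1, k2);
  int a = (k1 == cc) ? k2 : k1;
  int g1, g2; children_of(ch, cc, g1, g2);
  int g = (unif_rand() < 0.5) ? g1 : g2;
  auto is_sa_tip = [&](int x) { return x < M.ntip && ch.sa[x]; };
  if (is_sa_tip(a) || is_sa_tip(g)) return false;
  if (ch.age[cc] <= ch.age[a]) return false;
  ch.parent[g] = p;
  ch.parent[a] = cc;
  if (!constraints_ok(M, ch)) return false;
  log_hr = 0; ll_which = -1;
  return true;
}

bool mv_spr(const Model& M, Chain& ch, double& log_hr, int& ll_which) {
  const int nn = M.nn, ntip = M.ntip;
  int root = find_root(ch);
  auto is_sa_tip = [&](int x) { return x < ntip && ch.sa[x]; };
  auto sib_of = [&](int x) {
    int k1, k2; children_of(ch, ch.parent[x], k1, k2);
    return (k1 == x) ? k2 : k1;
  };
  std::vector<int> cand_x;
  for (int x = 0; x < nn; ++x) {
    if (x == root) continue;
    if (ch.parent[x] == root) continue;
    if (is_sa_tip(x)) continue;
    if (is_sa_tip(sib_of(x))) continue;
    cand_x.push_back(x);
  }
  if (cand_x.empty()) return false;
  int x = cand_x[runif_index((int)cand_x.size())];
  int p = ch.parent[x];
  int s = sib_of(x);
  int gp = ch.parent[p];
  // subtree of x
  std::vector<char> insub(nn, 0);
  insub[x] = 1;
  {
    bool changed = true;
    while (changed) {
      changed = false;
      for (int i = 0; i < nn; ++i)
        if (!insub[i] && ch.parent[i] >= 0 && insub[ch.parent[i]]) {
          insub[i] = 1; changed = true;
        }
    }
  }
  std::vector<int> cand_m;
  std::vector<double> lo_v, hi_v;
  for (int m = 0; m < nn; ++m) {
    if (insub[m] || m == p || m == root) continue;
    int pm = (m == s) ? gp : ch.parent[m];
    double hi = ch.age[pm];
    double lo = std::max(ch.age[x], ch.age[m]);
    if (hi > lo) { cand_m.push_back(m); lo_v.push_back(lo); hi_v.push_back(hi); }
  }
  if (cand_m.empty()) return false;
  int pick = runif_index((int)cand_m.size());
  int m = cand_m[pick];
  double u = R::runif(lo_v[pick], hi_v[pick]);
  double lo_rev = std::max(ch.age[x], ch.age[s]);
  double hi_rev = ch.age[gp];
  log_hr = std::log(hi_v[pick] - lo_v[pick]) - std::log(hi_rev - lo_rev);
  int mp = (m == s) ? gp : ch.parent[m];
  ch.parent[s] = gp;
  ch.parent[p] = mp;
  ch.parent[m] = p;
  ch.age[p] = u;
  if (!constraints_ok(M, ch)) return false;
  ll_which = -1;
  return true;
}

void active_branch(const Model& M, const Chain& ch, int& i, int& j) {
  std::vector<int> act;
  for (int b = 0; b < M.nn; ++b) {
    int p = ch.parent[b];
    if (p >= 0 && ch.age[p] - ch.age[b] > 0) act.push_back(b);
  }
  i = act[runif_index((int)act.size())];
  j = (M.npart == 1) ? 0 : runif_index(M.npart);
}

bool mv_rel_rate(const Model& M, Chain& ch, double& log_hr, int& ll_which) {
  int i, j; active_branch(M, ch, i, j);
  double m = std::exp(M.mult_rel * (unif_rand() - 0.5));
  ch.rel[i + (size_t)j * M.nn] *= m;
  log_hr = std::log(m); ll_which = j;
  return true;
}

bool mv_rel_redraw(const Model& M, Chain& ch, double& log_hr, int& ll_which) {
  int i, j; active_branch(M, ch, i, j);
  double dur = ch.age[ch.parent[i]] - ch.age[i];
  double shp = dur * ch.c / ch.sigma[j];
  double rnew = R::rgamma(shp, 1.0 / shp);
  if (rnew <= 1e-300 || !std::isfinite(rnew)) return false;
  double rold = ch.rel[i + (size_t)j * M.nn];
  log_hr = R::dgamma(rold, shp, 1.0 / shp, 1) -
           R::dgamma(rnew, shp, 1.0 / shp, 1);
  ch.rel[i + (size_t)j * M.nn] = rnew;
  ll_which = j;
  return true;
}

bool mv_clock_rate(const Model& M, Chain& ch, double& log_hr, int& ll_which) {
  double m = mult_factor(M.mult_scalar);
  ch.c *= m; log_hr = std::log(m); ll_which = -1;
  return true;
}

// funnel-sliding sigma move: scale sigma_j and map each branch rate
// through its gamma CDF so quantiles are preserved under the new shape;
// log_hr carries the transform's Jacobian (the rate-prior terms cancel
// inside the full posterior ratio)
bool mv_sigma_rates(const Model& M, Chain& ch, double& log_hr, int& ll_which) {
  int j = (M.npart == 1) ? 0 : runif_index(M.npart);
  double m = mult_factor(M.mult_scalar);
  double s_old = ch.sigma[j], s_new = s_old * m;
  double log_jac = std::log(m);
  const int nn = M.nn;
  for (int i = 0; i < nn; ++i) {
    int p = ch.parent[i];
    if (p < 0) continue;
    double dur = ch.age[p] - ch.age[i];
    if (dur <= 0) continue;
    double shp = dur * ch.c / s_old;
    double shp2 = shp / m;
    double r = ch.rel[i + (size_t)j * nn];
    double u = R::pgamma(r, shp, 1.0 / shp, 1, 0);
    if (u <= 0 || u >= 1) return false;
    double r2 = R::qgamma(u, shp2, 1.0 / shp2, 1, 0);
    if (!std::isfinite(r2) || r2 <= 1e-300) return false;
    log_jac += R::dgamma(r, shp, 1.0 / shp, 1) -
               R::dgamma(r2, shp2, 1.0 / shp2, 1);
    ch.rel[i + (size_t)j * nn] = r2;
  }
  ch.sigma[j] = s_new;
  log_hr = log_jac;
  ll_which = j;
  return true;
}

bool mv_sigma(const Model& M, Chain& ch, double& log_hr, int& ll_which) {
  int j = (M.npart == 1) ? 0 : runif_index(M.npart);
  double m = mult_factor(M.mult_scalar);
  ch.sigma[j] *= m; log_hr = std::log(m); ll_which = -2;
  return true;
}

bool mv_alpha(const Model& M, Chain& ch, double& log_hr, int& ll_which) {
  int j = (M.nalpha == 1) ? 0 : runif_index(M.nalpha);
  if (unif_rand() < 0.2) {
    // prior-independence component: bridges rate-variation regimes
    double a2 = R::rexp(1.0 / M.alpha_rate);
    if (a2 <= 1e-300) return false;
    log_hr = R::dexp(ch.alpha[j], 1.0 / M.alpha_rate, 1) -
             R::dexp(a2, 1.0 / M.alpha_rate, 1);
    ch.alpha[j] = a2;
  } else {
    double m = mult_factor(M.mult_scalar);
    ch.alpha[j] *= m;
    log_hr = std::log(m);
  }
  update_rates_mat(M, ch);
  ll_which = (M.nalpha == 1) ? -1 : j;
  return true;
}

bool mv_div_d(const Model& M, Chain& ch, double& log_hr, int& ll_which) {
  double m = mult_factor(M.mult_scalar);
  ch.d *= m; log_hr = std::log(m); ll_which = -2;
  return true;
}

double win01(double x, double w) {
  double y = x + R::runif(-w, w);
  if (y < 0) y = -y;
  if (y > 1) y = 2 - y;
  return y;
}

bool mv_div_v(const Model& M, Chain& ch, double& log_hr, int& ll_which) {
  ch.v = win01(ch.v, M.win_unit); log_hr = 0; ll_which = -2;
  return true;
}

bool mv_div_s(const Model& M, Chain& ch, double& log_hr, int& ll_which) {
  ch.s = win01(ch.s, M.win_unit); log_hr = 0; ll_which = -2;
  return true;
}

bool mv_rj_ancestor(const Model& M, Chain& ch, double& log_hr, int& ll_which) {
  std::vector<int> fossil;
  for (int i = 0; i < M.ntip; ++i)
    if (ch.age[i] > 1e-9 || ch.sa[i]) fossil.push_back(i);
  if (fossil.empty()) return false;
  int f = fossil[runif_index((int)fossil.size())];
  int p = ch.parent[f];
  int gp = ch.parent[p];
  if (gp < 0) return false;
  double yf = ch.age[f], tgp = ch.age[gp];
  if (tgp <= yf) return false;
  const int nn = M.nn;
  if (!ch.sa[f]) {
    int k1, k2; children_of(ch, p, k1, k2);
    int sib = (k1 == f) ? k2 : k1;
    if (ch.age[sib] > yf) return false;
    double durf = ch.age[p] - yf;
    if (durf <= 0) return false;
    log_hr = -std::log(tgp - yf);
    for (int j = 0; j < M.npart; ++j) {
      double shp = durf * ch.c / ch.sigma[j];
      log_hr += R::dgamma(ch.rel[f + (size_t)j * nn], shp, 1.0 / shp, 1);
    }
    ch.age[p] = yf;
    ch.sa[f] = 1;
    for (int j = 0; j < M.npart; ++j) ch.rel[f + (size_t)j * nn] = 1.0;
  } else {
    double x = R::runif(yf, tgp);
    log_hr = std::log(tgp - yf);
    std::vector<double> rnew(M.npart);
    for (int j = 0; j < M.npart; ++j) {
      double shp = (x - yf) * ch.c / ch.sigma[j];
      rnew[j] = R::rgamma(shp, 1.0 / shp);
      if (rnew[j] <= 1e-300 || !std::isfinite(rnew[j])) return false;
      log_hr -= R::dgamma(rnew[j], shp, 1.0 / shp, 1);
    }
    ch.age[p] = x;
    ch.sa[f] = 0;
    for (int j = 0; j < M.npart; ++j) ch.rel[f + (size_t)j * nn] = rnew[j];
  }
  ll_which = -1;
  return true;
}

const int N_MOVES = 16;
typedef bool (*MoveFn)(const Model&, Chain&, double&, int&);
MoveFn MOVES[N_MOVES] = {
  mv_node_age, mv_tree_scale, mv_time_rate_rescale, mv_tip_age, mv_nni,
  mv_spr, mv_rel_rate, mv_rel_redraw, mv_sigma_rates, mv_clock_rate,
  mv_sigma, mv_alpha, mv_div_d, mv_div_v, mv_div_s, mv_rj_ancestor };

}  // namespace

// One full MCMC run: n_chains Metropolis-coupled chains with annealed
// burn-in. Returns the cold-chain trace.
// [[Rcpp::export]]
List run_mcmc_cpp(const List& init_chains, const List& pack,
                  const List& part_groups, const NumericVector& weights,
                  const List& tune, const List& cfg_pack) {
  Model M;
  M.ntip = as<int>(pack["ntip"]);
  M.npart = as<int>(cfg_pack["npart"]);
  M.nn = 2 * M.ntip - 1;
  M.ncat = as<int>(cfg_pack["ncat"]);
  M.nalpha = as<int>(cfg_pack["nalpha"]);
  M.prior_only = as<bool>(cfg_pack["prior_only"]);
  M.mkv_correct = as<bool>(cfg_pack["mkv_correct"]);
  M.cond_sampling = as<bool>(pack["cond_sampling"]);
  M.removal_prob = as<double>(pack["removal_prob"]);
  M.rho = as<double>(pack["rho"]);
  {
    LogicalVector fm = pack["fossil_mask"];
    M.fossil_mask.assign(fm.begin(), fm.end());
    IntegerVector fi = pack["fossil_idx"];
    M.fossil_idx.assign(fi.begin(), fi.end());
    NumericVector lo = pack["fossil_min"], hi = pack["fossil_max"];
    M.fossil_min.assign(lo.begin(), lo.end());
    M.fossil_max.assign(hi.begin(), hi.end());
  }
  M.tip_window_const = as<double>(pack["tip_window_const"]);
  M.n_extant = as<int>(pack["n_extant"]);
  M.root_offset = as<double>(pack["root_offset"]);
  M.root_rate = as<double>(pack["root_rate"]);
  M.c_shape = as<double>(pack["c_shape"]);
  M.c_rate = as<double>(pack["c_rate"]);
  M.sigma_rate = as<double>(pack["sigma_rate"]);
  M.alpha_rate = as<double>(pack["alpha_rate"]);
  M.d_rate = as<double>(pack["d_rate"]);
  {
    IntegerVector ct = pack["calib_tips"];
    M.calib_tips.assign(ct.begin(), ct.end());
    M.calib_mean = as<double>(pack["calib_mean"]);
    M.calib_sd = as<double>(pack["calib_sd"]);
  }
  {
    List cons = cfg_pack["constraints"];
    for (int i = 0; i < cons.size(); ++i) {
      IntegerVector cl = cons[i];
      M.constraints.emplace_back(cl.begin(), cl.end());
    }
  }
  M.root_window = as<double>(tune["root_window"]);
  M.tip_window = as<double>(tune["tip_window"]);
  M.mult_rel = as<double>(tune["mult_rel"]);
  M.mult_scalar = as<double>(tune["mult_scalar"]);
  M.mult_tree = as<double>(tune["mult_tree"]);
  M.win_unit = as<double>(tune["win_unit"]);
  M.part_groups = part_groups;

  const int n_iter = as<int>(cfg_pack["n_iter"]);
  const int sample_every = as<int>(cfg_pack["sample_every"]);
  const int swap_every = as<int>(cfg_pack["swap_every"]);
  const double anneal_start = as<double>(cfg_pack["anneal_start"]);
  const double burnin_frac = as<double>(cfg_pack["burnin_frac"]);
  NumericVector heats = cfg_pack["heats"];
  const int n_chains = heats.size();

  // cumulative move weights
  std::vector<double> cumw(N_MOVES);
  double tot = 0;
  if (weights.size() != N_MOVES) stop("bad weight vector length");
  for (int i = 0; i < N_MOVES; ++i) { tot += weights[i]; cumw[i] = tot; }

  // initialize chains from R states
  std::vector<Chain> chains(n_chains);
  for (int c = 0; c < n_chains; ++c) {
    List st = init_chains[c];
    Chain& ch = chains[c];
    IntegerVector par = st["parent0"];
    ch.parent.assign(par.begin(), par.end());
    NumericVector age = st["age"];
    ch.age.assign(age.begin(), age.end());
    LogicalVector sa = st["sa"];
    ch.sa.assign(sa.begin(), sa.end());
    NumericMatrix rel = st["rel"];
    ch.rel.assign(rel.begin(), rel.end());
    NumericVector sg = st["sigma"];
    ch.sigma.assign(sg.begin(), sg.end());
    NumericVector al = st["alpha"];
    ch.alpha.assign(al.begin(), al.end());
    ch.c = as<double>(st["c"]);
    ch.d = as<double>(st["d"]);
    ch.v = as<double>(st["v"]);
    ch.s = as<double>(st["s"]);
    ch.ll.assign(M.npart, 0.0);
    update_rates_mat(M, ch);
    double lpr = lp_prior(M, ch);
    if (!std::isfinite(lpr)) stop("non-finite prior at initialization");
    if (!update_ll(M, ch, -1)) stop("non-finite likelihood at initialization");
    ch.lp = lpr;
    for (int j = 0; j < M.npart; ++j) ch.lp += ch.ll[j];
  }

  const int nsamp = n_iter / sample_every + 1;
  const int npcol = 4 + 1 + M.npart + M.nalpha + 4;
  NumericMatrix params(nsamp, npcol);
  List trees(nsamp);
  NumericVector att(N_MOVES), acc(N_MOVES);
  int swap_att = 0, swap_acc = 0;

  auto record = [&](int row, int it) {
    const Chain& ch = chains[0];
    int root = find_root(ch);
    int col = 0;
    double llsum = 0;
    for (int j = 0; j < M.npart; ++j) llsum += ch.ll[j];
    params(row, col++) = it;
    params(row, col++) = ch.lp;
    params(row, col++) = llsum;
    params(row, col++) = ch.age[root];
    params(row, col++) = ch.c;
    for (int j = 0; j < M.npart; ++j) params(row, col++) = ch.sigma[j];
    for (int j = 0; j < M.nalpha; ++j) params(row, col++) = ch.alpha[j];
    params(row, col++) = ch.d;
    params(row, col++) = ch.v;
    params(row, col++) = ch.s;
    int nsa = 0;
    for (int i = 0; i < M.ntip; ++i) nsa += ch.sa[i];
    params(row, col++) = nsa;
    IntegerVector par1(M.nn);
    for (int i = 0; i < M.nn; ++i)
      par1[i] = ch.parent[i] < 0 ? NA_INTEGER : ch.parent[i] + 1;
    NumericVector agev(ch.age.begin(), ch.age.end());
    LogicalVector sav(M.ntip);
    for (int i = 0; i < M.ntip; ++i) sav[i] = (bool)ch.sa[i];
    NumericMatrix relm(M.nn, M.npart);
    std::copy(ch.rel.begin(), ch.rel.end(), relm.begin());
    trees[row] = List::create(_["parent"] = par1, _["age"] = agev,
                              _["sa"] = sav, _["rel"] = relm);
  };
  record(0, 0);
  int row = 0;

  const int n_anneal = (int)(burnin_frac * n_iter);
  Chain prop;
  for (int it = 1; it <= n_iter; ++it) {
    double anneal = (it < n_anneal && anneal_start < 1)
      ? anneal_start + (1 - anneal_start) * ((double)it / n_anneal) : 1.0;
    for (int c = 0; c < n_chains; ++c) {
      double beta = heats[c] * anneal;
      double u = unif_rand() * tot;
      int mi = 0;
      while (u > cumw[mi]) ++mi;
      att[mi] += 1;
      prop = chains[c];
      double log_hr = 0;
      int ll_which = -2;
      if (!MOVES[mi](M, prop, log_hr, ll_which)) continue;
      double lpr = lp_prior(M, prop);
      if (!std::isfinite(lpr)) continue;
      if (ll_which != -2 && !update_ll(M, prop, ll_which)) continue;
      double lp2 = lpr;
      for (int j = 0; j < M.npart; ++j) lp2 += prop.ll[j];
      double log_acc = beta * (lp2 - chains[c].lp) + log_hr;
      if (std::log(unif_rand()) < log_acc) {
        prop.lp = lp2;
        chains[c] = prop;
        acc[mi] += 1;
      }
    }
    if (n_chains > 1 && it % swap_every == 0) {
      int i = (n_chains == 2) ? 0 : runif_index(n_chains - 1);
      ++swap_att;
      double log_acc = (heats[i] - heats[i + 1]) *
        (chains[i + 1].lp - chains[i].lp);
      if (std::log(unif_rand()) < log_acc) {
        std::swap(chains[i], chains[i + 1]);
        ++swap_acc;
      }
    }
    if (it % sample_every == 0) record(++row, it);
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["params"] = params, _["trees"] = trees, _["att"] = att, _["acc"] = acc,
    _["swap_att"] = swap_att, _["swap_acc"] = swap_acc);
}
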