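#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// postorder traversal from a 0-based parent vector (root coded -1)
static void postorder_nodes(const int* parent, int nn, std::vector<int>& ord) {
  std::vector<std::vector<int>> kids(nn);
  int root = -1;
  for (int i = 0; i < nn; ++i) {
    if (parent[i] < 0) root = i;
    else kids[parent[i]].push_back(i);
  }
  ord.clear();
  ord.reserve(nn);
  std::vector<int> stack;
  stack.push_back(root);
  while (!stack.empty()) {
    int nd = stack.back();
    stack.pop_back();
    ord.push_back(nd);
    for (int c : kids[nd]) stack.push_back(c);
  }
  std::reverse(ord.begin(), ord.end());
}

// Mkv log-likelihood of one model class on a dated tree.
// tipc: k x ntot x ntip cube of tip partials; the last k columns of every
// slice are the constant columns used by the acquisition-bias correction.
// Returns the summed corrected log-likelihood of the nchar data
// characters; -Inf when the Mkv denominator is non-positive.
static double group_loglik(const int* parent, int nn, int ntip,
                           const double* brlen,
                           const arma::mat& evec, const arma::vec& eval,
                           const arma::cube& tipc, int nchar,
                           const arma::vec& rates, bool correct,
                           const std::vector<int>& ord, int root,
                           bool unordered) {
  const int k = evec.n_rows;
  const int ntot = nchar + k;
  const int ncat = rates.n_elem;

  arma::mat ll(ntot, ncat);
  // partial-likelihood workspace: one k x ntot slab per node
  std::vector<double> part((size_t)nn * k * ntot);
  std::vector<double> logscale(ntot);
  std::vector<double> P(k * k), ev(k), child(k * ntot);
  // children of each internal node, found once
  std::vector<int> kid1(nn, -1), kid2(nn, -1);
  for (int i = 0; i < nn; ++i) {
    int p = parent[i];
    if (p >= 0) { if (kid1[p] < 0) kid1[p] = i; else kid2[p] = i; }
  }

  for (int cat = 0; cat < ncat; ++cat) {
    double rate = rates[cat];
    std::fill(logscale.begin(), logscale.end(), 0.0);
    for (int nd : ord) {
      if (nd < ntip) continue;
      double* acc = &part[(size_t)nd * k * ntot];
      for (int which = 0; which < 2; ++which) {
        int i = which == 0 ? kid1[nd] : kid2[nd];
        if (unordered) {
          // closed form for the unordered Mk chain: eigenvalues are 0 and
          // -k/(k-1); P = e I + (1-e)/k J with e = exp(-k b/(k-1))
          double e = std::exp(-(double)k / (k - 1.0) * brlen[i] * rate);
          double off = (1.0 - e) / k;
          double diag = e + off;
          for (int z = 0; z < k * k; ++z) P[z] = off;
          for (int a = 0; a < k; ++a) P[a + k * a] = diag;
        } else {
          // P = evec diag(exp(eval*b)) evec^T, column-major
          for (int s = 0; s < k; ++s)
            ev[s] = std::exp(eval[s] * brlen[i] * rate);
          for (int b = 0; b < k; ++b)
            for (int a = 0; a < k; ++a) {
              double acc2 = 0.0;
              for (int s = 0; s < k; ++s)
                acc2 += evec(a, s) * ev[s] * evec(b, s);
              P[a + k * b] = acc2 > 0.0 ? acc2 : 0.0;
            }
        }
        const double* L = (i < ntip) ? tipc.slice_memptr(i)
                                     : &part[(size_t)i * k * ntot];
        // child[, c] = P %*% L[, c]; accumulate product over children
        for (int c = 0; c < ntot; ++c) {
          const double* Lc = L + (size_t)c * k;
          for (int a = 0; a < k; ++a) {
            double s2 = 0.0;
            for (int s = 0; s < k; ++s) s2 += P[a + k * s] * Lc[s];
            child[a + (size_t)c * k] = s2;
          }
        }
        if (which == 0)
          std::copy(child.begin(), child.end(), acc);
        else
          for (int z = 0; z < k * ntot; ++z) acc[z] *= child[z];
      }
      // column scaling against underflow
      for (int c = 0; c < ntot; ++c) {
        double cm = 0.0;
        for (int a = 0; a < k; ++a) {
          double x = acc[a + (size_t)c * k];
          if (x > cm) cm = x;
        }
        if (cm > 0.0 && (cm < 1e-200 || cm > 1.0)) {
          for (int a = 0; a < k; ++a) acc[a + (size_t)c * k] /= cm;
          logscale[c] += std::log(cm);
        }
      }
    }
    const double* rootp = &part[(size_t)root * k * ntot];
    for (int c = 0; c < ntot; ++c) {
      double s2 = 0.0;
      for (int a = 0; a < k; ++a) s2 += rootp[a + (size_t)c * k];
      s2 /= (double)k;
      ll(c, cat) = (s2 > 0 ? std::log(s2) : -arma::datum::inf) + logscale[c];
    }
  }

  // average over categories (equal weights) on the log scale
  arma::vec lmean(ntot);
  for (int c = 0; c < ntot; ++c) {
    double m = ll.row(c).max();
    if (!std::isfinite(m)) { lmean[c] = -arma::datum::inf; continue; }
    double s = 0.0;
    for (int cat = 0; cat < ncat; ++cat) s += std::exp(ll(c, cat) - m);
    lmean[c] = m + std::log(s / ncat);
  }

  double total = 0.0;
  if (correct) {
    double pconst = 0.0;
    for (int s = 0; s < k; ++s) pconst += std::exp(lmean[nchar + s]);
    double denom = 1.0 - pconst;
    if (denom <= 0.0) return R_NegInf;
    double ldenom = std::log(denom);
    for (int c = 0; c < nchar; ++c) total += lmean[c] - ldenom;
  } else {
    for (int c = 0; c < nchar; ++c) total += lmean[c];
  }
  return total;
}

// Sum of corrected log-likelihoods over the model-class groups of one
// partition; shared by the exported evaluator and the MCMC core.
double mk_groups_loglik_raw(const int* parent, int nn, int ntip,
                            const double* brlen, const List& groups,
                            const double* rates, int ncat, bool correct) {
  std::vector<int> ord;
  postorder_nodes(parent, nn, ord);
  int root = -1;
  for (int i = 0; i < nn; ++i) if (parent[i] < 0) root = i;
  arma::vec rv(ncat);
  for (int c = 0; c < ncat; ++c) rv[c] = rates[c];
  double tot = 0.0;
  for (int gi = 0; gi < groups.size(); ++gi) {
    List g = groups[gi];
    NumericMatrix evec_r = g["evec"];
    NumericVector eval_r = g["eval"];
    NumericVector tipflat = g["tipflat"];
    int k = as<int>(g["k"]);
    int nchar = as<int>(g["nchar"]);
    bool unordered = !as<bool>(g["ordered"]);
    arma::mat evec(evec_r.begin(), k, k, false, true);
    arma::vec eval(eval_r.begin(), k, false, true);
    arma::cube tipc(tipflat.begin(), k, nchar + k, ntip, false, true);
    tot += group_loglik(parent, nn, ntip, brlen, evec, eval, tipc, nchar,
                        rv, correct, ord, root, unordered);
    if (!std::isfinite(tot)) return R_NegInf;
  }
  return tot;
}

// Log-likelihoods of selected partitions. part_groups is a list (one
// entry per partition) of lists of model-class groups, each group a list
// with elements evec (k x k), eval (k), tipflat (numeric of length
// k * (nchar + k) * ntip, constant columns appended), k, nchar.
// brlen_by_part: (2*ntip-1) x npart branch distances; rates_by_part:
// ncat x npart discrete-gamma rates. which_parts: 1-based partition
// indices to evaluate; other entries of the result are NA.
// [[Rcpp::export]]
NumericVector mk_loglik_parts_cpp(const IntegerVector& parent, int ntip,
                                  const NumericMatrix& brlen_by_part,
                                  const List& part_groups,
                                  const NumericMatrix& rates_by_part,
                                  bool correct,
                                  const IntegerVector& which_parts) {
  const int nn = parent.size();
  const int npart = part_groups.size();
  const int ncat = rates_by_part.nrow();
  std::vector<int> par(nn);
  for (int i = 0; i < nn; ++i) par[i] = parent[i];
  NumericVector out(npart, NA_REAL);
  for (int wi = 0; wi < which_parts.size(); ++wi) {
    int j = which_parts[wi] - 1;
    out[j] = mk_groups_loglik_raw(par.data(), nn, ntip, &brlen_by_part(0, j),
                                  part_groups[j], &rates_by_part(0, j),
                                  ncat, correct);
  }
  return out;
}

// Single-class interface used by the unit tests: tipL is a
// k x ntip x nchar cube of tip partials for the data characters only.
// [[Rcpp::export]]
double mk_group_loglik_cpp(const IntegerVector& parent, int ntip,
                           const NumericVector& brlen,
                           const arma::mat& evec, const arma::vec& eval,
                           const arma::cube& tipL, const arma::vec& rates,
                           bool correct) {
  const int nn = parent.size();
  const int k = evec.n_rows;
  const int nchar = tipL.n_slices;
  std::vector<int> par(nn);
  for (int i = 0; i < nn; ++i) par[i] = parent[i];
  std::vector<int> ord;
  postorder_nodes(par.data(), nn, ord);
  int root = -1;
  for (int i = 0; i < nn; ++i) if (par[i] < 0) root = i;
  // re-pack into the slice-per-tip layout with constant columns appended
  arma::cube tipc(k, nchar + k, ntip, arma::fill::zeros);
  for (int i = 0; i < ntip; ++i) {
    for (int c = 0; c < nchar; ++c) tipc.slice(i).col(c) = tipL.slice(c).col(i);
    for (int s = 0; s < k; ++s) tipc(s, nchar + s, i) = 1.0;
  }
  // exercise the eigen path here regardless of ordering so that the
  // closed-form unordered branch has an independent in-package check
  return group_loglik(par.data(), nn, ntip, brlen.begin(), evec, eval,
                      tipc, nchar, rates, correct, ord, root, false);
}

// Monophyly check of constraint tip sets given a 0-based parent vector.
// cons: list of 0-based tip index vectors.
// [[Rcpp::export]]
bool constraints_ok_cpp(const IntegerVector& parent, int ntip,
                        const List& cons) {
  const int nn = parent.size();
  std::vector<int> par(nn);
  for (int i = 0; i < nn; ++i) par[i] = parent[i];
  std::vector<int> ord;
  postorder_nodes(par.data(), nn, ord);
  std::vector<int> marked(nn), total(nn);
  for (int ci = 0; ci < cons.size(); ++ci) {
    IntegerVector cl = cons[ci];
    const int m = cl.size();
    std::fill(marked.begin(), marked.end(), 0);
    std::fill(total.begin(), total.end(), 0);
    for (int i = 0; i < m; ++i) marked[cl[i]] = 1;
    for (int i = 0; i < ntip; ++i) total[i] = 1;
    bool ok = false;
    for (int nd : ord) {
      int p = par[nd];
      if (p >= 0) { marked[p] += marked[nd]; total[p] += total[nd]; }
      if (nd >= ntip && marked[nd] == m && total[nd] == m) { ok = true; break; }
    }
    if (!ok) return false;
  }
  return true;
}

// Fast joint log prior of an MCMC state. pack is a list of constants
// assembled once per analysis (see .prior_pack in R). Mirrors the R
// reference implementation .lp_prior exactly.
// [[Rcpp::export]]
double lp_prior_cpp(const IntegerVector& parent, const NumericVector& age,
                    const LogicalVector& sa, const NumericMatrix& rel,
                    double c, const NumericVector& sigma,
                    const NumericVector& alpha, double d, double v,
                    double s, const List& pack) {
  if (d <= 0 || v < 0 || v >= 1 || s < 0 || s >= 1) return R_NegInf;
  if (c <= 0) return R_NegInf;
  const int npart = sigma.size();
  for (int j = 0; j < npart; ++j) if (sigma[j] <= 0) return R_NegInf;
  for (int j = 0; j < alpha.size(); ++j) if (alpha[j] <= 0) return R_NegInf;

  const double r = as<double>(pack["removal_prob"]);
  const double rho = as<double>(pack["rho"]);
  const bool cond_sampling = as<bool>(pack["cond_sampling"]);
  const int ntip = as<int>(pack["ntip"]);
  const LogicalVector fossil_mask = pack["fossil_mask"];
  const IntegerVector fossil_idx = pack["fossil_idx"];   // 0-based
  const NumericVector fmin = pack["fossil_min"];
  const NumericVector fmax = pack["fossil_max"];
  const double tip_window_const = as<double>(pack["tip_window_const"]);
  const int n_extant = as<int>(pack["n_extant"]);
  const double root_offset = as<double>(pack["root_offset"]);
  const double root_rate = as<double>(pack["root_rate"]);
  const double c_shape = as<double>(pack["c_shape"]);
  const double c_rate = as<double>(pack["c_rate"]);
  const double sigma_rate = as<double>(pack["sigma_rate"]);
  const double alpha_rate = as<double>(pack["alpha_rate"]);
  const double d_rate = as<double>(pack["d_rate"]);
  const IntegerVector calib_tips = pack["calib_tips"];   // 0-based, may be empty
  const double calib_mean = as<double>(pack["calib_mean"]);
  const double calib_sd = as<double>(pack["calib_sd"]);

  const int nn = parent.size();
  double lambda = d / (1 - v);
  double psi, mu;
  if (s == 0) { psi = 0.0; mu = v * lambda; }
  else {
    psi = v * lambda * s / (1 - s + r * s);
    mu = psi * (1 - s) / s;
  }
  int n_sa = 0, n_fossil_tip = 0;
  for (int i = 0; i < ntip; ++i) {
    if (sa[i]) ++n_sa;
    else if (fossil_mask[i]) ++n_fossil_tip;
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

  int root = -1;
  for (int i = ntip; i < nn; ++i) if (parent[i] < 0) { root = i; break; }
  if (root < 0) return R_NegInf;

  std::vector<bool> birth(nn, false);
  for (int i = ntip; i < nn; ++i) birth[i] = true;
  birth[root] = false;
  for (int i = 0; i < ntip; ++i) if (sa[i]) birth[parent[i]] = false;

  double lp = 2.0 * log_q(age[root]) + n_extant * std::log(rho);
  double llam = std::log(lambda);
  for (int i = ntip; i < nn; ++i)
    if (birth[i]) lp += llam + log_q(age[i]);
  if (n_fossil_tip > 0) {
    double lpsi = std::log(psi);
    for (int i = 0; i < ntip; ++i)
      if (fossil_mask[i] && !sa[i])
        lp += lpsi + std::log(r + (1 - r) * p0(age[i])) - log_q(age[i]);
  }
  if (n_sa > 0) lp += n_sa * (std::log(psi) + std::log1p(-r));
  if (cond_sampling) {
    double z = p0(age[root]);
    lp -= std::log1p(-z * z);
  }

  double troot = age[root];
  if (troot < root_offset) return R_NegInf;
  lp += std::log(root_rate) - root_rate * (troot - root_offset);
  for (int w = 0; w < fossil_idx.size(); ++w) {
    double ta = age[fossil_idx[w]];
    if (ta < fmin[w] || ta > fmax[w]) return R_NegInf;
  }
  lp += tip_window_const;

  // relative-rate priors (gamma with shape = rate = t_i c / sigma_j)
  for (int i = 0; i < nn; ++i) {
    int p = parent[i];
    if (p < 0) continue;
    double dur = age[p] - age[i];
    if (dur <= 0) continue;
    for (int j = 0; j < npart; ++j) {
      double shp = dur * c / sigma[j];
      lp += R::dgamma(rel(i, j), shp, 1.0 / shp, 1);
    }
  }

  lp += R::dgamma(c, c_shape, 1.0 / c_rate, 1);
  for (int j = 0; j < npart; ++j) lp += R::dexp(sigma[j], 1.0 / sigma_rate, 1);
  for (int j = 0; j < alpha.size(); ++j)
    lp += R::dexp(alpha[j], 1.0 / alpha_rate, 1);
  lp += R::dexp(d, 1.0 / d_rate, 1);

  if (calib_tips.size() > 0) {
    // MRCA of the calibrated tip set
    std::vector<int> cnt(nn, 0);
    int m = calib_tips.size();
    for (int w = 0; w < m; ++w) {
      int i = calib_tips[w];
      while (i >= 0) { ++cnt[i]; i = parent[i]; }
    }
    int mrca = root;
    // deepest node containing all: walk from root down is complex; use
    // the lowest node with cnt == m along the first tip's path
    int i = calib_tips[0];
    while (i >= 0) {
      if (cnt[i] == m) { mrca = i; break; }
      i = parent[i];
    }
    lp += R::dnorm(age[mrca], calib_mean, calib_sd, 1);
  }
  return lp;
}
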