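#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for binomial-logit models with an
// optional fixed covariate effect, an intrinsic CAR (ICAR) spatial random
// effect and an exchangeable random effect:
//   R_i ~ Binomial(N_i, p_i),  logit(p_i) = b0 [+ b1 X_i] [+ u_i] [+ v_i]
// Priors: b0, b1 ~ Normal(0, prior_sd_beta^2); sigma_u, sigma_v half-normal
// with scale prior_sd_sigma; u has the intrinsic pairwise-difference prior
// with per-sweep sum-to-zero recentering per connected component (the
// removed mean is absorbed into b0); islands (no neighbours) have u = 0.
// Single-site random-walk updates everywhere; proposal scales adapt toward
// a 0.44 acceptance rate during burn-in only; sigmas are updated by a
// random walk on the log scale. Uses R's RNG, so set.seed() in R makes
// runs reproducible.

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// [[Rcpp::export]]
List bym_mcmc_cpp(IntegerVector N, IntegerVector R, NumericVector X,
                  List nbrs, IntegerVector comp,
                  bool use_fixed, bool use_car, bool use_iid,
                  double prior_sd_beta, double prior_sd_sigma,
                  int iterations, int burnin, int thin, int adapt_window) {
  const int n = N.size();
  const double pb2 = 2.0 * prior_sd_beta * prior_sd_beta;
  const double ps2 = 2.0 * prior_sd_sigma * prior_sd_sigma;

  // adjacency as flat arrays
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = nbrs[i];
    nb[i] = std::vector<int>(v.begin(), v.end());
  }
  // edge list i<j and ICAR rank k_u
  std::vector<int> e1, e2;
  for (int i = 0; i < n; ++i)
    for (size_t k = 0; k < nb[i].size(); ++k)
      if (i < nb[i][k]) { e1.push_back(i); e2.push_back(nb[i][k]); }

  int n_comp = 0;
  for (int i = 0; i < n; ++i) n_comp = std::max(n_comp, comp[i] + 1);
  std::vector<int> comp_size(n_comp, 0);
  for (int i = 0; i < n; ++i) comp_size[comp[i]]++;
  int k_u = 0;  // rank of the ICAR precision = sum over components (size-1),
                // islands (size 1) contribute 0
  for (int c = 0; c < n_comp; ++c) if (comp_size[c] >= 2) k_u += comp_size[c] - 1;

  // state
  double Rtot = 0, Ntot = 0;
  for (int i = 0; i < n; ++i) { Rtot += R[i]; Ntot += N[i]; }
  double b0 = std::log((Rtot + 0.5) / (Ntot - Rtot + 0.5));
  double b1 = 0.0;
  std::vector<double> u(n, 0.0), v(n, 0.0), eta(n);
  double lsu = std::log(0.1), lsv = std::log(0.1);

  std::vector<double> Rd(n), Nd(n);
  for (int i = 0; i < n; ++i) { Rd[i] = R[i]; Nd[i] = N[i]; }

  auto recompute_eta = [&]() {
    for (int i = 0; i < n; ++i) {
      eta[i] = b0;
      if (use_fixed) eta[i] += b1 * X[i];
      if (use_car) eta[i] += u[i];
      if (use_iid) eta[i] += v[i];
    }
  };
  recompute_eta();

  auto loglik_i = [&](int i, double e) { return Rd[i] * e - Nd[i] * log1pexp_(e); };

  // proposal scales and acceptance bookkeeping
  double s_b0 = 0.1, s_b1 = 0.1, s_u = 0.3, s_v = 0.3, s_lu = 0.5, s_lv = 0.5;
  double a_b0 = 0, t_b0 = 0, a_b1 = 0, t_b1 = 0, a_u = 0, t_u = 0,
         a_v = 0, t_v = 0, a_lu = 0, t_lu = 0, a_lv = 0, t_lv = 0;
  const double target = 0.44;
  auto tune = [&](double &s, double &acc, double &tot) {
    if (tot > 0) {
      double r = acc / tot;
      s *= std::exp(0.8 * (r - target));
      if (s < 1e-4) s = 1e-4;
      if (s > 20.0) s = 20.0;
    }
    acc = 0; tot = 0;
  };

  const int n_ret = (iterations - burnin) / thin;
  NumericVector out_b0(n_ret), out_b1(use_fixed ? n_ret : 0),
      out_su(use_car ? n_ret : 0), out_sv(use_iid ? n_ret : 0), out_dev(n_ret);
  NumericMatrix out_u(use_car ? n_ret : 0, use_car ? n : 0);
  NumericMatrix out_v(use_iid ? n_ret : 0, use_iid ? n : 0);
  int ret = 0;

  for (int it = 0; it < iterations; ++it) {
    // --- b0 ---
    {
      double d = R::rnorm(0.0, s_b0);
      double dll = 0.0;
      for (int i = 0; i < n; ++i)
        dll += loglik_i(i, eta[i] + d) - loglik_i(i, eta[i]);
      dll += -((b0 + d) * (b0 + d) - b0 * b0) / pb2;
      t_b0 += 1;
      if (std::log(R::runif(0.0, 1.0)) < dll) {
        b0 += d; for (int i = 0; i < n; ++i) eta[i] += d; a_b0 += 1;
      }
    }
    // --- b1 ---
    if (use_fixed) {
      double d = R::rnorm(0.0, s_b1);
      double dll = 0.0;
      for (int i = 0; i < n; ++i)
        dll += loglik_i(i, eta[i] + d * X[i]) - loglik_i(i, eta[i]);
      dll += -((b1 + d) * (b1 + d) - b1 * b1) / pb2;
      t_b1 += 1;
      if (std::log(R::runif(0.0, 1.0)) < dll) {
        b1 += d; for (int i = 0; i < n; ++i) eta[i] += d * X[i]; a_b1 += 1;
      }
    }
    // --- u (single site), then recenter per component ---
    if (use_car) {
      double su2 = std::exp(2.0 * lsu);
      for (int i = 0; i < n; ++i) {
        if (nb[i].empty()) continue;  // island: u fixed at 0
        double d = R::rnorm(0.0, s_u);
        double ui2 = u[i] + d;
        double dpr = 0.0;
        for (size_t k = 0; k < nb[i].size(); ++k) {
          double uj = u[nb[i][k]];
          dpr += (ui2 - uj) * (ui2 - uj) - (u[i] - uj) * (u[i] - uj);
        }
        double dll = loglik_i(i, eta[i] + d) - loglik_i(i, eta[i]) - dpr / (2.0 * su2);
        t_u += 1;
        if (std::log(R::runif(0.0, 1.0)) < dll) { u[i] = ui2; eta[i] += d; a_u += 1; }
      }
      // sum-to-zero recentering; mean absorbed into b0
      std::vector<double> msum(n_comp, 0.0);
      for (int i = 0; i < n; ++i) msum[comp[i]] += u[i];
      double shift = 0.0;
      for (int c = 0; c < n_comp; ++c)
        if (comp_size[c] >= 2) shift += msum[c];
      shift /= n;
      for (int i = 0; i < n; ++i)
        if (comp_size[comp[i]] >= 2) u[i] -= msum[comp[i]] / comp_size[comp[i]];
      b0 += shift;
      recompute_eta();
    }
    // --- v (single site) ---
    if (use_iid) {
      double sv2 = std::exp(2.0 * lsv);
      for (int i = 0; i < n; ++i) {
        double d = R::rnorm(0.0, s_v);
        double vi2 = v[i] + d;
        double dll = loglik_i(i, eta[i] + d) - loglik_i(i, eta[i])
                     - (vi2 * vi2 - v[i] * v[i]) / (2.0 * sv2);
        t_v += 1;
        if (std::log(R::runif(0.0, 1.0)) < dll) { v[i] = vi2; eta[i] += d; a_v += 1; }
      }
    }
    // --- sigma_u (log-scale RW; half-normal prior) ---
    if (use_car) {
      double ss = 0.0;
      for (size_t k = 0; k < e1.size(); ++k) {
        double dd = u[e1[k]] - u[e2[k]];
        ss += dd * dd;
      }
      double lsu2 = lsu + R::rnorm(0.0, s_lu);
      double sg1 = std::exp(lsu), sg2 = std::exp(lsu2);
      double lp1 = -k_u * lsu - ss / (2.0 * sg1 * sg1) - sg1 * sg1 / ps2 + lsu;
      double lp2 = -k_u * lsu2 - ss / (2.0 * sg2 * sg2) - sg2 * sg2 / ps2 + lsu2;
      t_lu += 1;
      if (std::log(R::runif(0.0, 1.0)) < lp2 - lp1) { lsu = lsu2; a_lu += 1; }
    }
    // --- sigma_v ---
    if (use_iid) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += v[i] * v[i];
      double lsv2 = lsv + R::rnorm(0.0, s_lv);
      double sg1 = std::exp(lsv), sg2 = std::exp(lsv2);
      double lp1 = -n * lsv - ss / (2.0 * sg1 * sg1) - sg1 * sg1 / ps2 + lsv;
      double lp2 = -n * lsv2 - ss / (2.0 * sg2 * sg2) - sg2 * sg2 / ps2 + lsv2;
      t_lv += 1;
      if (std::log(R::runif(0.0, 1.0)) < lp2 - lp1) { lsv = lsv2; a_lv += 1; }
    }

    // adapt during burn-in only
    if (it < burnin && ((it + 1) % adapt_window == 0)) {
      tune(s_b0, a_b0, t_b0);
      if (use_fixed) tune(s_b1, a_b1, t_b1);
      if (use_car) { tune(s_u, a_u, t_u); tune(s_lu, a_lu, t_lu); }
      if (use_iid) { tune(s_v, a_v, t_v); tune(s_lv, a_lv, t_lv); }
    }
    if (it == burnin - 1) {  // reset acceptance counters for reporting
      a_b0 = t_b0 = a_b1 = t_b1 = a_u = t_u = a_v = t_v = a_lu = t_lu = a_lv = t_lv = 0;
    }

    // retain
    if (it >= burnin && ((it - burnin) % thin == 0) && ret < n_ret) {
      double dev = 0.0;
      for (int i = 0; i < n; ++i) dev += loglik_i(i, eta[i]);
      out_dev[ret] = -2.0 * dev;
      out_b0[ret] = b0;
      if (use_fixed) out_b1[ret] = b1;
      if (use_car) {
        out_su[ret] = std::exp(lsu);
        for (int i = 0; i < n; ++i) out_u(ret, i) = u[i];
      }
      if (use_iid) {
        out_sv[ret] = std::exp(lsv);
        for (int i = 0; i < n; ++i) out_v(ret, i) = v[i];
      }
      ++ret;
    }
  }

  NumericVector acc = NumericVector::create(
      _["beta0"] = t_b0 > 0 ? a_b0 / t_b0 : NA_REAL,
      _["beta1"] = t_b1 > 0 ? a_b1 / t_b1 : NA_REAL,
      _["u"] = t_u > 0 ? a_u / t_u : NA_REAL,
      _["v"] = t_v > 0 ? a_v / t_v : NA_REAL,
      _["log_sigma_u"] = t_lu > 0 ? a_lu / t_lu : NA_REAL,
      _["log_sigma_v"] = t_lv > 0 ? a_lv / t_lv : NA_REAL);

  return List::create(_["beta0"] = out_b0, _["beta1"] = out_b1,
                      _["sigma_u"] = out_su, _["sigma_v"] = out_sv,
                      _["u"] = out_u, _["v"] = out_v,
                      _["deviance"] = out_dev, _["acceptance"] = acc);
}
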