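// Single-site Gibbs samplers for whole-genome regression
// y = mu + sum_k z_k g_k + e, with model-specific marker-effect priors:
//   BRR    : g_k ~ N(0, s2g) common variance
//   BayesA : g_k ~ N(0, s2_k), s2_k ~ scaled-inv-chi2(df_g, S_g)
//   BayesB : point mass at 0 w.p. pi + BayesA slab
//   BayesC : point mass at 0 w.p. pi + common-variance normal slab
//   BL     : double-exponential via the exponential scale mixture
// All randomness goes through R's RNG, so chains are reproducible with
// set.seed() on the R side.
#include <Rcpp.h>
#include <numeric>
using namespace Rcpp;

// scaled-inverse-chi-square draw: (S + ss) / chi2_{df}
static inline double rsichisq(double df, double S) {
  return S / R::rchisq(df);
}

// inverse-Gaussian via Michael, Schucany & Haas (1976)
static inline double rinvgauss(double mu, double lambda) {
  double nu = R::norm_rand();
  double y = nu * nu;
  double x = mu + mu * mu * y / (2.0 * lambda) -
    mu / (2.0 * lambda) *
    std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  if (R::unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// [[Rcpp::export(name = ".gibbs_wgr")]]
List gibbs_wgr(NumericMatrix Z, NumericVector y, int model,
               int iters, int burnin, int thin,
               double df_e, double S_e, double df_g, double S_g,
               double pi0, bool estimate_pi,
               double bl_lambda2, double bl_shape, double bl_rate) {
  const int n = Z.nrow(), m = Z.ncol();
  std::vector<double> xtx(m);
  for (int k = 0; k < m; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, k) * Z(i, k);
    xtx[k] = s;
  }

  double mu = mean(y);
  std::vector<double> g(m, 0.0), e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  double vy = var(y);
  double s2e = vy * 0.5;
  double s2g_common = S_g / (df_g + 2.0);      // prior mode (BRR/BayesC)
  std::vector<double> s2g_k(m, s2g_common);    // per-marker (BayesA/B)
  std::vector<double> tau2(m, 1.0);            // BL scale mixture
  double lambda2 = bl_lambda2;
  double pi_zero = pi0;
  std::vector<int> delta(m, 1);

  std::vector<double> g_post(m, 0.0);
  double mu_post = 0.0, s2e_post = 0.0, s2g_post = 0.0, pi_post = 0.0;
  int n_saved = 0;
  std::vector<double> s2e_chain;

  for (int it = 0; it < iters; ++it) {
    // intercept (flat prior)
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = mu + ebar + R::norm_rand() * std::sqrt(s2e / n);
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    // marker effects
    int n_zero = 0;
    for (int k = 0; k < m; ++k) {
      if (xtx[k] < 1e-12) { g[k] = 0.0; ++n_zero; continue; }
      double g_old = g[k];
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += Z(i, k) * e[i];
      rhs += xtx[k] * g_old;

      double g_new;
      if (model == 3 || model == 4) { // spike and slab
        double vark = (model == 3) ? s2g_k[k] : s2g_common;
        double v0 = xtx[k] * s2e;
        double v1 = xtx[k] * xtx[k] * vark + v0;
        double log_in = std::log(1.0 - pi_zero) - 0.5 * std::log(v1) -
          0.5 * rhs * rhs / v1;
        double log_out = std::log(pi_zero) - 0.5 * std::log(v0) -
          0.5 * rhs * rhs / v0;
        double p_in = 1.0 / (1.0 + std::exp(log_out - log_in));
        if (R::unif_rand() < p_in) {
          delta[k] = 1;
          double c = xtx[k] + s2e / vark;
          g_new = rhs / c + R::norm_rand() * std::sqrt(s2e / c);
        } else {
          delta[k] = 0;
          g_new = 0.0;
          ++n_zero;
        }
      } else if (model == 5) { // Bayesian LASSO
        double c = xtx[k] + 1.0 / tau2[k];
        g_new = rhs / c + R::norm_rand() * std::sqrt(s2e / c);
      } else { // BRR (1) / BayesA (2)
        double vark = (model == 2) ? s2g_k[k] : s2g_common;
        double c = xtx[k] + s2e / vark;
        g_new = rhs / c + R::norm_rand() * std::sqrt(s2e / c);
      }
      if (g_new != g_old) {
        double dg = g_new - g_old;
        for (int i = 0; i < n; ++i) e[i] -= Z(i, k) * dg;
        g[k] = g_new;
      }
    }

    // marker-effect variances
    if (model == 2 || model == 3) {
      for (int k = 0; k < m; ++k)
        s2g_k[k] = rsichisq(df_g + 1.0, S_g + g[k] * g[k]);
    } else if (model == 1 || model == 4) {
      double ss = 0.0; int cnt = 0;
      for (int k = 0; k < m; ++k)
        if (g[k] != 0.0) { ss += g[k] * g[k]; ++cnt; }
      s2g_common = rsichisq(df_g + cnt, S_g + ss);
    } else if (model == 5) {
      double sum_tau2 = 0.0;
      for (int k = 0; k < m; ++k) {
        double g2 = g[k] * g[k];
        if (g2 < 1e-12) {
          tau2[k] = R::exp_rand() * 2.0 / lambda2; // prior Exp(lambda2/2)
        } else {
          double inv = rinvgauss(std::sqrt(lambda2 * s2e / g2), lambda2);
          tau2[k] = 1.0 / inv;
        }
        sum_tau2 += tau2[k];
      }
      lambda2 = R::rgamma(bl_shape + m, 1.0 / (bl_rate + sum_tau2 / 2.0));
    }

    // mixture proportion
    if ((model == 3 || model == 4) && estimate_pi) {
      int nz = 0;
      for (int k = 0; k < m; ++k) if (delta[k] == 0) ++nz;
      pi_zero = R::rbeta(1.0 + nz, 1.0 + (m - nz));
      if (pi_zero < 1e-6) pi_zero = 1e-6;
      if (pi_zero > 1.0 - 1e-6) pi_zero = 1.0 - 1e-6;
    }

    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = rsichisq(df_e + n, S_e + sse);

    if (it >= burnin && ((it - burnin) % thin == 0)) {
      ++n_saved;
      mu_post += mu;
      s2e_post += s2e;
      s2g_post += (model == 2 || model == 3)
        ? std::accumulate(s2g_k.begin(), s2g_k.end(), 0.0) / m
        : s2g_common;
      pi_post += pi_zero;
      for (int k = 0; k < m; ++k) g_post[k] += g[k];
      s2e_chain.push_back(s2e);
    }
  }

  NumericVector gp(m);
  for (int k = 0; k < m; ++k) gp[k] = g_post[k] / n_saved;
  return List::create(
    _["mu"] = mu_post / n_saved,
    _["effects"] = gp,
    _["sigma2_e"] = s2e_post / n_saved,
    _["sigma2_g"] = s2g_post / n_saved,
    _["pi_zero"] = pi_post / n_saved,
    _["n_saved"] = n_saved,
    _["sigma2_e_chain"] = wrap(s2e_chain));
}
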