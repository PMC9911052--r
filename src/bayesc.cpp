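#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-site Gibbs sampler for BayesC with fixed pi: y = Z a d + e, with
// d_j ~ Bern(1 - pi), a_j | d_j = 1 ~ N(0, s2a) (common slab variance),
// scaled-inverse-chi-square priors on s2a and s2e (nu df, scales s_a, s_e).
// Z is expected centred with fixed effects already projected out, so no
// explicit intercept is sampled.  Uses R's RNG.
// [[Rcpp::export]]
List bayesc_gibbs(const NumericMatrix &Z, const NumericVector &y,
                  double pi0, int iters, int burnin, double nu,
                  double s_a, double s_e) {
  const int n = Z.nrow(), m = Z.ncol();
  std::vector<double> a(m, 0.0), e(n), czz(m);
  std::vector<int> in_model(m, 0);
  for (int i = 0; i < n; ++i) e[i] = y[i];
  for (int j = 0; j < m; ++j) {
    double c = 0.0;
    for (int i = 0; i < n; ++i) c += Z(i, j) * Z(i, j);
    czz[j] = c;
  }
  double s2a = s_a, s2e = s_e;
  const double log_prior_odds =
      (pi0 <= 0.0) ? R_PosInf : std::log((1.0 - pi0) / pi0);

  NumericVector post_a(m), post_incl(m);
  double post_s2a = 0.0, post_s2e = 0.0;
  int n_keep = 0;

  for (int it = 0; it < iters; ++it) {
    for (int j = 0; j < m; ++j) {
      const double c = czz[j];
      if (c <= 0.0) continue; // monomorphic column
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += Z(i, j) * e[i];
      rhs += c * a[j];
      // marginal of rhs: N(0, c*s2e) under exclusion,
      // N(0, c^2*s2a + c*s2e) under inclusion
      const double v0 = c * s2e, v1 = c * c * s2a + c * s2e;
      bool include;
      if (pi0 <= 0.0) {
        include = true;
      } else {
        const double logbf = 0.5 * std::log(v0 / v1) +
                             0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
        const double lodds = log_prior_odds + logbf;
        const double p1 = 1.0 / (1.0 + std::exp(-lodds));
        include = unif_rand() < p1;
      }
      double a_new = 0.0;
      if (include) {
        const double prec = c + s2e / s2a;
        a_new = rhs / prec + norm_rand() * std::sqrt(s2e / prec);
      }
      if (a_new != a[j]) {
        const double diff = a[j] - a_new;
        for (int i = 0; i < n; ++i) e[i] += Z(i, j) * diff;
        a[j] = a_new;
      }
      in_model[j] = include ? 1 : 0;
    }
    // variance components
    double ssa = 0.0;
    int m_in = 0;
    for (int j = 0; j < m; ++j)
      if (in_model[j]) { ssa += a[j] * a[j]; ++m_in; }
    s2a = (ssa + nu * s_a) / R::rchisq(nu + m_in);
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = (sse + nu * s_e) / R::rchisq(nu + n);
    if (!std::isfinite(s2e) || !std::isfinite(s2a) || s2e > 1e12)
      stop("BayesC variance update diverged at iteration %d", it + 1);

    if (it >= burnin) {
      for (int j = 0; j < m; ++j) {
        post_a[j] += a[j];
        post_incl[j] += in_model[j];
      }
      post_s2a += s2a;
      post_s2e += s2e;
      ++n_keep;
    }
  }
  for (int j = 0; j < m; ++j) {
    post_a[j] /= n_keep;
    post_incl[j] /= n_keep;
  }
  return List::create(_["alpha"] = post_a, _["inclusion"] = post_incl,
                      _["s2a"] = post_s2a / n_keep,
                      _["s2e"] = post_s2e / n_keep, _["mu"] = 0.0);
}
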