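#include <Rcpp.h>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double softplus(double x) {
  if (x > 35.0) return x + std::exp(-x);
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Joint log density (non-centred parameterisation, log-scale sigmas with
// Jacobian) and its gradient, for the aggregated binomial multilevel
// model. Mirrors the reference R implementation lp_grad_r(); the two are
// cross-checked in the test suite.
//
// theta layout: alpha, beta (p_eff), z per group (concatenated), log_sigma
// per group.
// [[Rcpp::export(name = ".lp_grad_cpp")]]
List lp_grad_cpp(NumericVector theta, List ctx) {
  NumericVector k = ctx["k"];
  NumericVector W = ctx["W"];
  NumericMatrix X = ctx["X"];
  List group_idx = ctx["group_idx"];      // 1-based index vectors
  IntegerVector group_sizes = ctx["group_sizes"];
  LogicalVector centered = ctx["centered"];
  NumericVector prior_alpha = ctx["prior_alpha"];  // (loc, scale)
  NumericVector prior_beta = ctx["prior_beta"];    // (loc, scale)
  double sigma_rate = as<double>(ctx["sigma_rate"]);
  double lchoose_sum = as<double>(ctx["lchoose_sum"]);

  const int n = k.size();
  const int p_eff = X.ncol();
  const int n_groups = group_idx.size();

  int pos = 0;
  const double alpha = theta[pos++];
  std::vector<double> beta(p_eff);
  for (int j = 0; j < p_eff; ++j) beta[j] = theta[pos++];
  std::vector<int> z_off(n_groups);
  int off = pos;
  for (int g = 0; g < n_groups; ++g) { z_off[g] = off; off += group_sizes[g]; }
  std::vector<double> log_sig(n_groups), sig(n_groups);
  for (int g = 0; g < n_groups; ++g) {
    log_sig[g] = theta[off + g];
    sig[g] = std::exp(log_sig[g]);
  }

  // linear predictor
  std::vector<double> eta(n, alpha);
  for (int j = 0; j < p_eff; ++j) {
    const double b = beta[j];
    for (int i = 0; i < n; ++i) eta[i] += b * X(i, j);
  }
  for (int g = 0; g < n_groups; ++g) {
    IntegerVector idx = group_idx[g];
    const double s = centered[g] ? 1.0 : sig[g];
    const int zo = z_off[g];
    for (int i = 0; i < n; ++i) eta[i] += s * theta[zo + idx[i] - 1];
  }

  // binomial log likelihood and d ll / d eta
  double lp = lchoose_sum;
  std::vector<double> d_eta(n);
  for (int i = 0; i < n; ++i) {
    lp += k[i] * eta[i] - W[i] * softplus(eta[i]);
    const double p = 1.0 / (1.0 + std::exp(-eta[i]));
    d_eta[i] = k[i] - W[i] * p;
  }

  NumericVector grad(theta.size());
  // priors on alpha and beta
  const double a_sc2 = prior_alpha[1] * prior_alpha[1];
  lp += -0.5 * (alpha - prior_alpha[0]) * (alpha - prior_alpha[0]) / a_sc2;
  const double b_sc2 = prior_beta[1] * prior_beta[1];
  for (int j = 0; j < p_eff; ++j) {
    lp += -0.5 * (beta[j] - prior_beta[0]) * (beta[j] - prior_beta[0]) / b_sc2;
  }
  double g_alpha = -(alpha - prior_alpha[0]) / a_sc2;
  for (int i = 0; i < n; ++i) g_alpha += d_eta[i];
  grad[0] = g_alpha;
  for (int j = 0; j < p_eff; ++j) {
    double gb = -(beta[j] - prior_beta[0]) / b_sc2;
    for (int i = 0; i < n; ++i) gb += X(i, j) * d_eta[i];
    grad[1 + j] = gb;
  }
  // groups: sigma ~ Exp(rate) on the natural scale, sampled as log sigma
  // (Jacobian included); intercepts either non-centred (z ~ N(0,1),
  // a = sigma z) or centred (a ~ N(0, sigma) directly)
  for (int g = 0; g < n_groups; ++g) {
    IntegerVector idx = group_idx[g];
    const int L = group_sizes[g];
    const int zo = z_off[g];
    const double s = sig[g];
    std::vector<double> s_de(L, 0.0);
    for (int i = 0; i < n; ++i) s_de[idx[i] - 1] += d_eta[i];
    if (centered[g]) {
      const double s2 = s * s;
      double asum2 = 0.0;
      for (int l = 0; l < L; ++l) {
        const double a = theta[zo + l];
        asum2 += a * a;
        grad[zo + l] = s_de[l] - a / s2;
      }
      lp += -0.5 * asum2 / s2 - L * log_sig[g] - sigma_rate * s + log_sig[g];
      grad[off + g] = asum2 / s2 - L - sigma_rate * s + 1.0;
    } else {
      double zsum2 = 0.0, zde = 0.0;
      for (int l = 0; l < L; ++l) {
        const double z = theta[zo + l];
        zsum2 += z * z;
        zde += z * s_de[l];
        grad[zo + l] = s * s_de[l] - z;
      }
      lp += -0.5 * zsum2 - sigma_rate * s + log_sig[g];
      grad[off + g] = s * zde - sigma_rate * s + 1.0;
    }
  }
  return List::create(Named("lp") = lp, Named("grad") = grad);
}
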