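#include <Rcpp.h>
using namespace Rcpp;

// One EM (Baum-Welch) step for a 2-state / 2-symbol HMM with scaled
// forward-backward recursions. obs is 1-based symbol indices (1 or 2).
// Returns the updated parameters together with the log-likelihood of the
// *current* parameters (the standard E-step likelihood).
// [[Rcpp::export(name = ".hmm_em_step")]]
List hmm_em_step(const IntegerVector& obs,
                 const NumericMatrix& P,
                 const NumericMatrix& E,
                 const NumericVector& pi0) {
  const int n = obs.size();
  NumericMatrix alpha(n, 2), beta(n, 2);
  NumericVector scale(n);

  double a0 = pi0[0] * E(0, obs[0] - 1);
  double a1 = pi0[1] * E(1, obs[0] - 1);
  scale[0] = a0 + a1;
  if (scale[0] <= 0.0) return List::create(_["loglik"] = R_NegInf);
  alpha(0, 0) = a0 / scale[0];
  alpha(0, 1) = a1 / scale[0];
  for (int t = 1; t < n; ++t) {
    const int o = obs[t] - 1;
    a0 = (alpha(t - 1, 0) * P(0, 0) + alpha(t - 1, 1) * P(1, 0)) * E(0, o);
    a1 = (alpha(t - 1, 0) * P(0, 1) + alpha(t - 1, 1) * P(1, 1)) * E(1, o);
    scale[t] = a0 + a1;
    if (scale[t] <= 0.0) return List::create(_["loglik"] = R_NegInf);
    alpha(t, 0) = a0 / scale[t];
    alpha(t, 1) = a1 / scale[t];
  }
  double loglik = 0.0;
  for (int t = 0; t < n; ++t) loglik += std::log(scale[t]);

  beta(n - 1, 0) = 1.0;
  beta(n - 1, 1) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    const int o = obs[t + 1] - 1;
    const double b0 = E(0, o) * beta(t + 1, 0);
    const double b1 = E(1, o) * beta(t + 1, 1);
    beta(t, 0) = (P(0, 0) * b0 + P(0, 1) * b1) / scale[t + 1];
    beta(t, 1) = (P(1, 0) * b0 + P(1, 1) * b1) / scale[t + 1];
  }

  // gamma accumulators for the M-step
  double xi[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
  double gsum[2] = {0.0, 0.0};
  double esum[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
  NumericVector pi_new(2);
  for (int t = 0; t < n; ++t) {
    double g0 = alpha(t, 0) * beta(t, 0);
    double g1 = alpha(t, 1) * beta(t, 1);
    const double gs = g0 + g1;
    g0 /= gs;
    g1 /= gs;
    if (t == 0) { pi_new[0] = g0; pi_new[1] = g1; }
    const int o = obs[t] - 1;
    esum[0][o] += g0;
    esum[1][o] += g1;
    gsum[0] += g0;
    gsum[1] += g1;
    if (t < n - 1) {
      const int o1 = obs[t + 1] - 1;
      for (int i = 0; i < 2; ++i)
        for (int j = 0; j < 2; ++j)
          xi[i][j] += alpha(t, i) * P(i, j) * E(j, o1) * beta(t + 1, j) /
                      scale[t + 1];
    }
  }
  NumericMatrix P_new(2, 2), E_new(2, 2);
  for (int i = 0; i < 2; ++i) {
    const double rs = xi[i][0] + xi[i][1];
    for (int j = 0; j < 2; ++j)
      P_new(i, j) = rs > 0.0 ? xi[i][j] / rs : NA_REAL;
    for (int k = 0; k < 2; ++k)
      E_new(i, k) = gsum[i] > 0.0 ? esum[i][k] / gsum[i] : NA_REAL;
  }
  return List::create(_["P"] = P_new, _["E"] = E_new, _["pi"] = pi_new,
                      _["loglik"] = loglik);
}
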