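#include <Rcpp.h>
using namespace Rcpp;

// One EM E-step for a discrete-output hidden Markov model over a list
// of observation sequences (0-based symbol indices). Scaled
// forward-backward; returns the log-likelihood and the sufficient
// statistics for the M-step.
// [[Rcpp::export]]
List hmm_estep(List seqs, NumericMatrix A, NumericMatrix B,
               NumericVector pi0) {
  const int K = A.nrow();
  const int S = B.ncol();
  NumericMatrix xi_sum(K, K);     // expected transition counts
  NumericMatrix gs(K, S);         // expected state-symbol counts
  NumericVector g1(K);            // expected initial-state counts
  double loglik = 0.0;

  for (int q = 0; q < seqs.size(); ++q) {
    IntegerVector obs = seqs[q];
    const int T = obs.size();
    if (T < 1) continue;
    NumericMatrix alpha(T, K), beta(T, K);
    NumericVector c(T);

    // forward
    double csum = 0.0;
    for (int k = 0; k < K; ++k) {
      alpha(0, k) = pi0[k] * B(k, obs[0]);
      csum += alpha(0, k);
    }
    if (csum <= 0) csum = 1e-300;
    c[0] = csum;
    for (int k = 0; k < K; ++k) alpha(0, k) /= csum;
    for (int t = 1; t < T; ++t) {
      csum = 0.0;
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j) s += alpha(t - 1, j) * A(j, k);
        double v = s * B(k, obs[t]);
        alpha(t, k) = v;
        csum += v;
      }
      if (csum <= 0) csum = 1e-300;
      c[t] = csum;
      for (int k = 0; k < K; ++k) alpha(t, k) /= csum;
    }
    for (int t = 0; t < T; ++t) loglik += std::log(c[t]);

    // backward (scaled with the same constants)
    for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < K; ++j)
          s += A(k, j) * B(j, obs[t + 1]) * beta(t + 1, j);
        beta(t, k) = s / c[t + 1];
      }
    }

    // accumulate statistics
    for (int t = 0; t < T; ++t) {
      for (int k = 0; k < K; ++k) {
        double g = alpha(t, k) * beta(t, k);
        gs(k, obs[t]) += g;
        if (t == 0) g1[k] += g;
      }
    }
    for (int t = 0; t < T - 1; ++t) {
      for (int k = 0; k < K; ++k) {
        double a = alpha(t, k);
        if (a == 0.0) continue;
        for (int j = 0; j < K; ++j) {
          xi_sum(k, j) += a * A(k, j) * B(j, obs[t + 1]) *
            beta(t + 1, j) / c[t + 1];
        }
      }
    }
  }
  return List::create(_["loglik"] = loglik, _["xi"] = xi_sum,
                      _["gamma_symbol"] = gs, _["gamma_init"] = g1);
}
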