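#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward E-step for a zero-mean Gaussian-emission HMM over
// displacement sequences. obs holds all sequences concatenated; seqlen gives
// the length of each. Returns the pooled sufficient statistics for the
// Baum-Welch M-step and, optionally, the per-observation posterior marginals.
// [[Rcpp::export]]
List hmm_estep_cpp(NumericVector obs, IntegerVector seqlen,
                   NumericVector var, NumericVector pi, NumericMatrix A,
                   bool want_gamma = false) {
  const int K = var.size();
  const int n = obs.size();
  const int S = seqlen.size();
  const double tiny = 1e-300;

  NumericMatrix B(n, K);
  for (int k = 0; k < K; ++k) {
    const double v = var[k];
    const double c = 1.0 / std::sqrt(2.0 * M_PI * v);
    for (int t = 0; t < n; ++t) {
      double d = c * std::exp(-0.5 * obs[t] * obs[t] / v);
      B(t, k) = (d > tiny) ? d : tiny;
    }
  }

  double loglik = 0.0;
  NumericVector Ng(K), Sxx(K), first(K);
  NumericMatrix Xi(K, K);
  NumericMatrix G = want_gamma ? NumericMatrix(n, K) : NumericMatrix(1, 1);

  int off = 0;
  for (int s = 0; s < S; ++s) {
    const int T = seqlen[s];
    NumericMatrix alpha(T, K), beta(T, K);
    NumericVector cs(T);

    double csum = 0.0;
    for (int k = 0; k < K; ++k) {
      alpha(0, k) = pi[k] * B(off, k);
      csum += alpha(0, k);
    }
    if (csum < tiny) csum = tiny;
    cs[0] = csum;
    for (int k = 0; k < K; ++k) alpha(0, k) /= csum;

    for (int t = 1; t < T; ++t) {
      csum = 0.0;
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j) acc += alpha(t - 1, j) * A(j, k);
        alpha(t, k) = acc * B(off + t, k);
        csum += alpha(t, k);
      }
      if (csum < tiny) csum = tiny;
      cs[t] = csum;
      for (int k = 0; k < K; ++k) alpha(t, k) /= csum;
    }

    for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int j = 0; j < K; ++j) {
        double acc = 0.0;
        for (int k = 0; k < K; ++k)
          acc += A(j, k) * B(off + t + 1, k) * beta(t + 1, k);
        beta(t, j) = acc / cs[t + 1];
      }
    }

    for (int t = 0; t < T; ++t) {
      double gsum = 0.0;
      for (int k = 0; k < K; ++k) gsum += alpha(t, k) * beta(t, k);
      if (gsum < tiny) gsum = tiny;
      for (int k = 0; k < K; ++k) {
        const double g = alpha(t, k) * beta(t, k) / gsum;
        Ng[k] += g;
        Sxx[k] += g * obs[off + t] * obs[off + t];
        if (t == 0) first[k] += g;
        if (want_gamma) G(off + t, k) = g;
      }
    }

    for (int t = 0; t < T - 1; ++t) {
      for (int j = 0; j < K; ++j) {
        for (int k = 0; k < K; ++k) {
          Xi(j, k) += alpha(t, j) * A(j, k) * B(off + t + 1, k) *
                      beta(t + 1, k) / cs[t + 1];
        }
      }
    }

    for (int t = 0; t < T; ++t) loglik += std::log(cs[t]);
    off += T;
  }

  List out = List::create(
    _["loglik"] = loglik, _["Ngamma"] = Ng, _["Sxx"] = Sxx,
    _["xi"] = Xi, _["first"] = first);
  if (want_gamma) out["gamma"] = G;
  return out;
}
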