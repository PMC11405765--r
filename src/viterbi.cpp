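#include <Rcpp.h>
using namespace Rcpp;

// Most-probable state path for a homogeneous HMM with Gaussian emissions.
// obs: observed per-bin frequencies (no NAs); means/variance: shared-variance
// Gaussian emission parameters; log_init: log initial state probabilities;
// log_trans: S x S log transition matrix. Returns 0-based state codes.
// [[Rcpp::export]]
IntegerVector viterbi_gauss(NumericVector obs, NumericVector means,
                            double variance, NumericVector log_init,
                            NumericMatrix log_trans) {
  const int n = obs.size();
  const int S = means.size();
  if (n == 0) stop("empty observation sequence");
  const double inv2v = 1.0 / (2.0 * variance);
  // log N(x; mu, v) up to the common constant -0.5*log(2*pi*v), which
  // cancels in the argmax.
  NumericMatrix delta(S, n);
  IntegerMatrix psi(S, n);
  for (int s = 0; s < S; ++s) {
    double d = obs[0] - means[s];
    delta(s, 0) = log_init[s] - d * d * inv2v;
  }
  for (int t = 1; t < n; ++t) {
    for (int s = 0; s < S; ++s) {
      double best = delta(0, t - 1) + log_trans(0, s);
      int arg = 0;
      for (int r = 1; r < S; ++r) {
        double v = delta(r, t - 1) + log_trans(r, s);
        if (v > best) { best = v; arg = r; }
      }
      double d = obs[t] - means[s];
      delta(s, t) = best - d * d * inv2v;
      psi(s, t) = arg;
    }
  }
  IntegerVector path(n);
  int arg = 0;
  double best = delta(0, n - 1);
  for (int s = 1; s < S; ++s)
    if (delta(s, n - 1) > best) { best = delta(s, n - 1); arg = s; }
  path[n - 1] = arg;
  for (int t = n - 1; t > 0; --t) {
    arg = psi(arg, t);
    path[t - 1] = arg;
  }
  return path;
}
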