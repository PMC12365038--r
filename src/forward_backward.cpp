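#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursion for a discrete-state HMM.
// logB: T x K log emission densities; pi: K initial probs; A: K x K
// transition matrix (rows sum to 1). Per-sample scaling prevents underflow;
// the per-row max of logB is factored out so emissions stay in range.
// Returns marginal posteriors gamma (T x K), summed two-slice marginals
// xi_sum (K x K) and the total data log-likelihood.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix logB, NumericVector pi, NumericMatrix A) {
  const int T = logB.nrow(), K = logB.ncol();
  if (K > 8) stop("forward-backward supports at most 8 states");
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), B(T, K), xisum(K, K);
  std::vector<double> c(T), m(T);

  for (int t = 0; t < T; t++) {
    double mx = logB(t, 0);
    for (int k = 1; k < K; k++) mx = std::max(mx, logB(t, k));
    m[t] = mx;
    for (int k = 0; k < K; k++) B(t, k) = std::exp(logB(t, k) - mx);
  }

  double s = 0.0;
  for (int k = 0; k < K; k++) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
  if (s <= 0.0) stop("forward pass underflow at t = 1");
  c[0] = s;
  for (int k = 0; k < K; k++) alpha(0, k) /= s;

  for (int t = 1; t < T; t++) {
    s = 0.0;
    for (int k = 0; k < K; k++) {
      double a = 0.0;
      for (int j = 0; j < K; j++) a += alpha(t - 1, j) * A(j, k);
      a *= B(t, k);
      alpha(t, k) = a;
      s += a;
    }
    if (s <= 0.0) stop("forward pass underflow");
    c[t] = s;
    for (int k = 0; k < K; k++) alpha(t, k) /= s;
  }

  for (int k = 0; k < K; k++) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; t--) {
    for (int j = 0; j < K; j++) {
      double b = 0.0;
      for (int k = 0; k < K; k++) b += A(j, k) * B(t + 1, k) * beta(t + 1, k);
      beta(t, j) = b / c[t + 1];
    }
  }

  double ll = 0.0;
  for (int t = 0; t < T; t++) ll += std::log(c[t]) + m[t];

  for (int t = 0; t < T; t++) {
    double g = 0.0;
    for (int k = 0; k < K; k++) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; k++) gamma(t, k) /= g;
  }

  for (int t = 0; t < T - 1; t++) {
    double z = 0.0;
    double xi[64];
    int idx = 0;
    for (int j = 0; j < K; j++)
      for (int k = 0; k < K; k++) {
        double v = alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k);
        xi[idx++] = v;
        z += v;
      }
    idx = 0;
    for (int j = 0; j < K; j++)
      for (int k = 0; k < K; k++) xisum(j, k) += xi[idx++] / z;
  }

  return List::create(_["gamma"] = gamma, _["xi_sum"] = xisum,
                      _["loglik"] = ll);
}
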