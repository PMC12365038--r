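#include <Rcpp.h>
using namespace Rcpp;

// direct form II transposed IIR filter, zero initial conditions, in place
static void lfilter(const std::vector<double>& b, const std::vector<double>& a,
                    std::vector<double>& x) {
  const int nz = std::max(b.size(), a.size()) - 1;
  // coefficients zero-padded to a common length so the inner loop is tight
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  std::copy(b.begin(), b.end(), bb.begin());
  std::copy(a.begin(), a.end(), aa.begin());
  std::vector<double> z(nz + 1, 0.0);
  const double b0 = bb[0];
  const double* __restrict bp = bb.data();
  const double* __restrict ap = aa.data();
  double* __restrict zp = z.data();
  double* __restrict xp = x.data();
  const size_t n = x.size();
  for (size_t t = 0; t < n; t++) {
    const double xi = xp[t];
    const double yi = b0 * xi + zp[0];
    for (int k = 0; k < nz; k++)
      zp[k] = bp[k + 1] * xi + zp[k + 1] - ap[k + 1] * yi;
    xp[t] = yi;
  }
}

// Zero-phase (forward-backward) IIR filtering of each row of X with
// reflected edge padding of npad samples per end.
// [[Rcpp::export(name = ".filtfilt_cpp")]]
NumericMatrix filtfilt_cpp(NumericVector b_, NumericVector a_,
                           NumericMatrix X, int npad) {
  const int nch = X.nrow(), n = X.ncol();
  if (npad >= n) stop("padding must be shorter than the series");
  std::vector<double> b(b_.begin(), b_.end()), a(a_.begin(), a_.end());
  const double a0 = a[0];
  for (auto& v : b) v /= a0;
  for (auto& v : a) v /= a0;
  NumericMatrix Y(nch, n);
  std::vector<double> buf(n + 2 * npad);
  for (int c = 0; c < nch; c++) {
    for (int t = 0; t < npad; t++)
      buf[t] = 2.0 * X(c, 0) - X(c, npad - t);
    for (int t = 0; t < n; t++) buf[npad + t] = X(c, t);
    for (int t = 0; t < npad; t++)
      buf[npad + n + t] = 2.0 * X(c, n - 1) - X(c, n - 2 - t);
    lfilter(b, a, buf);
    std::reverse(buf.begin(), buf.end());
    lfilter(b, a, buf);
    std::reverse(buf.begin(), buf.end());
    for (int t = 0; t < n; t++) Y(c, t) = buf[npad + t];
  }
  return Y;
}
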