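#include <Rcpp.h>
using namespace Rcpp;

// Cascade of second-order sections applied forward-backward (zero phase)
// to every column of x, with odd-reflection edge padding of `padlen`
// samples. `b` and `a` hold one section per row (3 coefficients each,
// a[.,0] normalized to 1).

static inline void run_cascade(std::vector<double>& y,
                               const NumericMatrix& b,
                               const NumericMatrix& a) {
  const int nsec = b.nrow();
  const int n = (int) y.size();
  for (int s = 0; s < nsec; ++s) {
    const double b0 = b(s, 0), b1 = b(s, 1), b2 = b(s, 2);
    const double a1 = a(s, 1), a2 = a(s, 2);
    double z1 = 0.0, z2 = 0.0; // direct form II transposed state
    for (int i = 0; i < n; ++i) {
      const double xi = y[i];
      const double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix sos_filtfilt_cpp(const NumericMatrix& x,
                               const NumericMatrix& b,
                               const NumericMatrix& a,
                               int padlen) {
  const int n = x.nrow(), nc = x.ncol();
  if (padlen > n - 1) padlen = n - 1;
  const int np = n + 2 * padlen;
  NumericMatrix out(n, nc);
  std::vector<double> y(np);
  for (int j = 0; j < nc; ++j) {
    // odd reflection about the first and last samples
    for (int i = 0; i < padlen; ++i)
      y[i] = 2.0 * x(0, j) - x(padlen - i, j);
    for (int i = 0; i < n; ++i)
      y[padlen + i] = x(i, j);
    for (int i = 0; i < padlen; ++i)
      y[padlen + n + i] = 2.0 * x(n - 1, j) - x(n - 2 - i, j);
    run_cascade(y, b, a);
    std::reverse(y.begin(), y.end());
    run_cascade(y, b, a);
    std::reverse(y.begin(), y.end());
    for (int i = 0; i < n; ++i)
      out(i, j) = y[padlen + i];
  }
  return out;
}
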