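#include <Rcpp.h>
using namespace Rcpp;

// Columnwise IIR difference equation (direct form II transposed),
// zero initial state. Used twice (forward/backward) by lowpass_filter().
// [[Rcpp::export(name = ".iir_mat")]]
NumericMatrix iir_mat(NumericVector b, NumericVector a, NumericMatrix x) {
  const int n = x.nrow(), p = x.ncol();
  const int nb = b.size(), na = a.size();
  const int m = std::max(nb, na) - 1;
  std::vector<double> bb(m + 1, 0.0), aa(m + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  const double a0 = aa[0];
  NumericMatrix y(n, p);
  std::vector<double> z(m);
  for (int j = 0; j < p; ++j) {
    std::fill(z.begin(), z.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double xi = x(i, j);
      const double yi = (bb[0] * xi + z[0]) / a0;
      for (int k = 0; k < m - 1; ++k)
        z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
      z[m - 1] = bb[m] * xi - aa[m] * yi;
      y(i, j) = yi;
    }
  }
  return y;
}
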