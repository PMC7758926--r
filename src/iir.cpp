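#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with explicit initial state.
// b, a must be same length with a[0] == 1. zi has length(b) - 1.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  const int n = x.size();
  const int m = b.size() - 1;
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (m > 0 ? z[0] : 0.0);
    for (int j = 0; j < m - 1; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    if (m > 0)
      z[m - 1] = b[m] * xi - a[m] * yi;
    y[i] = yi;
  }
  return y;
}
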