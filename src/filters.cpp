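#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial conditions.
// b and a must have equal length n with a[0] == 1; zi has length n - 1.
// [[Rcpp::export]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  const int n = b.size();
  const int nx = x.size();
  NumericVector y(nx);
  std::vector<double> z(zi.begin(), zi.end());
  for (int i = 0; i < nx; ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + (n > 1 ? z[0] : 0.0);
    for (int j = 0; j < n - 2; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    if (n > 1)
      z[n - 2] = b[n - 1] * xi - a[n - 1] * yi;
    y[i] = yi;
  }
  return y;
}
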