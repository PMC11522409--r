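#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, y = filter(b, a, x) with a[0] = 1.
// [[Rcpp::export]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nw = std::max(nb, na) - 1;
  std::vector<double> bb(nw + 1, 0.0), aa(nw + 1, 0.0), w(nw + 1, 0.0);
  for (int k = 0; k < nb; ++k) bb[k] = b[k];
  for (int k = 0; k < na; ++k) aa[k] = a[k];
  NumericVector y(n);
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int i = 0; i < n; ++i) {
    double xi = xp[i];
    double yi = bb[0] * xi + w[0];
    for (int k = 0; k < nw; ++k)
      w[k] = bb[k + 1] * xi - aa[k + 1] * yi + w[k + 1];
    yp[i] = yi;
  }
  return y;
}
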