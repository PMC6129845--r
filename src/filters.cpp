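#include <Rcpp.h>
using namespace Rcpp;

// IIR filter along the columns of a (series x time) matrix.
// Direct-form I: y[,t] = sum_i b[i] x[,t-i] - sum_j a[j] y[,t-j].
// Coefficients must already be normalized so a[0] == 1.
// When steady_init is true the filter history is initialized as if the
// input had been constant at x[,0] forever (x history = x[,0], y history =
// DC gain * x[,0]), which suppresses start-up transients the way
// steady-state initial conditions do in standard zero-phase filtering.
// [[Rcpp::export]]
NumericMatrix iir_cols_cpp(NumericMatrix x, NumericVector b, NumericVector a,
                           bool steady_init = false) {
  const int p = x.nrow();
  const int n = x.ncol();
  const int nb = b.size();
  const int na = a.size();
  NumericMatrix y(p, n);
  double bsum = 0.0, asum = 0.0;
  for (int i = 0; i < nb; ++i) bsum += b[i];
  for (int j = 0; j < na; ++j) asum += a[j];
  const double gain = (asum != 0.0) ? bsum / asum : 0.0;
  for (int t = 0; t < n; ++t) {
    double* yt = &y(0, t);
    for (int i = 0; i < nb; ++i) {
      const double bi = b[i];
      if (bi == 0.0) continue;
      if (i <= t) {
        const double* xs = &x(0, t - i);
        for (int k = 0; k < p; ++k) yt[k] += bi * xs[k];
      } else if (steady_init) {
        const double* x0 = &x(0, 0);
        for (int k = 0; k < p; ++k) yt[k] += bi * x0[k];
      }
    }
    for (int j = 1; j < na; ++j) {
      const double aj = a[j];
      if (aj == 0.0) continue;
      if (j <= t) {
        const double* ys = &y(0, t - j);
        for (int k = 0; k < p; ++k) yt[k] -= aj * ys[k];
      } else if (steady_init) {
        const double* x0 = &x(0, 0);
        for (int k = 0; k < p; ++k) yt[k] -= aj * gain * x0[k];
      }
    }
  }
  return y;
}
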