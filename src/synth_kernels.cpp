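#include <Rcpp.h>
using namespace Rcpp;

// Sum of first-order recursive lowpass stages applied column-wise:
// y[, j] = sum_s w[s] * filter(x[, j]; pole a[s]).
// [[Rcpp::export]]
NumericMatrix onepole_cascade(const NumericMatrix& x,
                              const NumericVector& poles,
                              const NumericVector& weights) {
  const int n = x.nrow(), k = x.ncol(), ns = poles.size();
  NumericMatrix y(n, k);
  for (int j = 0; j < k; ++j) {
    for (int s = 0; s < ns; ++s) {
      const double a = poles[s], w = weights[s];
      double state = 0.0;
      for (int i = 0; i < n; ++i) {
        state = x(i, j) + a * state;
        y(i, j) += w * state;
      }
    }
  }
  return y;
}

// Linear interpolation of a complex baseband onto the full-rate grid and
// shift onto the band-centre carrier:
// out[t, j] = Re(zi) * ccos[t] - Im(zi) * csin[t],
// zi = z[i0[t], j] * (1 - frac[t]) + z[i0[t] + 1, j] * frac[t].
// i0 is 1-based (from R).
// [[Rcpp::export]]
NumericMatrix band_carrier_interp(const ComplexMatrix& z,
                                  const IntegerVector& i0,
                                  const NumericVector& frac,
                                  const NumericVector& ccos,
                                  const NumericVector& csin) {
  const int n = i0.size(), k = z.ncol();
  NumericMatrix out(n, k);
  for (int j = 0; j < k; ++j) {
    for (int t = 0; t < n; ++t) {
      const int i = i0[t] - 1;
      const double f = frac[t];
      const Rcomplex z0 = z(i, j), z1 = z(i + 1, j);
      const double re = z0.r * (1.0 - f) + z1.r * f;
      const double im = z0.i * (1.0 - f) + z1.i * f;
      out(t, j) = re * ccos[t] - im * csin[t];
    }
  }
  return out;
}
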