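#include <Rcpp.h>
using namespace Rcpp;

// Second-order-section IIR cascade, direct form II transposed.
// sos: n_sections x 6 matrix (b0 b1 b2 a0 a1 a2), a0 must be 1.
// zi:  n_sections x 2 matrix of initial filter states.
// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x, NumericMatrix zi) {
  const int ns = sos.nrow();
  const R_xlen_t n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = zi(s, 0), z2 = zi(s, 1);
    for (R_xlen_t i = 0; i < n; ++i) {
      const double xn = y[i];
      const double yn = b0 * xn + z1;
      z1 = b1 * xn - a1 * yn + z2;
      z2 = b2 * xn - a2 * yn;
      y[i] = yn;
    }
  }
  return y;
}

// Normalized cross-correlation of a template against every fully
// overlapping window of the signal. Lag k (0-based) aligns the template
// start with signal sample k; output has length n - L + 1.
// Windows with (near-)zero variance yield NCC = 0, never NaN.
// [[Rcpp::export]]
NumericVector ncc_cpp(NumericVector s, NumericVector t) {
  const R_xlen_t n = s.size(), L = t.size();
  const R_xlen_t nl = n - L + 1;
  NumericVector out(nl);

  double mu_t = 0.0;
  for (R_xlen_t j = 0; j < L; ++j) mu_t += t[j];
  mu_t /= (double)L;
  double sst = 0.0;
  for (R_xlen_t j = 0; j < L; ++j) {
    const double d = t[j] - mu_t;
    sst += d * d;
  }

  for (R_xlen_t k = 0; k < nl; ++k) {
    double mu_s = 0.0;
    for (R_xlen_t j = 0; j < L; ++j) mu_s += s[k + j];
    mu_s /= (double)L;
    double num = 0.0, sss = 0.0;
    for (R_xlen_t j = 0; j < L; ++j) {
      const double ds = s[k + j] - mu_s;
      num += ds * (t[j] - mu_t);
      sss += ds * ds;
    }
    const double den = std::sqrt(sss * sst);
    out[k] = (den > 0.0 && R_finite(den)) ? num / den : 0.0;
  }
  return out;
}
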