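#include <Rcpp.h>
using namespace Rcpp;

static inline void run_cascade(double* y, R_xlen_t n, int step,
                               const std::vector<double>& b0,
                               const std::vector<double>& b1,
                               const std::vector<double>& b2,
                               const std::vector<double>& a1,
                               const std::vector<double>& a2) {
  const int ns = (int) b0.size();
  std::vector<double> z1(ns, 0.0), z2(ns, 0.0);
  R_xlen_t i = (step > 0) ? 0 : n - 1;
  for (R_xlen_t c = 0; c < n; ++c, i += step) {
    double v = y[i];
    for (int s = 0; s < ns; ++s) {
      double w = b0[s] * v + z1[s];
      z1[s] = b1[s] * v - a1[s] * w + z2[s];
      z2[s] = b2[s] * v - a2[s] * w;
      v = w;
    }
    y[i] = v;
  }
}

// Cascade of second-order sections, direct form II transposed.
// sos: n_sections x 6 matrix, rows (b0, b1, b2, a0, a1, a2) with a0 = 1.
// forward pass only.
// [[Rcpp::export(name = ".sosfilt_c")]]
NumericVector sosfilt_c(NumericMatrix sos, NumericVector x) {
  const int ns = sos.nrow();
  NumericVector y = clone(x);
  std::vector<double> b0(ns), b1(ns), b2(ns), a1(ns), a2(ns);
  for (int s = 0; s < ns; ++s) {
    b0[s] = sos(s, 0); b1[s] = sos(s, 1); b2[s] = sos(s, 2);
    a1[s] = sos(s, 4); a2[s] = sos(s, 5);
  }
  run_cascade(REAL(y), y.size(), +1, b0, b1, b2, a1, a2);
  return y;
}

// forward then backward pass (zero phase), avoiding any reversal copies.
// [[Rcpp::export(name = ".filtfilt_sos_c")]]
NumericVector filtfilt_sos_c(NumericMatrix sos, NumericVector x) {
  const int ns = sos.nrow();
  NumericVector y = clone(x);
  std::vector<double> b0(ns), b1(ns), b2(ns), a1(ns), a2(ns);
  for (int s = 0; s < ns; ++s) {
    b0[s] = sos(s, 0); b1[s] = sos(s, 1); b2[s] = sos(s, 2);
    a1[s] = sos(s, 4); a2[s] = sos(s, 5);
  }
  run_cascade(REAL(y), y.size(), +1, b0, b1, b2, a1, a2);
  run_cascade(REAL(y), y.size(), -1, b0, b1, b2, a1, a2);
  return y;
}
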