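#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Phase lag index for all region pairs of one epoch.
//
// phases: n_regions x n_samples matrix of instantaneous phases (radians).
// PLI(i,j) = | mean_t sign( sin(phi_i(t) - phi_j(t)) ) |, sign(0) = 0.
// Uses sin(a-b) = sin a cos b - cos a sin b so the trig is computed once
// per region rather than once per pair.
// [[Rcpp::export]]
NumericMatrix pli_phase_matrix_cpp(const NumericMatrix& phases) {
  const int n = phases.nrow();
  const int T = phases.ncol();
  if (T < 1) stop("phase series must contain at least one sample");

  std::vector<double> s(static_cast<size_t>(n) * T);
  std::vector<double> c(static_cast<size_t>(n) * T);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < T; ++t) {
      const double ph = phases(i, t);
      s[static_cast<size_t>(i) * T + t] = std::sin(ph);
      c[static_cast<size_t>(i) * T + t] = std::cos(ph);
    }
  }

  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    const double* si = &s[static_cast<size_t>(i) * T];
    const double* ci = &c[static_cast<size_t>(i) * T];
    for (int j = i + 1; j < n; ++j) {
      const double* sj = &s[static_cast<size_t>(j) * T];
      const double* cj = &c[static_cast<size_t>(j) * T];
      long acc = 0;
      for (int t = 0; t < T; ++t) {
        const double v = si[t] * cj[t] - ci[t] * sj[t];
        acc += (v > 0.0) - (v < 0.0);
      }
      const double pli = std::fabs(static_cast<double>(acc)) / T;
      out(i, j) = pli;
      out(j, i) = pli;
    }
  }
  return out;
}
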