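#include <Rcpp.h>
using namespace Rcpp;

// Chebyshev template match: max_l |x[i+l]-x[j+l]| <= r over l = 0..m-1
static inline bool cheb_match(const double* x, int i, int j, int m, double r) {
  for (int l = 0; l < m; ++l) {
    double d = x[i + l] - x[j + l];
    if (d > r || d < -r) return false;
  }
  return true;
}

// Pincus approximate entropy: Phi^m - Phi^{m+1}; self-matches included;
// Phi^m = mean_i ln C_i^m over the n-m+1 templates. Single fused pass:
// pairs matching at length m are extended by one sample for length m+1.
// [[Rcpp::export]]
double cpp_apen(NumericVector x_, int m, double r) {
  const int n = x_.size();
  const double* x = x_.begin();
  const int nt = n - m + 1, nt1 = n - m;
  std::vector<int> cm(nt, 1), c1(nt1, 1);  // self-matches
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      if (cheb_match(x, i, j, m, r)) {
        ++cm[i]; ++cm[j];
        if (j < nt1) {
          double d = x[i + m] - x[j + m];
          if (d <= r && d >= -r) { ++c1[i]; ++c1[j]; }
        }
      }
    }
  }
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nt; ++i) phi_m += std::log((double)cm[i] / nt);
  for (int i = 0; i < nt1; ++i) phi_m1 += std::log((double)c1[i] / nt1);
  return phi_m / nt - phi_m1 / nt1;
}

// Richman-Moorman sample entropy: -ln(A/B); self-matches excluded; both
// lengths use the first n-m templates. Returns NA when A or B is zero.
// [[Rcpp::export]]
double cpp_sampen(NumericVector x_, int m, double r) {
  const int n = x_.size();
  const double* x = x_.begin();
  const int nt = n - m; // templates considered at both lengths
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      if (cheb_match(x, i, j, m, r)) {
        B += 1.0;
        double d = x[i + m] - x[j + m];
        if (d <= r && d >= -r) A += 1.0;
      }
    }
  }
  if (A == 0.0 || B == 0.0) return NA_REAL;
  return -std::log(A / B);
}

// Histogram entropy (bits) of the strict upper triangle of the Gram matrix
// between delay-embedded pieces of the (already centred) series: K
// equal-width bins over the observed range.
// [[Rcpp::export]]
double cpp_sscen(NumericVector x_, int D, int K) {
  const int n = x_.size();
  const double* x = x_.begin();
  const int nw = n - D + 1;
  const long np = (long)nw * (nw - 1) / 2;
  std::vector<double> v(np);
  long idx = 0;
  double lo = R_PosInf, hi = R_NegInf;
  for (int i = 0; i < nw - 1; ++i) {
    for (int j = i + 1; j < nw; ++j) {
      double s = 0.0;
      for (int d = 0; d < D; ++d) s += x[i + d] * x[j + d];
      v[idx++] = s;
      if (s < lo) lo = s;
      if (s > hi) hi = s;
    }
  }
  if (K <= 1 || hi <= lo) return 0.0;
  std::vector<long> counts(K, 0);
  const double w = (hi - lo) / K;
  for (long p = 0; p < np; ++p) {
    int b = (int)((v[p] - lo) / w);
    if (b >= K) b = K - 1;
    if (b < 0) b = 0;
    ++counts[b];
  }
  double H = 0.0;
  for (int b = 0; b < K; ++b) {
    if (counts[b] > 0) {
      double pr = (double)counts[b] / (double)np;
      H -= pr * std::log2(pr);
    }
  }
  return H;
}
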