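#include <Rcpp.h>
using namespace Rcpp;

// Natural cubic spline through knots (t, v), evaluated at integers 0..n-1.
// Knots are strictly increasing; values outside [t0, tK] use the end cubics.
static void spline_eval(const std::vector<double>& t, const std::vector<double>& v,
                        int n, std::vector<double>& out) {
  const int K = t.size();
  if (K == 2) { // straight line
    double slope = (v[1] - v[0]) / (t[1] - t[0]);
    for (int i = 0; i < n; ++i) out[i] = v[0] + slope * (i - t[0]);
    return;
  }
  // second derivatives M by Thomas algorithm, natural BCs M[0] = M[K-1] = 0
  std::vector<double> h(K - 1), a(K), b(K), c(K), d(K), M(K, 0.0);
  for (int i = 0; i < K - 1; ++i) h[i] = t[i + 1] - t[i];
  for (int i = 1; i < K - 1; ++i) {
    a[i] = h[i - 1];
    b[i] = 2.0 * (h[i - 1] + h[i]);
    c[i] = h[i];
    d[i] = 6.0 * ((v[i + 1] - v[i]) / h[i] - (v[i] - v[i - 1]) / h[i - 1]);
  }
  for (int i = 2; i < K - 1; ++i) {
    double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    d[i] -= w * d[i - 1];
  }
  for (int i = K - 2; i >= 1; --i)
    M[i] = (d[i] - (i < K - 2 ? c[i] * M[i + 1] : 0.0)) / b[i];
  // evaluate
  int seg = 0;
  for (int i = 0; i < n; ++i) {
    double x = (double)i;
    while (seg < K - 2 && x > t[seg + 1]) ++seg;
    double hh = h[seg];
    double A = (t[seg + 1] - x) / hh, B = (x - t[seg]) / hh;
    out[i] = A * v[seg] + B * v[seg + 1] +
      ((A * A * A - A) * M[seg] + (B * B * B - B) * M[seg + 1]) * hh * hh / 6.0;
  }
}

// Local extrema of x (strict); returns indices.
static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& imax, std::vector<int>& imin) {
  imax.clear(); imin.clear();
  const int n = x.size();
  for (int i = 1; i < n - 1; ++i) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) imax.push_back(i);
    else if (x[i] < x[i - 1] && x[i] < x[i + 1]) imin.push_back(i);
  }
}

// Mirror the first/last extrema across the series boundaries so envelopes do
// not collapse at the edges (standard boundary treatment for short epochs).
static void extend_knots(const std::vector<int>& idx, const std::vector<double>& val,
                         int n, std::vector<double>& t, std::vector<double>& v) {
  const int p = idx.size();
  t.clear(); v.clear();
  int nref = std::min(2, p);
  for (int j = nref - 1; j >= 0; --j) { // reflect about sample 0
    t.push_back(-(double)idx[j]); v.push_back(val[j]);
  }
  for (int j = 0; j < p; ++j) { t.push_back((double)idx[j]); v.push_back(val[j]); }
  for (int j = p - 1; j >= p - nref; --j) { // reflect about sample n-1
    t.push_back(2.0 * (n - 1) - idx[j]); v.push_back(val[j]);
  }
  // enforce strict increase (duplicates can appear when an extremum sits at 0)
  std::vector<double> t2, v2;
  for (size_t j = 0; j < t.size(); ++j) {
    if (t2.empty() || t[j] > t2.back() + 1e-9) { t2.push_back(t[j]); v2.push_back(v[j]); }
  }
  t.swap(t2); v.swap(v2);
}

// [[Rcpp::export]]
List cpp_emd(NumericVector x_, int max_imfs = 12, int max_sift = 10,
             double sd_tol = 0.2) {
  const int n = x_.size();
  std::vector<double> resid(x_.begin(), x_.end());
  std::vector<std::vector<double> > imfs;
  std::vector<double> h(n), upper(n), lower(n), tmax, vmax, tmin, vmin;
  std::vector<int> imax, imin;

  for (int k = 0; k < max_imfs; ++k) {
    find_extrema(resid, imax, imin);
    if ((int)imax.size() < 2 || (int)imin.size() < 2) break; // residual (quasi-)monotone
    h = resid;
    for (int s = 0; s < max_sift; ++s) {
      find_extrema(h, imax, imin);
      if ((int)imax.size() < 2 || (int)imin.size() < 2) break;
      std::vector<double> vmx(imax.size()), vmn(imin.size());
      for (size_t j = 0; j < imax.size(); ++j) vmx[j] = h[imax[j]];
      for (size_t j = 0; j < imin.size(); ++j) vmn[j] = h[imin[j]];
      extend_knots(imax, vmx, n, tmax, vmax);
      extend_knots(imin, vmn, n, tmin, vmin);
      spline_eval(tmax, vmax, n, upper);
      spline_eval(tmin, vmin, n, lower);
      double num = 0.0, den = 0.0;
      for (int i = 0; i < n; ++i) {
        double m = 0.5 * (upper[i] + lower[i]);
        num += m * m;
        den += h[i] * h[i];
        h[i] -= m;
      }
      if (den > 0 && num / den < sd_tol) break; // Cauchy-type SD stop
    }
    imfs.push_back(h);
    for (int i = 0; i < n; ++i) resid[i] -= h[i];
  }

  NumericMatrix M(n, (int)imfs.size());
  for (size_t k = 0; k < imfs.size(); ++k)
    for (int i = 0; i < n; ++i) M(i, k) = imfs[k][i];
  return List::create(_["imfs"] = M,
                      _["residual"] = NumericVector(resid.begin(), resid.end()));
}
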