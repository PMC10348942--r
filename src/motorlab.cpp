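#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter, single pass.
// zi holds the initial filter state (length max(na, nb) - 1), already
// scaled by the caller (steady-state state times first sample).
// [[Rcpp::export(name = ".iir_df2t")]]
NumericVector iir_df2t(NumericVector b, NumericVector a, NumericVector x,
                       NumericVector zi) {
  const int n = x.size();
  const int nf = std::max(a.size(), b.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0), z(nf, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  for (int i = 0; i < zi.size() && i < nf - 1; ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + z[0];
    for (int j = 1; j < nf - 1; ++j)
      z[j - 1] = bb[j] * xi + z[j] - aa[j] * yi;
    z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}

// Sample entropy match counts: B = template pairs of length m within
// Chebyshev distance r, A = same for length m + 1.  Pairs i < j over the
// n - m templates; self-matches excluded by construction.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of length-(m+1) templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool match_m = true;
      for (int k = 0; k < m; ++k) {
        d = std::fabs(x[i + k] - x[j + k]);
        if (d > r) { match_m = false; break; }
      }
      if (!match_m) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
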