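#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy (Richman & Moorman): -log(A/B) with B the number of
// template pairs (i < j, i,j <= N-m) matching at length m under the
// Chebyshev metric within tolerance r, and A the matches at length m+1.
// Self-matches are excluded by construction (i < j).
// [[Rcpp::export(name = ".sampleEntropyCpp")]]
double sampleEntropyCpp(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;  // number of templates of length m and m+1 (i = 0..nt-1)
  if (nt < 2) return NA_REAL;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) break;
      }
      if (d <= r) {
        B += 1.0;
        double dd = std::fabs(x[i + m] - x[j + m]);
        if (dd <= r && d <= r) A += 1.0;
      }
    }
  }
  if (A <= 0.0 || B <= 0.0) return NA_REAL;
  return -std::log(A / B);
}
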