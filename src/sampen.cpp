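#include <Rcpp.h>
using namespace Rcpp;

// Matching-template pair counts for sample entropy.
//
// Counts pairs (i, j), i < j, of templates of length m and m + 1 whose
// Chebyshev distance is <= r.  Both counts run over the same template start
// positions i = 0 .. n - m - 1 (Richman & Moorman convention), so every
// length-m template has a corresponding length-(m+1) template and
// self-matches are excluded by construction.
//
// [[Rcpp::export]]
List sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int N = n - m;  // number of templates of either length
  double A = 0.0, B = 0.0;
  if (N < 2) return List::create(Named("A") = A, Named("B") = B);
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d = 0.0;
      bool match_m = true;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
        if (d > r) { match_m = false; break; }
      }
      if (!match_m) continue;
      B += 1.0;
      double dm = std::fabs(x[i + m] - x[j + m]);
      if (dm <= r && d <= r) A += 1.0;
    }
  }
  return List::create(Named("A") = A, Named("B") = B);
}
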