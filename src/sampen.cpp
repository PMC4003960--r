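#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman & Moorman counting):
// B = number of ordered-pair-free (i < j) matches of length m, A = matches
// of length m + 1, both over the n - m templates that admit a continuation.
// Chebyshev distance, self-matches excluded, early abort on tolerance.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double tol) {
  const int n = x.size();
  const int N = n - m;  // templates with an (m+1)-th point available
  double A = 0.0, B = 0.0;
  if (N < 2 || m < 1) return NumericVector::create(_["B"] = 0.0, _["A"] = 0.0);
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::abs(x[i + k] - x[j + k]) > tol) { ok = false; break; }
      }
      if (ok) {
        B += 1.0;
        if (std::abs(x[i + m] - x[j + m]) <= tol) A += 1.0;
      }
    }
  }
  return NumericVector::create(_["B"] = B, _["A"] = A);
}
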