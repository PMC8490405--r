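#include <Rcpp.h>
using namespace Rcpp;

// Number of neighbours of each sequence at >= theta identity (including
// itself). Identity is plain Hamming identity over all L columns; the gap
// is an ordinary 21st symbol. O(M^2 L) but trivially cheap per comparison,
// and the inner loop bails out early once a pair can no longer reach the
// threshold.
// [[Rcpp::export]]
IntegerVector neighbor_counts(const IntegerMatrix &codes, double theta) {
  const int M = codes.nrow();
  const int L = codes.ncol();
  // matches >= theta * L  (exact threshold, guard against FP noise)
  const int need = (int)std::ceil(theta * L - 1e-9);
  IntegerVector counts(M, 1); // each sequence is its own neighbour
  for (int m1 = 0; m1 < M; ++m1) {
    for (int m2 = m1 + 1; m2 < M; ++m2) {
      int matches = 0;
      int remaining = L;
      for (int j = 0; j < L; ++j, --remaining) {
        if (codes(m1, j) == codes(m2, j)) ++matches;
        if (matches + remaining - 1 < need) break;
      }
      if (matches >= need) {
        ++counts[m1];
        ++counts[m2];
      }
    }
  }
  return counts;
}
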