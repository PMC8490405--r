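#include <Rcpp.h>
using namespace Rcpp;

// Weighted indicator means for a set of (i, j, k, a, b, c) tuples:
// returns a 7-column matrix with f_i(a), f_j(b), f_k(c), f_ij(a,b),
// f_ik(a,c), f_jk(b,c), f_ijk(a,b,c). Sites and codes are 0-based.
// [[Rcpp::export]]
NumericMatrix triplet_freqs(const IntegerMatrix &codes,
                            const NumericVector &w,
                            const IntegerMatrix &tuples) {
  const int M = codes.nrow();
  const int T = tuples.nrow();
  double wsum = 0.0;
  for (int m = 0; m < M; ++m) wsum += w[m];
  NumericMatrix out(T, 7);
  for (int t = 0; t < T; ++t) {
    const int i = tuples(t, 0), j = tuples(t, 1), k = tuples(t, 2);
    const int a = tuples(t, 3), b = tuples(t, 4), c = tuples(t, 5);
    double fi = 0, fj = 0, fk = 0, fij = 0, fik = 0, fjk = 0, fijk = 0;
    for (int m = 0; m < M; ++m) {
      const bool ia = codes(m, i) == a;
      const bool jb = codes(m, j) == b;
      const bool kc = codes(m, k) == c;
      if (!(ia || jb || kc)) continue;
      const double wm = w[m];
      if (ia) fi += wm;
      if (jb) fj += wm;
      if (kc) fk += wm;
      if (ia && jb) fij += wm;
      if (ia && kc) fik += wm;
      if (jb && kc) fjk += wm;
      if (ia && jb && kc) fijk += wm;
    }
    out(t, 0) = fi / wsum;
    out(t, 1) = fj / wsum;
    out(t, 2) = fk / wsum;
    out(t, 3) = fij / wsum;
    out(t, 4) = fik / wsum;
    out(t, 5) = fjk / wsum;
    out(t, 6) = fijk / wsum;
  }
  return out;
}
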