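#include <Rcpp.h>
using namespace Rcpp;

// Marginal-preserving rectangle shuffle.
//
// Repeatedly proposes (row a, row b, col i, col j) uniformly at random and
// applies the 2x2 swap when m[a,i]==m[b,j], m[a,j]==m[b,i] and
// m[a,i]!=m[a,j]; such a swap exchanges the crossed values within the two
// rows and leaves every row sum and every column sum unchanged.  Invalid
// proposals are resampled and do not count toward n_swaps.  Uses R's RNG,
// so results are reproducible under set.seed().
//
// [[Rcpp::export]]
IntegerMatrix cpp_rect_shuffle(IntegerMatrix m, double n_swaps,
                               double max_consecutive_fail) {
  IntegerMatrix x = clone(m);
  int N = x.nrow(), M = x.ncol();
  if (N < 2 || M < 2)
    stop("rectangle shuffle needs at least 2 rows and 2 columns");
  double accepted = 0.0, fails = 0.0;
  while (accepted < n_swaps) {
    int a = (int)(unif_rand() * N); if (a == N) a = N - 1;
    int b = (int)(unif_rand() * (N - 1)); if (b >= a) b++;
    int i = (int)(unif_rand() * M); if (i == M) i = M - 1;
    int j = (int)(unif_rand() * (M - 1)); if (j >= i) j++;
    int ai = x(a, i), aj = x(a, j);
    if (ai != aj && ai == x(b, j) && aj == x(b, i)) {
      x(a, i) = aj; x(a, j) = ai;
      x(b, i) = ai; x(b, j) = aj;
      accepted += 1.0;
      fails = 0.0;
    } else {
      fails += 1.0;
      if (fails > max_consecutive_fail)
        stop("degenerate matrix: no valid rectangle swap found in %.0f attempts",
             max_consecutive_fail);
    }
  }
  return x;
}
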