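#include <Rcpp.h>
using namespace Rcpp;

// Rolling range (max - min) over a trailing window of w samples, per
// column. The window is truncated at the start of the series. w is small
// (a fraction of a second of samples), so the direct O(n*w) scan is fast
// and branch-predictable.
// [[Rcpp::export]]
NumericMatrix rolling_range_cpp(const NumericMatrix& x, const int w) {
  const int n = x.nrow(), k = x.ncol();
  NumericMatrix out(n, k);
  for (int j = 0; j < k; ++j) {
    const double* col = &x(0, j);
    for (int i = 0; i < n; ++i) {
      const int lo = i - w + 1 > 0 ? i - w + 1 : 0;
      double mx = col[lo], mn = col[lo];
      for (int t = lo + 1; t <= i; ++t) {
        const double v = col[t];
        if (v > mx) mx = v;
        if (v < mn) mn = v;
      }
      out(i, j) = mx - mn;
    }
  }
  return out;
}
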