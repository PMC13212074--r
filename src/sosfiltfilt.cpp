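#include <Rcpp.h>
using namespace Rcpp;

// Zero-phase (forward-backward) IIR filtering in cascaded second-order
// sections, columnwise over a matrix. The input is extended by odd
// reflection at both ends (npad samples) and each section starts from
// its steady-state step-response state scaled by the first sample, which
// suppresses start-up transients (the scipy filtfilt convention).
//
// sos: k x 6 matrix, rows (b0, b1, b2, 1, a1, a2)
// zi:  k x 2 matrix of unit step-response initial states per section
// [[Rcpp::export]]
NumericMatrix sosfiltfilt_cpp(const NumericMatrix& x, const NumericMatrix& sos,
                              const NumericMatrix& zi, const int npad) {
  const int n = x.nrow(), ncol = x.ncol(), ns = sos.nrow();
  const int m = n + 2 * npad;
  std::vector<double> buf(m);
  NumericMatrix out(n, ncol);

  for (int j = 0; j < ncol; ++j) {
    // odd reflection padding
    for (int i = 0; i < npad; ++i)
      buf[i] = 2.0 * x(0, j) - x(npad - i, j);
    for (int i = 0; i < n; ++i) buf[npad + i] = x(i, j);
    for (int i = 0; i < npad; ++i)
      buf[npad + n + i] = 2.0 * x(n - 1, j) - x(n - 2 - i, j);

    for (int pass = 0; pass < 2; ++pass) {
      for (int s = 0; s < ns; ++s) {
        const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
        const double a1 = sos(s, 4), a2 = sos(s, 5);
        double z1 = zi(s, 0) * buf[0], z2 = zi(s, 1) * buf[0];
        for (int t = 0; t < m; ++t) {
          const double xt = buf[t];
          const double yt = b0 * xt + z1;
          z1 = b1 * xt + z2 - a1 * yt;
          z2 = b2 * xt - a2 * yt;
          buf[t] = yt;
        }
      }
      std::reverse(buf.begin(), buf.end());
    }
    for (int i = 0; i < n; ++i) out(i, j) = buf[npad + i];
  }
  return out;
}
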