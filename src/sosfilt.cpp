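#include <Rcpp.h>
using namespace Rcpp;

// Cascade of biquad sections applied to every column of x (time along rows),
// direct form II transposed, zero initial state.  sos rows: b0 b1 b2 a0 a1 a2
// with a0 == 1.
// [[Rcpp::export(name = ".sosfilt_cpp")]]
NumericMatrix sosfilt_cpp(NumericMatrix sos, NumericMatrix x) {
  const int nt = x.nrow(), nc = x.ncol(), ns = sos.nrow();
  NumericMatrix y = clone(x);
  double *Y = REAL(y);
  for (int s = 0; s < ns; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    for (int c = 0; c < nc; ++c) {
      double *col = Y + (size_t)c * nt;
      double z1 = 0.0, z2 = 0.0;
      for (int t = 0; t < nt; ++t) {
        const double xt = col[t];
        const double yt = b0 * xt + z1;
        z1 = b1 * xt + z2 - a1 * yt;
        z2 = b2 * xt - a2 * yt;
        col[t] = yt;
      }
    }
  }
  return y;
}
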