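#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// One forward pass of a cascaded biquad over a contiguous buffer.
// z1/z2 must hold the (already input-scaled) initial state per section.
static inline void sos_pass(double* x, int n, const double* b0,
                            const double* b1, const double* b2,
                            const double* a1, const double* a2, int K,
                            double* z1, double* z2) {
  for (int k = 0; k < K; ++k) {
    const double bk0 = b0[k], bk1 = b1[k], bk2 = b2[k];
    const double ak1 = a1[k], ak2 = a2[k];
    double s1 = z1[k], s2 = z2[k];
    for (int i = 0; i < n; ++i) {
      const double v = x[i];
      const double w = bk0 * v + s1;
      s1 = bk1 * v - ak1 * w + s2;
      s2 = bk2 * v - ak2 * w;
      x[i] = w;
    }
  }
}

// Zero-phase forward-backward second-order-section filtering along the
// rows of x (time down the rows, columns independent), with odd-reflection
// end padding of `padlen` samples and steady-state initial conditions
// (zi, K x 2, per unit input) scaled by the first padded sample.
// [[Rcpp::export]]
NumericMatrix sosfiltfilt_cpp(NumericMatrix x, NumericMatrix sos,
                              NumericMatrix zi, int padlen) {
  const int n = x.nrow(), m = x.ncol(), K = sos.nrow();
  if (padlen > n - 1) padlen = n - 1;
  NumericMatrix y(n, m);
  std::vector<double> b0(K), b1(K), b2(K), a1(K), a2(K), zc1(K), zc2(K);
  for (int k = 0; k < K; ++k) {
    b0[k] = sos(k, 0); b1[k] = sos(k, 1); b2[k] = sos(k, 2);
    a1[k] = sos(k, 4); a2[k] = sos(k, 5);
  }
  const int ext = n + 2 * padlen;
  std::vector<double> buf(ext);
  std::vector<double> z1(K), z2(K);
  for (int j = 0; j < m; ++j) {
    const double* xc = &x(0, j);
    // odd reflection about the end points
    for (int i = 0; i < padlen; ++i)
      buf[i] = 2.0 * xc[0] - xc[padlen - i];
    for (int i = 0; i < n; ++i) buf[padlen + i] = xc[i];
    for (int i = 0; i < padlen; ++i)
      buf[padlen + n + i] = 2.0 * xc[n - 1] - xc[n - 2 - i];
    // forward
    for (int k = 0; k < K; ++k) {
      z1[k] = zi(k, 0) * buf[0];
      z2[k] = zi(k, 1) * buf[0];
    }
    sos_pass(buf.data(), ext, b0.data(), b1.data(), b2.data(),
             a1.data(), a2.data(), K, z1.data(), z2.data());
    // backward
    std::reverse(buf.begin(), buf.end());
    for (int k = 0; k < K; ++k) {
      z1[k] = zi(k, 0) * buf[0];
      z2[k] = zi(k, 1) * buf[0];
    }
    sos_pass(buf.data(), ext, b0.data(), b1.data(), b2.data(),
             a1.data(), a2.data(), K, z1.data(), z2.data());
    double* yc = &y(0, j);
    for (int i = 0; i < n; ++i) yc[i] = buf[ext - 1 - padlen - i];
  }
  return y;
}
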