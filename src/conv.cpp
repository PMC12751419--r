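#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Patch extraction for 1-D convolution over [N, T, C] feature arrays
// (column-major, sample index fastest). Output rows are ordered (n, t_out)
// with n fastest; columns are ordered (tap j, channel c) with c fastest,
// matching the kernel matrix layout (k*C_in) x C_out.

// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(NumericVector X, int N, int T, int C,
                         int k, int stride, int pad, int dil) {
  const int To = (T + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  NumericMatrix M(N * To, k * C);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < C; ++c) {
      const int col = j * C + c;
      double *dst = &M(0, col);
      if (stride == 1) {
        // source block is contiguous across (n, t): one copy per column
        const int t0 = j * dil - pad;
        const int lo = t0 < 0 ? -t0 : 0;          // first valid to
        const int hi = std::min(To, T - t0);      // one past last valid to
        if (hi > lo)
          std::memcpy(dst + (size_t)N * lo,
                      &X[(size_t)N * (t0 + lo + (size_t)T * c)],
                      (size_t)N * (hi - lo) * sizeof(double));
      } else {
        for (int to = 0; to < To; ++to) {
          const int t = to * stride + j * dil - pad;
          if (t < 0 || t >= T) continue;
          std::memcpy(dst + (size_t)N * to,
                      &X[(size_t)N * (t + (size_t)T * c)],
                      N * sizeof(double));
        }
      }
    }
  return M;
}

// Adjoint of im2col: scatter-add patch gradients back onto the input grid.

// [[Rcpp::export(name = ".col2im_cpp")]]
NumericVector col2im_cpp(NumericMatrix dM, int N, int T, int C,
                         int k, int stride, int pad, int dil) {
  const int To = (T + 2 * pad - dil * (k - 1) - 1) / stride + 1;
  NumericVector dX((size_t)N * T * C);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < C; ++c) {
      const int col = j * C + c;
      const double *src = &dM(0, col);
      if (stride == 1) {
        const int t0 = j * dil - pad;
        const int lo = t0 < 0 ? -t0 : 0;
        const int hi = std::min(To, T - t0);
        if (hi > lo) {
          double *dst = &dX[(size_t)N * (t0 + lo + (size_t)T * c)];
          const double *s2 = src + (size_t)N * lo;
          const size_t len = (size_t)N * (hi - lo);
          for (size_t i = 0; i < len; ++i) dst[i] += s2[i];
        }
      } else {
        for (int to = 0; to < To; ++to) {
          const int t = to * stride + j * dil - pad;
          if (t < 0 || t >= T) continue;
          double *dst = &dX[(size_t)N * (t + (size_t)T * c)];
          const double *s2 = src + (size_t)N * to;
          for (int n = 0; n < N; ++n) dst[n] += s2[n];
        }
      }
    }
  dX.attr("dim") = IntegerVector::create(N, T, C);
  return dX;
}

// column-broadcast helpers: out[n, c] = m[n, c] op v[c % len(v)] where v has
// one entry per feature column (avoids materializing rep(v, each = N) in R)

// [[Rcpp::export(name = ".coladd_cpp")]]
NumericMatrix coladd_cpp(NumericMatrix m, NumericVector v) {
  const int N = m.nrow(), C = m.ncol();
  NumericMatrix out(N, C);
  for (int c = 0; c < C; ++c) {
    const double x = v[c % v.size()];
    const double *src = &m(0, c);
    double *dst = &out(0, c);
    for (int n = 0; n < N; ++n) dst[n] = src[n] + x;
  }
  return out;
}

// [[Rcpp::export(name = ".colmul_cpp")]]
NumericMatrix colmul_cpp(NumericMatrix m, NumericVector v) {
  const int N = m.nrow(), C = m.ncol();
  NumericMatrix out(N, C);
  for (int c = 0; c < C; ++c) {
    const double x = v[c % v.size()];
    const double *src = &m(0, c);
    double *dst = &out(0, c);
    for (int n = 0; n < N; ++n) dst[n] = src[n] * x;
  }
  return out;
}
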