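// im2col / col2im for 1-D same-padded (optionally dilated) convolution on
// (batch N, time L, channel C) arrays stored column-major. These two hot
// loops are the only compiled code; all matrix products stay on the BLAS.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col1d(NumericVector x, int N, int L, int C, int k, int dilation) {
  int pad = (k - 1) / 2 * dilation;
  NumericMatrix out((R_xlen_t)N * L, (R_xlen_t)k * C);
  for (int j = 0; j < k; ++j) {
    int off = j * dilation - pad;
    for (int c = 0; c < C; ++c) {
      double* dst = &out(0, (R_xlen_t)j * C + c);
      for (int t = 0; t < L; ++t) {
        int ts = t + off;
        double* drow = dst + (R_xlen_t)t * N;
        if (ts < 0 || ts >= L) {
          std::fill(drow, drow + N, 0.0);
        } else {
          const double* src = &x[(R_xlen_t)N * (ts + (R_xlen_t)L * c)];
          std::copy(src, src + N, drow);
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im1d(NumericMatrix dXcol, int N, int L, int C, int k, int dilation) {
  int pad = (k - 1) / 2 * dilation;
  NumericVector dx((R_xlen_t)N * L * C);
  for (int j = 0; j < k; ++j) {
    int off = j * dilation - pad;
    for (int c = 0; c < C; ++c) {
      const double* srccol = &dXcol(0, (R_xlen_t)j * C + c);
      for (int t = 0; t < L; ++t) {
        int ts = t + off;
        if (ts < 0 || ts >= L) continue;
        double* dst = &dx[(R_xlen_t)N * (ts + (R_xlen_t)L * c)];
        const double* src = srccol + (R_xlen_t)t * N;
        for (int n = 0; n < N; ++n) dst[n] += src[n];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(N, L, C);
  return dx;
}
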