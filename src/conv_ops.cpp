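// Hot kernels of the convolution engine: patch unfolding (im2col) and its
// adjoint scatter-add (col2im). Tensors are channels-last R arrays with
// dimension (height, width, batch, channel); the unfolded matrix has one
// row per output pixel per batch element and k*k blocks of C columns, in
// (dh, dw) offset order — the same layout the R code used, so the matrix
// products on either side are unchanged.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix im2col_cpp(const NumericVector& xp, int k, int stride,
                         int ho, int wo) {
  IntegerVector d = xp.attr("dim");
  const int Hp = d[0], Wp = d[1], N = d[2], C = d[3];
  const int rows = ho * wo * N;
  NumericMatrix M(rows, k * k * C);
  const double* X = xp.begin();
  double* Mp = M.begin();
  int q = 0;
  for (int dh = 0; dh < k; ++dh) {
    for (int dw = 0; dw < k; ++dw, ++q) {
      for (int c = 0; c < C; ++c) {
        double* col = Mp + (ptrdiff_t)(q * C + c) * rows;
        for (int n = 0; n < N; ++n) {
          const double* base = X + ((ptrdiff_t)c * N + n) * Hp * Wp;
          for (int w = 0; w < wo; ++w) {
            const double* src = base + (ptrdiff_t)(dw + w * stride) * Hp + dh;
            double* dst = col + (ptrdiff_t)n * ho * wo + (ptrdiff_t)w * ho;
            for (int h = 0; h < ho; ++h) {
              dst[h] = src[(ptrdiff_t)h * stride];
            }
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(const NumericMatrix& dM, int k, int stride,
                         int ho, int wo, IntegerVector dpad) {
  const int Hp = dpad[0], Wp = dpad[1], N = dpad[2], C = dpad[3];
  const int rows = ho * wo * N;
  NumericVector dxp((ptrdiff_t)Hp * Wp * N * C);
  dxp.attr("dim") = dpad;
  double* X = dxp.begin();
  const double* Mp = dM.begin();
  int q = 0;
  for (int dh = 0; dh < k; ++dh) {
    for (int dw = 0; dw < k; ++dw, ++q) {
      for (int c = 0; c < C; ++c) {
        const double* col = Mp + (ptrdiff_t)(q * C + c) * rows;
        for (int n = 0; n < N; ++n) {
          double* base = X + ((ptrdiff_t)c * N + n) * Hp * Wp;
          for (int w = 0; w < wo; ++w) {
            double* dst = base + (ptrdiff_t)(dw + w * stride) * Hp + dh;
            const double* src = col + (ptrdiff_t)n * ho * wo +
              (ptrdiff_t)w * ho;
            for (int h = 0; h < ho; ++h) {
              dst[(ptrdiff_t)h * stride] += src[h];
            }
          }
        }
      }
    }
  }
  return dxp;
}
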