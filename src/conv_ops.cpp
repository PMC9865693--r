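#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as R arrays with dim (C, H, W), channel fastest.
// im2col unrolls every kernel window into one column so a convolution
// becomes a single (C_out x C*kh*kw) %*% (C*kh*kw x Ho*Wo) matrix product.
// Row order within a column is c fastest, then kernel row, then kernel col;
// column order is output row fastest (matches an R (Ho, Wo) array).

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int C, int H, int W,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericMatrix out(C * kh * kw, Ho * Wo);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = wo * Ho + ho;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      double* colp = op + (R_xlen_t)col * (C * kh * kw);
      int r = 0;
      for (int j = 0; j < kw; ++j) {
        const int w = w0 + j;
        for (int i = 0; i < kh; ++i) {
          const int h = h0 + i;
          if (h >= 0 && h < H && w >= 0 && w < W) {
            const double* src = xp + ((R_xlen_t)w * H + h) * C;
            for (int c = 0; c < C; ++c) colp[r++] = src[c];
          } else {
            for (int c = 0; c < C; ++c) colp[r++] = 0.0;
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-adds column gradients back onto the
// (C, H, W) input layout.

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int C, int H, int W,
                         int kh, int kw, int stride, int pad) {
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  NumericVector x((R_xlen_t)C * H * W);
  double* xp = x.begin();
  const double* cp = cols.begin();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int col = wo * Ho + ho;
      const int h0 = ho * stride - pad;
      const int w0 = wo * stride - pad;
      const double* colp = cp + (R_xlen_t)col * (C * kh * kw);
      int r = 0;
      for (int j = 0; j < kw; ++j) {
        const int w = w0 + j;
        for (int i = 0; i < kh; ++i) {
          const int h = h0 + i;
          if (h >= 0 && h < H && w >= 0 && w < W) {
            double* dst = xp + ((R_xlen_t)w * H + h) * C;
            for (int c = 0; c < C; ++c) dst[c] += colp[r++];
          } else {
            r += C;
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(C, H, W);
  return x;
}
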