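#include <Rcpp.h>
using namespace Rcpp;

// im2col for a 3x3, stride-1, zero-pad-1 convolution. Input x is an
// [H, W, C] array; output is an (H*W) x (9*C) matrix whose row r = i + H*j
// corresponds to output pixel (i, j) and whose column (ky + 3*kx + 9*c)
// holds x[i + ky - 1, j + kx - 1, c] (zero outside the image). This layout
// matches matrix(W[3, 3, C, K], 9*C, K) on the weight side.

// [[Rcpp::export(name = ".im2col3_cpp")]]
NumericMatrix im2col3_cpp(NumericVector x, int h, int w, int c) {
  NumericMatrix out(h * w, 9 * c);
  const double *px = x.begin();
  for (int ch = 0; ch < c; ++ch) {
    const double *plane = px + (R_xlen_t)h * w * ch;
    for (int kx = 0; kx < 3; ++kx) {
      for (int ky = 0; ky < 3; ++ky) {
        double *col = &out(0, ky + 3 * kx + 9 * ch);
        const int di = ky - 1, dj = kx - 1;
        for (int j = 0; j < w; ++j) {
          const int sj = j + dj;
          double *dst = col + (R_xlen_t)h * j;
          if (sj < 0 || sj >= w) continue;  // stays zero
          const double *srcc = plane + (R_xlen_t)h * sj;
          const int i0 = di < 0 ? 1 : 0;
          const int i1 = di > 0 ? h - 1 : h;
          for (int i = i0; i < i1; ++i) dst[i] = srcc[i + di];
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add column gradients back to the image grid.

// [[Rcpp::export(name = ".col2im3_cpp")]]
NumericVector col2im3_cpp(NumericMatrix dcols, int h, int w, int c) {
  NumericVector dx((R_xlen_t)h * w * c);
  double *pdx = dx.begin();
  for (int ch = 0; ch < c; ++ch) {
    double *plane = pdx + (R_xlen_t)h * w * ch;
    for (int kx = 0; kx < 3; ++kx) {
      for (int ky = 0; ky < 3; ++ky) {
        const double *col = &dcols(0, ky + 3 * kx + 9 * ch);
        const int di = ky - 1, dj = kx - 1;
        for (int j = 0; j < w; ++j) {
          const int sj = j + dj;
          if (sj < 0 || sj >= w) continue;
          const double *src = col + (R_xlen_t)h * j;
          double *dst = plane + (R_xlen_t)h * sj;
          const int i0 = di < 0 ? 1 : 0;
          const int i1 = di > 0 ? h - 1 : h;
          for (int i = i0; i < i1; ++i) dst[i + di] += src[i];
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(h, w, c);
  return dx;
}
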