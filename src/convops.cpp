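#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Feature maps are passed as (H*W*B) x C matrices, row index
// r = h + H*w + H*W*b (column-major within each image, images stacked),
// so consecutive conv layers chain without array permutations.
// These two kernels only gather/scatter patches; the actual convolution
// is a BLAS matrix product on the R side.

// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(NumericMatrix x, int H, int W, int B,
                         int kh, int kw, int stride, int pad) {
  const int C = x.ncol();
  const int OH = (H + 2 * pad - kh) / stride + 1;
  const int OW = (W + 2 * pad - kw) / stride + 1;
  const int P = OH * OW;
  NumericMatrix out(P * B, kh * kw * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        double* oc = &out(0, col);
        for (int b = 0; b < B; ++b) {
          const double* xb = xc + (R_xlen_t)H * W * b;
          double* ob = oc + (R_xlen_t)P * b;
          for (int ow = 0; ow < OW; ++ow) {
            const int w = ow * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            const double* xw = xb + (R_xlen_t)H * w;
            double* op = ob + (R_xlen_t)OH * ow;
            for (int oh = 0; oh < OH; ++oh) {
              const int h = oh * stride - pad + ki;
              if (h < 0 || h >= H) continue;
              op[oh] = xw[h];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add columns back into an (H*W*B) x C map.
// [[Rcpp::export(name = ".col2im_cpp")]]
NumericMatrix col2im_cpp(NumericMatrix cols, int H, int W, int B,
                         int kh, int kw, int stride, int pad) {
  const int C = cols.ncol() / (kh * kw);
  const int OH = (H + 2 * pad - kh) / stride + 1;
  const int OW = (W + 2 * pad - kw) / stride + 1;
  const int P = OH * OW;
  NumericMatrix out((R_xlen_t)H * W * B, C);
  for (int c = 0; c < C; ++c) {
    double* xc = &out(0, c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        const double* oc = &cols(0, col);
        for (int b = 0; b < B; ++b) {
          double* xb = xc + (R_xlen_t)H * W * b;
          const double* ob = oc + (R_xlen_t)P * b;
          for (int ow = 0; ow < OW; ++ow) {
            const int w = ow * stride - pad + kj;
            if (w < 0 || w >= W) continue;
            double* xw = xb + (R_xlen_t)H * w;
            const double* op = ob + (R_xlen_t)OH * ow;
            for (int oh = 0; oh < OH; ++oh) {
              const int h = oh * stride - pad + ki;
              if (h < 0 || h >= H) continue;
              xw[h] += op[oh];
            }
          }
        }
      }
    }
  }
  return out;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Non-local means on one channel (H x W, column-major vector).
// Each output pixel is the weight-normalised average over the search
// window; weights exp(-max(d2 - 2*sigma^2, 0)/h2) from the mean squared
// patch difference d2. Patch coordinates are clamped at the borders.
// [[Rcpp::export(name = ".nlm_channel_cpp")]]
NumericVector nlm_channel_cpp(NumericVector x, int H, int W,
                              int patch_radius, int search_radius,
                              double hpar, double sigma) {
  NumericVector out((R_xlen_t)H * W);
  const double h2 = hpar * hpar;
  const double s2 = 2.0 * sigma * sigma;
  const int pr = patch_radius, sr = search_radius;
  const int np = (2 * pr + 1) * (2 * pr + 1);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      double wsum = 0.0, vsum = 0.0;
      for (int dw = -sr; dw <= sr; ++dw) {
        const int w2 = w + dw;
        if (w2 < 0 || w2 >= W) continue;
        for (int dh = -sr; dh <= sr; ++dh) {
          const int h2i = h + dh;
          if (h2i < 0 || h2i >= H) continue;
          double d2 = 0.0;
          for (int pw = -pr; pw <= pr; ++pw) {
            const int a1 = clampi(w + pw, 0, W - 1);
            const int a2 = clampi(w2 + pw, 0, W - 1);
            for (int ph = -pr; ph <= pr; ++ph) {
              const int b1 = clampi(h + ph, 0, H - 1);
              const int b2 = clampi(h2i + ph, 0, H - 1);
              const double diff = x[b1 + (R_xlen_t)H * a1] -
                                  x[b2 + (R_xlen_t)H * a2];
              d2 += diff * diff;
            }
          }
          d2 /= np;
          double excess = d2 - s2;
          if (excess < 0.0) excess = 0.0;
          const double wt = h2 > 0.0 ? std::exp(-excess / h2)
                                     : (excess == 0.0 ? 1.0 : 0.0);
          wsum += wt;
          vsum += wt * x[h2i + (R_xlen_t)H * w2];
        }
      }
      out[h + (R_xlen_t)H * w] = wsum > 0.0 ? vsum / wsum
                                            : x[h + (R_xlen_t)H * w];
    }
  }
  return out;
}
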