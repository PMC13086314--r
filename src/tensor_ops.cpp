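#include <Rcpp.h>
using namespace Rcpp;

// Tensors use the (B, C, H, W) dimension convention throughout the package;
// R stores arrays column-major, so the batch index varies fastest.

static inline R_xlen_t idx4(int b, int c, int h, int w,
                            int B, int C, int H) {
  return (R_xlen_t)b + (R_xlen_t)B * (c + (R_xlen_t)C * (h + (R_xlen_t)H * w));
}

// Unfold sliding kh x kw patches of a zero-padded (B, C, H, W) array into a
// (C*kh*kw) x (B*OH*OW) matrix, ready for a single GEMM against the
// (Cout) x (C*kh*kw) weight matrix. Column index runs batch-fastest, then
// output row, then output column.
// [[Rcpp::export(name = ".im2col_nchw")]]
NumericMatrix im2col_nchw(NumericVector x, IntegerVector dims,
                          int kh, int kw, int sh, int sw, int ph, int pw) {
  int B = dims[0], C = dims[1], H = dims[2], W = dims[3];
  int OH = (H + 2 * ph - kh) / sh + 1;
  int OW = (W + 2 * pw - kw) / sw + 1;
  NumericMatrix cols(C * kh * kw, B * OH * OW);
  double *pc = cols.begin();
  const double *px = x.begin();
  int nrow = C * kh * kw;
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      for (int b = 0; b < B; ++b) {
        R_xlen_t col = (R_xlen_t)b + (R_xlen_t)B * (oh + (R_xlen_t)OH * ow);
        double *dst = pc + col * nrow;
        for (int kwi = 0; kwi < kw; ++kwi) {
          int w = ow * sw - pw + kwi;
          for (int khi = 0; khi < kh; ++khi) {
            int h = oh * sh - ph + khi;
            for (int c = 0; c < C; ++c) {
              double v = 0.0;
              if (h >= 0 && h < H && w >= 0 && w < W)
                v = px[idx4(b, c, h, w, B, C, H)];
              dst[c + C * (khi + kh * kwi)] = v;
            }
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add patch-matrix gradients back onto the
// (B, C, H, W) input gradient.
// [[Rcpp::export(name = ".col2im_nchw")]]
NumericVector col2im_nchw(NumericMatrix cols, IntegerVector dims,
                          int kh, int kw, int sh, int sw, int ph, int pw) {
  int B = dims[0], C = dims[1], H = dims[2], W = dims[3];
  int OH = (H + 2 * ph - kh) / sh + 1;
  int OW = (W + 2 * pw - kw) / sw + 1;
  NumericVector dx((R_xlen_t)B * C * H * W);
  double *pdx = dx.begin();
  const double *pc = cols.begin();
  int nrow = C * kh * kw;
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      for (int b = 0; b < B; ++b) {
        R_xlen_t col = (R_xlen_t)b + (R_xlen_t)B * (oh + (R_xlen_t)OH * ow);
        const double *src = pc + col * nrow;
        for (int kwi = 0; kwi < kw; ++kwi) {
          int w = ow * sw - pw + kwi;
          if (w < 0 || w >= W) continue;
          for (int khi = 0; khi < kh; ++khi) {
            int h = oh * sh - ph + khi;
            if (h < 0 || h >= H) continue;
            for (int c = 0; c < C; ++c)
              pdx[idx4(b, c, h, w, B, C, H)] += src[c + C * (khi + kh * kwi)];
          }
        }
      }
    }
  }
  dx.attr("dim") = dims;
  return dx;
}

// Max pooling over kh x kw windows with stride and zero-ignoring padding
// (padded cells are treated as -Inf). Returns the pooled map and the 1-based
// flat argmax index into the input, for the backward scatter.
// [[Rcpp::export(name = ".maxpool_nchw")]]
List maxpool_nchw(NumericVector x, IntegerVector dims,
                  int kh, int kw, int sh, int sw, int ph, int pw) {
  int B = dims[0], C = dims[1], H = dims[2], W = dims[3];
  int OH = (H + 2 * ph - kh) / sh + 1;
  int OW = (W + 2 * pw - kw) / sw + 1;
  NumericVector out((R_xlen_t)B * C * OH * OW);
  IntegerVector arg((R_xlen_t)B * C * OH * OW);
  const double *px = x.begin();
  for (int ow = 0; ow < OW; ++ow)
    for (int oh = 0; oh < OH; ++oh)
      for (int c = 0; c < C; ++c)
        for (int b = 0; b < B; ++b) {
          double best = R_NegInf;
          R_xlen_t besti = -1;
          for (int kwi = 0; kwi < kw; ++kwi) {
            int w = ow * sw - pw + kwi;
            if (w < 0 || w >= W) continue;
            for (int khi = 0; khi < kh; ++khi) {
              int h = oh * sh - ph + khi;
              if (h < 0 || h >= H) continue;
              R_xlen_t ii = idx4(b, c, h, w, B, C, H);
              if (px[ii] > best) { best = px[ii]; besti = ii; }
            }
          }
          R_xlen_t oo = (R_xlen_t)b + (R_xlen_t)B * (c + (R_xlen_t)C * (oh + (R_xlen_t)OH * ow));
          out[oo] = best;
          arg[oo] = (int)(besti + 1);
        }
  out.attr("dim") = IntegerVector::create(B, C, OH, OW);
  return List::create(_["value"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool_backward_nchw")]]
NumericVector maxpool_backward_nchw(NumericVector dout, IntegerVector argmax,
                                    IntegerVector dims) {
  NumericVector dx((R_xlen_t)dims[0] * dims[1] * dims[2] * dims[3]);
  for (R_xlen_t i = 0; i < dout.size(); ++i)
    dx[argmax[i] - 1] += dout[i];
  dx.attr("dim") = dims;
  return dx;
}
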