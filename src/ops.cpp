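// Low-level numeric kernels for the detector's computational graph.
// All feature tensors are R arrays with dim = c(B, C, H, W) (column-major,
// batch fastest).  0-based index of element (b,c,h,w):
//   b + B*(c + C*(h + H*w))
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t idx4(int b, int c, int h, int w,
                            int B, int C, int H) {
  return b + (R_xlen_t)B * (c + (R_xlen_t)C * (h + (R_xlen_t)H * w));
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector wt, NumericVector bias,
                        int stride, int padh, int padw) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = wt.attr("dim");
  const int B = xd[0], Ci = xd[1], H = xd[2], W = xd[3];
  const int Co = wd[0], KH = wd[2], KW = wd[3];
  if (wd[1] != Ci) stop("conv2d: channel mismatch");
  const int Ho = (H + 2 * padh - KH) / stride + 1;
  const int Wo = (W + 2 * padw - KW) / stride + 1;
  NumericVector out(no_init((R_xlen_t)B * Co * Ho * Wo));
  out.attr("dim") = IntegerVector::create(B, Co, Ho, Wo);
  const double* xp = x.begin();
  const double* wp = wt.begin();
  double* op = out.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int co = 0; co < Co; ++co) {
        const double bz = bias[co];
        for (int b = 0; b < B; ++b) {
          double acc = bz;
          for (int kw = 0; kw < KW; ++kw) {
            const int wi = wo * stride + kw - padw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < KH; ++kh) {
              const int hi = ho * stride + kh - padh;
              if (hi < 0 || hi >= H) continue;
              for (int ci = 0; ci < Ci; ++ci)
                acc += xp[idx4(b, ci, hi, wi, B, Ci, H)] *
                       wp[idx4(co, ci, kh, kw, Co, Ci, KH)];
            }
          }
          op[idx4(b, co, ho, wo, B, Co, Ho)] = acc;
        }
      }
  return out;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector wt, NumericVector gout,
               int stride, int padh, int padw) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = wt.attr("dim");
  IntegerVector gd = gout.attr("dim");
  const int B = xd[0], Ci = xd[1], H = xd[2], W = xd[3];
  const int Co = wd[0], KH = wd[2], KW = wd[3];
  const int Ho = gd[2], Wo = gd[3];
  NumericVector gx((R_xlen_t)B * Ci * H * W);
  gx.attr("dim") = xd;
  NumericVector gw((R_xlen_t)Co * Ci * KH * KW);
  gw.attr("dim") = wd;
  NumericVector gb(Co);
  const double* xp = x.begin();
  const double* wp = wt.begin();
  const double* gp = gout.begin();
  double* gxp = gx.begin();
  double* gwp = gw.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int co = 0; co < Co; ++co)
        for (int b = 0; b < B; ++b) {
          const double g = gp[idx4(b, co, ho, wo, B, Co, Ho)];
          if (g == 0.0) continue;
          gb[co] += g;
          for (int kw = 0; kw < KW; ++kw) {
            const int wi = wo * stride + kw - padw;
            if (wi < 0 || wi >= W) continue;
            for (int kh = 0; kh < KH; ++kh) {
              const int hi = ho * stride + kh - padh;
              if (hi < 0 || hi >= H) continue;
              for (int ci = 0; ci < Ci; ++ci) {
                gxp[idx4(b, ci, hi, wi, B, Ci, H)] +=
                    g * wp[idx4(co, ci, kh, kw, Co, Ci, KH)];
                gwp[idx4(co, ci, kh, kw, Co, Ci, KH)] +=
                    g * xp[idx4(b, ci, hi, wi, B, Ci, H)];
              }
            }
          }
        }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Bilinear sampling helper: value at continuous point (cy, cx) where pixel
// (h, w) is centred at (h + 0.5, w + 0.5).  Out-of-range coordinates clamp
// to the border pixel.
static inline void bilin_coef(double c, int n, int& i0, int& i1, double& w1) {
  double f = c - 0.5;
  if (f < 0) f = 0;
  if (f > n - 1) f = n - 1;
  i0 = (int)std::floor(f);
  if (i0 > n - 2) i0 = n - 2;
  if (i0 < 0) i0 = 0;
  i1 = i0 + 1;
  if (n == 1) { i0 = 0; i1 = 0; w1 = 0.0; return; }
  w1 = f - i0;
}

// rois: N x 5 matrix (0-based batch index, x1, y1, x2, y2 in [0,1])
// [[Rcpp::export]]
NumericVector roi_align_fw(NumericVector x, NumericMatrix rois,
                           int oh, int ow) {
  IntegerVector xd = x.attr("dim");
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int N = rois.nrow();
  NumericVector out(no_init((R_xlen_t)N * C * oh * ow));
  out.attr("dim") = IntegerVector::create(N, C, oh, ow);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < N; ++n) {
    const int b = (int)rois(n, 0);
    const double x1 = rois(n, 1) * W, y1 = rois(n, 2) * H;
    const double bw = (rois(n, 3) - rois(n, 1)) * W;
    const double bh = (rois(n, 4) - rois(n, 2)) * H;
    for (int j = 0; j < ow; ++j) {
      const double cx = x1 + (j + 0.5) * bw / ow;
      int x0, x1i; double wx;
      bilin_coef(cx, W, x0, x1i, wx);
      for (int i = 0; i < oh; ++i) {
        const double cy = y1 + (i + 0.5) * bh / oh;
        int y0, y1i; double wy;
        bilin_coef(cy, H, y0, y1i, wy);
        for (int c = 0; c < C; ++c) {
          const double v00 = xp[idx4(b, c, y0, x0, B, C, H)];
          const double v01 = xp[idx4(b, c, y0, x1i, B, C, H)];
          const double v10 = xp[idx4(b, c, y1i, x0, B, C, H)];
          const double v11 = xp[idx4(b, c, y1i, x1i, B, C, H)];
          op[idx4(n, c, i, j, N, C, oh)] =
              (1 - wy) * ((1 - wx) * v00 + wx * v01) +
              wy * ((1 - wx) * v10 + wx * v11);
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector roi_align_bw(NumericVector x, NumericMatrix rois,
                           NumericVector gout, int oh, int ow) {
  IntegerVector xd = x.attr("dim");
  const int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int N = rois.nrow();
  NumericVector gx((R_xlen_t)B * C * H * W);
  gx.attr("dim") = xd;
  double* gxp = gx.begin();
  const double* gp = gout.begin();
  for (int n = 0; n < N; ++n) {
    const int b = (int)rois(n, 0);
    const double x1 = rois(n, 1) * W, y1 = rois(n, 2) * H;
    const double bw = (rois(n, 3) - rois(n, 1)) * W;
    const double bh = (rois(n, 4) - rois(n, 2)) * H;
    for (int j = 0; j < ow; ++j) {
      const double cx = x1 + (j + 0.5) * bw / ow;
      int x0, x1i; double wx;
      bilin_coef(cx, W, x0, x1i, wx);
      for (int i = 0; i < oh; ++i) {
        const double cy = y1 + (i + 0.5) * bh / oh;
        int y0, y1i; double wy;
        bilin_coef(cy, H, y0, y1i, wy);
        for (int c = 0; c < C; ++c) {
          const double g = gp[idx4(n, c, i, j, N, C, oh)];
          if (g == 0.0) continue;
          gxp[idx4(b, c, y0, x0, B, C, H)] += g * (1 - wy) * (1 - wx);
          gxp[idx4(b, c, y0, x1i, B, C, H)] += g * (1 - wy) * wx;
          gxp[idx4(b, c, y1i, x0, B, C, H)] += g * wy * (1 - wx);
          gxp[idx4(b, c, y1i, x1i, B, C, H)] += g * wy * wx;
        }
      }
    }
  }
  return gx;
}
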