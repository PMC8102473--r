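#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Tensor layout (2D nets): dim = (H, W, C, N), column-major as in R arrays.
// Convolutions are stride-1, odd kernel, "same" zero padding; spatial
// down/upsampling is done by pooling / nearest upsampling, never by the
// convolution itself.

static inline int idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + H * (w + W * (c + C * n));
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, IntegerVector xdim,
                        NumericVector wgt, IntegerVector wdim,
                        NumericVector bias) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int K = wdim[0], Ci = wdim[2], Co = wdim[3];
  if (Ci != C) stop("conv2d_fw: channel mismatch");
  const int P = (K - 1) / 2;
  NumericVector out(static_cast<R_xlen_t>(H) * W * Co * N);
  const double *px = x.begin(), *pw = wgt.begin(), *pb = bias.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double b = pb[co];
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          po[idx4(h, w, co, n, H, W, Co)] = b;
      for (int ci = 0; ci < C; ++ci)
        for (int kw = 0; kw < K; ++kw)
          for (int kh = 0; kh < K; ++kh) {
            const double wv = pw[kh + K * (kw + K * (ci + Ci * co))];
            if (wv == 0.0) continue;
            const int dh = kh - P, dw = kw - P;
            const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
            for (int w = w0; w < w1; ++w) {
              const double *xc = px + idx4(h0 + dh, w + dw, ci, n, H, W, C);
              double *oc = po + idx4(h0, w, co, n, H, W, Co);
              for (int h = 0; h < h1 - h0; ++h) oc[h] += wv * xc[h];
            }
          }
    }
  out.attr("dim") = IntegerVector::create(H, W, Co, N);
  return out;
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x, IntegerVector xdim,
               NumericVector wgt, IntegerVector wdim,
               NumericVector gout) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int K = wdim[0], Ci = wdim[2], Co = wdim[3];
  const int P = (K - 1) / 2;
  NumericVector gx(x.size()), gw(wgt.size()), gb(Co);
  const double *px = x.begin(), *pw = wgt.begin(), *pg = gout.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      double acc = 0.0;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          acc += pg[idx4(h, w, co, n, H, W, Co)];
      pgb[co] += acc;
      for (int ci = 0; ci < C; ++ci)
        for (int kw = 0; kw < K; ++kw)
          for (int kh = 0; kh < K; ++kh) {
            const int dh = kh - P, dw = kw - P;
            const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
            const double wv = pw[kh + K * (kw + K * (ci + Ci * co))];
            double gwacc = 0.0;
            for (int w = w0; w < w1; ++w) {
              const double *xc = px + idx4(h0 + dh, w + dw, ci, n, H, W, C);
              const double *gc = pg + idx4(h0, w, co, n, H, W, Co);
              double *gxc = pgx + idx4(h0 + dh, w + dw, ci, n, H, W, C);
              for (int h = 0; h < h1 - h0; ++h) {
                gwacc += xc[h] * gc[h];
                gxc[h] += wv * gc[h];
              }
            }
            pgw[kh + K * (kw + K * (ci + Ci * co))] += gwacc;
          }
    }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based argmax
// positions into the flattened input (ties -> first in column-major order).
// [[Rcpp::export]]
List maxpool2_fw(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  if (H % 2 || W % 2) stop("maxpool2_fw: odd spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  IntegerVector amax(out.size());
  const double *px = x.begin();
  double *po = out.begin();
  int *pa = amax.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL; int bi = 0;
          for (int dw = 0; dw < 2; ++dw)
            for (int dh = 0; dh < 2; ++dh) {
              const int i = idx4(2 * ho + dh, 2 * wo + dw, c, n, H, W, C);
              if (px[i] > best) { best = px[i]; bi = i; }
            }
          const int o = idx4(ho, wo, c, n, Ho, Wo, C);
          po[o] = best; pa[o] = bi + 1;
        }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(NumericVector gout, IntegerVector argmax,
                          IntegerVector xdim) {
  NumericVector gx(static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3]);
  const double *pg = gout.begin(); const int *pa = argmax.begin();
  double *pgx = gx.begin();
  for (R_xlen_t i = 0; i < gout.size(); ++i) pgx[pa[i] - 1] += pg[i];
  gx.attr("dim") = xdim;
  return gx;
}

// ---- 3D counterparts; layout dim = (H, W, D, C, N) ----

static inline R_xlen_t idx5(int h, int w, int d, int c, int n,
                            int H, int W, int D, int C) {
  return h + static_cast<R_xlen_t>(H) *
         (w + static_cast<R_xlen_t>(W) *
          (d + static_cast<R_xlen_t>(D) * (c + static_cast<R_xlen_t>(C) * n)));
}

// [[Rcpp::export]]
NumericVector conv3d_fw(NumericVector x, IntegerVector xdim,
                        NumericVector wgt, IntegerVector wdim,
                        NumericVector bias) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3], N = xdim[4];
  const int K = wdim[0], Ci = wdim[3], Co = wdim[4];
  if (Ci != C) stop("conv3d_fw: channel mismatch");
  const int P = (K - 1) / 2;
  NumericVector out(static_cast<R_xlen_t>(H) * W * D * Co * N);
  const double *px = x.begin(), *pw = wgt.begin(), *pb = bias.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double b = pb[co];
      for (int d = 0; d < D; ++d)
        for (int w = 0; w < W; ++w)
          for (int h = 0; h < H; ++h)
            po[idx5(h, w, d, co, n, H, W, D, Co)] = b;
      for (int ci = 0; ci < C; ++ci)
        for (int kd = 0; kd < K; ++kd)
          for (int kw = 0; kw < K; ++kw)
            for (int kh = 0; kh < K; ++kh) {
              const double wv =
                pw[kh + K * (kw + K * (kd + K * (ci + Ci * co)))];
              if (wv == 0.0) continue;
              const int dh = kh - P, dw = kw - P, dd = kd - P;
              const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
              const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
              const int d0 = std::max(0, -dd), d1 = std::min(D, D - dd);
              for (int d = d0; d < d1; ++d)
                for (int w = w0; w < w1; ++w) {
                  const double *xc =
                    px + idx5(h0 + dh, w + dw, d + dd, ci, n, H, W, D, C);
                  double *oc = po + idx5(h0, w, d, co, n, H, W, D, Co);
                  for (int h = 0; h < h1 - h0; ++h) oc[h] += wv * xc[h];
                }
            }
    }
  out.attr("dim") = IntegerVector::create(H, W, D, Co, N);
  return out;
}

// [[Rcpp::export]]
List conv3d_bw(NumericVector x, IntegerVector xdim,
               NumericVector wgt, IntegerVector wdim,
               NumericVector gout) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3], N = xdim[4];
  const int K = wdim[0], Ci = wdim[3], Co = wdim[4];
  const int P = (K - 1) / 2;
  NumericVector gx(x.size()), gw(wgt.size()), gb(Co);
  const double *px = x.begin(), *pw = wgt.begin(), *pg = gout.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      double acc = 0.0;
      for (int d = 0; d < D; ++d)
        for (int w = 0; w < W; ++w)
          for (int h = 0; h < H; ++h)
            acc += pg[idx5(h, w, d, co, n, H, W, D, Co)];
      pgb[co] += acc;
      for (int ci = 0; ci < C; ++ci)
        for (int kd = 0; kd < K; ++kd)
          for (int kw = 0; kw < K; ++kw)
            for (int kh = 0; kh < K; ++kh) {
              const int dh = kh - P, dw = kw - P, dd = kd - P;
              const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
              const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
              const int d0 = std::max(0, -dd), d1 = std::min(D, D - dd);
              const R_xlen_t wi = kh + K * (kw + K * (kd + K * (ci + Ci * co)));
              const double wv = pw[wi];
              double gwacc = 0.0;
              for (int d = d0; d < d1; ++d)
                for (int w = w0; w < w1; ++w) {
                  const double *xc =
                    px + idx5(h0 + dh, w + dw, d + dd, ci, n, H, W, D, C);
                  const double *gc = pg + idx5(h0, w, d, co, n, H, W, D, Co);
                  double *gxc =
                    pgx + idx5(h0 + dh, w + dw, d + dd, ci, n, H, W, D, C);
                  for (int h = 0; h < h1 - h0; ++h) {
                    gwacc += xc[h] * gc[h];
                    gxc[h] += wv * gc[h];
                  }
                }
              pgw[wi] += gwacc;
            }
    }
  gx.attr("dim") = xdim;
  gw.attr("dim") = wdim;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool3_fw(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3], N = xdim[4];
  if (H % 2 || W % 2 || D % 2) stop("maxpool3_fw: odd spatial dims");
  const int Ho = H / 2, Wo = W / 2, Do = D / 2;
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * Do * C * N);
  IntegerVector amax(out.size());
  const double *px = x.begin();
  double *po = out.begin();
  int *pa = amax.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int dd = 0; dd < Do; ++dd)
        for (int wo = 0; wo < Wo; ++wo)
          for (int ho = 0; ho < Ho; ++ho) {
            double best = -HUGE_VAL; R_xlen_t bi = 0;
            for (int zd = 0; zd < 2; ++zd)
              for (int zw = 0; zw < 2; ++zw)
                for (int zh = 0; zh < 2; ++zh) {
                  const R_xlen_t i = idx5(2 * ho + zh, 2 * wo + zw,
                                          2 * dd + zd, c, n, H, W, D, C);
                  if (px[i] > best) { best = px[i]; bi = i; }
                }
            const R_xlen_t o = idx5(ho, wo, dd, c, n, Ho, Wo, Do, C);
            po[o] = best; pa[o] = static_cast<int>(bi) + 1;
          }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Do, C, N);
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool3_bw(NumericVector gout, IntegerVector argmax,
                          IntegerVector xdim) {
  R_xlen_t sz = 1;
  for (int i = 0; i < xdim.size(); ++i) sz *= xdim[i];
  NumericVector gx(sz);
  const double *pg = gout.begin(); const int *pa = argmax.begin();
  double *pgx = gx.begin();
  for (R_xlen_t i = 0; i < gout.size(); ++i) pgx[pa[i] - 1] += pg[i];
  gx.attr("dim") = xdim;
  return gx;
}
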