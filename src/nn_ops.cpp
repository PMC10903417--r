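// Convolutional primitives for the cGAN / U-Net engine.
//
// Tensor convention: R numeric arrays, column-major, dim (H, W, C, N).
// Weights: dim (k, k, Cin, Cout); for a fixed output channel the
// (k, k, Cin) block is contiguous, so the weight matrix (k*k*Cin x Cout)
// maps directly onto the R array.
//
// GEMMs run in single precision (the network is trained with noisy
// gradients; float accuracy is far below the optimization noise floor),
// with activations fused into the convolution kernels:
//   act: 0 = identity, 1 = ReLU, 2 = leaky ReLU (0.2), 3 = sigmoid.
// Convolutions use zero padding. Single-threaded and bit-deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const float LRELU_A = 0.2f;

static inline void get_dims4(const NumericVector &x, int d[4]) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

// im2col in transposed layout (rows: output pixel ho + Ho*wo, sample-major
// blocks; column: i + k*j + k*k*c), casting double input to float.
static void im2col_f(const double *xs, int H, int W, int C,
                     int k, int stride, int pad, int Ho, int Wo,
                     arma::fmat &colT, size_t row_off = 0) {
  const size_t ld = colT.n_rows;
  for (int c = 0; c < C; ++c) {
    const double *xc = xs + (size_t)c * H * W;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        float *dst = colT.memptr() + (size_t)(i + k * j + k * k * c) * ld
                     + row_off;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          float *dcol = dst + (size_t)wo * Ho;
          if (wi < 0 || wi >= W) {
            std::memset(dcol, 0, sizeof(float) * Ho);
            continue;
          }
          const double *xcol = xc + (size_t)wi * H;
          if (stride == 1) {
            int lo = std::max(0, pad - i);
            int hi_end = std::min(Ho, H + pad - i);
            for (int ho = 0; ho < lo; ++ho) dcol[ho] = 0.0f;
            const double *src = xcol - pad + i;
            for (int ho = lo; ho < hi_end; ++ho) dcol[ho] = (float)src[ho];
            for (int ho = hi_end; ho < Ho; ++ho) dcol[ho] = 0.0f;
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + i;
              dcol[ho] = (hi >= 0 && hi < H) ? (float)xcol[hi] : 0.0f;
            }
          }
        }
      }
    }
  }
}

// scatter-add one sample's float column gradient back to the double input
static void col2im_f(const arma::fmat &gcolT, int H, int W, int C,
                     int k, int stride, int pad, int Ho, int Wo,
                     double *gxs, size_t row_off = 0) {
  const size_t ld = gcolT.n_rows;
  for (int c = 0; c < C; ++c) {
    double *gxc = gxs + (size_t)c * H * W;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const float *src = gcolT.memptr() + (size_t)(i + k * j + k * k * c) * ld
                           + row_off;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          double *gxcol = gxc + (size_t)wi * H;
          const float *scol = src + (size_t)wo * Ho;
          if (stride == 1) {
            int lo = std::max(0, pad - i);
            int hi_end = std::min(Ho, H + pad - i);
            double *g = gxcol - pad + i;
            for (int ho = lo; ho < hi_end; ++ho) g[ho] += (double)scol[ho];
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              int hi = ho * stride - pad + i;
              if (hi >= 0 && hi < H) gxcol[hi] += (double)scol[ho];
            }
          }
        }
      }
    }
  }
}

static inline float apply_act(float v, int act) {
  switch (act) {
  case 1: return v > 0.0f ? v : 0.0f;
  case 2: return v > 0.0f ? v : LRELU_A * v;
  case 3: return 1.0f / (1.0f + std::exp(-v));
  default: return v;
  }
}

// derivative of the activation expressed through the activated output y
static inline float act_deriv(float y, int act) {
  switch (act) {
  case 1: return y > 0.0f ? 1.0f : 0.0f;
  case 2: return y > 0.0f ? 1.0f : LRELU_A;
  case 3: return y * (1.0f - y);
  default: return 1.0f;
  }
}

static inline int out_size(int H, int k, int stride, int pad) {
  return (H + 2 * pad - k) / stride + 1;
}

// ---- direct 3x3 stride-1 pad-1 path (the generator's conv workload) ----
// Weight layout for the direct kernels: wf[i + 3*j + 9*c + 9*C*o].

// y[ho, wo, o] = act( b[o] + sum_{c,i,j} x[ho+i-1, wo+j-1, c] * w[i,j,c,o] )
static void direct3_fwd(const float *xf, int H, int W, int C,
                        const float *wf, const double *b, int Cout,
                        int act, float *acc, double *yd) {
  const size_t HW = (size_t)H * W;
  for (int o = 0; o < Cout; ++o) {
    std::memset(acc, 0, sizeof(float) * HW);
    for (int c = 0; c < C; ++c) {
      const float *xc = xf + (size_t)c * HW;
      for (int j = 0; j < 3; ++j) {
        const int wo_lo = std::max(0, 1 - j), wo_hi = std::min(W, W + 1 - j);
        const float *wj = wf + 3 * j + 9 * c + 9 * (size_t)C * o;
        const float w0 = wj[0], w1 = wj[1], w2 = wj[2];
        for (int wo = wo_lo; wo < wo_hi; ++wo) {
          const float *src = xc + (size_t)(wo + j - 1) * H;
          float *dst = acc + (size_t)wo * H;
          dst[0] += w1 * src[0] + w2 * src[1];
          for (int ho = 1; ho < H - 1; ++ho) {
            dst[ho] += w0 * src[ho - 1] + w1 * src[ho] + w2 * src[ho + 1];
          }
          dst[H - 1] += w0 * src[H - 2] + w1 * src[H - 1];
        }
      }
    }
    const float bo = (float)b[o];
    double *yo = yd + (size_t)o * HW;
    for (size_t p = 0; p < HW; ++p) yo[p] = (double)apply_act(acc[p] + bo, act);
  }
}

// accumulate gw[i,j,c,o] += sum x[ho+i-1, wo+j-1, c] * gy[ho, wo, o]
static void direct3_gw(const float *xf, const float *gyf, int H, int W,
                       int C, int Cout, double *gw) {
  const size_t HW = (size_t)H * W;
  for (int o = 0; o < Cout; ++o) {
    const float *go = gyf + (size_t)o * HW;
    for (int c = 0; c < C; ++c) {
      const float *xc = xf + (size_t)c * HW;
      for (int j = 0; j < 3; ++j) {
        const int wo_lo = std::max(0, 1 - j), wo_hi = std::min(W, W + 1 - j);
        for (int i = 0; i < 3; ++i) {
          const int ho_lo = std::max(0, 1 - i), ho_hi = std::min(H, H + 1 - i);
          float acc = 0.0f;
          for (int wo = wo_lo; wo < wo_hi; ++wo) {
            const float *xs = xc + (size_t)(wo + j - 1) * H + (i - 1);
            const float *gs = go + (size_t)wo * H;
            float dot = 0.0f;
            for (int ho = ho_lo; ho < ho_hi; ++ho) dot += xs[ho] * gs[ho];
            acc += dot;
          }
          gw[(size_t)i + 3 * j + 9 * (size_t)c + 9 * (size_t)C * o] +=
              (double)acc;
        }
      }
    }
  }
}

// gx[:, :, c] += sum_o conv(gy[:, :, o], flipped w[:, :, c, o]);
// wT must be pre-flipped with layout [i + 3j + 9o + 9*Cout*c].
// gx[:, :, c] += sum_o conv(gy[:, :, o], flipped w[:, :, c, o]);
// wT must be pre-flipped with layout [i + 3j + 9o + 9*Cout*c].
static void direct3_gx(const float *gyf, int H, int W, int Cout,
                       const float *wT, int C, float *acc, double *gxd) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    std::memset(acc, 0, sizeof(float) * HW);
    for (int o = 0; o < Cout; ++o) {
      const float *gc = gyf + (size_t)o * HW;
      for (int j = 0; j < 3; ++j) {
        const int wo_lo = std::max(0, 1 - j), wo_hi = std::min(W, W + 1 - j);
        const float *wj = wT + 3 * j + 9 * o + 9 * (size_t)Cout * c;
        const float w0 = wj[0], w1 = wj[1], w2 = wj[2];
        for (int wo = wo_lo; wo < wo_hi; ++wo) {
          const float *src = gc + (size_t)(wo + j - 1) * H;
          float *dst = acc + (size_t)wo * H;
          dst[0] += w1 * src[0] + w2 * src[1];
          for (int ho = 1; ho < H - 1; ++ho) {
            dst[ho] += w0 * src[ho - 1] + w1 * src[ho] + w2 * src[ho + 1];
          }
          dst[H - 1] += w0 * src[H - 2] + w1 * src[H - 1];
        }
      }
    }
    double *gxo = gxd + (size_t)c * HW;
    for (size_t p = 0; p < HW; ++p) gxo[p] += (double)acc[p];
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad, int act = 0) {
  int dx[4], dw[4];
  get_dims4(x, dx);
  get_dims4(w, dw);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cin = dw[2], Cout = dw[3];
  if (dw[1] != k) stop("kernel must be square");
  if (Cin != C) stop("input has ", C, " channels but kernel expects ", Cin);
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("field smaller than kernel support");
  const size_t HoWo = (size_t)Ho * Wo, kkC = (size_t)k * k * C;

  NumericVector y(static_cast<R_xlen_t>(HoWo) * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::fmat Wf(kkC, Cout);
  {
    const double *pw = w.begin();
    float *pf = Wf.memptr();
    for (size_t i = 0; i < kkC * (size_t)Cout; ++i) pf[i] = (float)pw[i];
  }
  if (k == 3 && stride == 1 && pad == 1) {
    // direct path: x layout (i + 3j + 9c + 9C*o) coincides with the R array
    static arma::fvec xf_ws, acc_ws;
    const size_t HWC = (size_t)H * W * C;
    xf_ws.set_size(HWC);
    acc_ws.set_size((size_t)H * W);
    for (int n = 0; n < N; ++n) {
      const double *xs = x.begin() + (size_t)n * HWC;
      float *xf = xf_ws.memptr();
      for (size_t p = 0; p < HWC; ++p) xf[p] = (float)xs[p];
      direct3_fwd(xf, H, W, C, Wf.memptr(), b.begin(), Cout, act,
                  acc_ws.memptr(), y.begin() + (size_t)n * HoWo * Cout);
    }
    return y;
  }
  // persistent workspaces: one GEMM over the whole batch
  static arma::fmat colT, ys;
  const size_t rows = HoWo * (size_t)N;
  colT.set_size(rows, kkC);
  ys.set_size(rows, Cout);
  for (int n = 0; n < N; ++n) {
    im2col_f(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad,
             Ho, Wo, colT, (size_t)n * HoWo);
  }
  ys = colT * Wf;
  for (int n = 0; n < N; ++n) {
    double *yd = y.begin() + (size_t)n * HoWo * Cout;
    for (int c = 0; c < Cout; ++c) {
      const float *src = ys.colptr(c) + (size_t)n * HoWo;
      const float bc = (float)b[c];
      double *dst = yd + (size_t)c * HoWo;
      for (size_t p = 0; p < HoWo; ++p) {
        dst[p] = (double)apply_act(src[p] + bc, act);
      }
    }
  }
  return y;
}

// Backward pass through activation + convolution. `y` is the activated
// forward output (used for the activation derivative); `gy` the gradient
// at the activated output.
// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector y,
                NumericVector gy, int stride, int pad, int act = 0) {
  int dx[4], dw[4], dy[4];
  get_dims4(x, dx);
  get_dims4(w, dw);
  get_dims4(gy, dy);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[3];
  const int Ho = dy[0], Wo = dy[1];
  if (dy[2] != Cout || dy[3] != N) stop("gradient shape mismatch");
  const size_t HoWo = (size_t)Ho * Wo, kkC = (size_t)k * k * C;

  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw(static_cast<R_xlen_t>(k) * k * C * Cout);
  gw.attr("dim") = IntegerVector::create(k, k, C, Cout);
  NumericVector gb(Cout);

  arma::fmat Wf(kkC, Cout);
  {
    const double *pw = w.begin();
    float *pf = Wf.memptr();
    for (size_t i = 0; i < kkC * (size_t)Cout; ++i) pf[i] = (float)pw[i];
  }
  if (k == 3 && stride == 1 && pad == 1) {
    static arma::fvec xf_ws, gyf_ws, acc_ws, wT_ws;
    const size_t HWC = (size_t)H * W * C;
    const size_t HWCo = (size_t)Ho * Wo * Cout;
    xf_ws.set_size(HWC);
    gyf_ws.set_size(HWCo);
    acc_ws.set_size((size_t)H * W);
    wT_ws.set_size(kkC * (size_t)Cout);
    // flipped kernel, layout [i + 3j + 9o + 9*Cout*c]
    {
      const double *pw = w.begin();
      float *pt = wT_ws.memptr();
      for (int c = 0; c < C; ++c)
        for (int o = 0; o < Cout; ++o)
          for (int j = 0; j < 3; ++j)
            for (int i = 0; i < 3; ++i)
              pt[i + 3 * j + 9 * o + 9 * (size_t)Cout * c] =
                  (float)pw[(2 - i) + 3 * (2 - j) + 9 * c + 9 * (size_t)C * o];
    }
    arma::fvec gbf(Cout, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      const double *xs = x.begin() + (size_t)n * HWC;
      float *xf = xf_ws.memptr();
      for (size_t p = 0; p < HWC; ++p) xf[p] = (float)xs[p];
      const double *gyd = gy.begin() + (size_t)n * HWCo;
      const double *yd2 = y.begin() + (size_t)n * HWCo;
      float *gyf = gyf_ws.memptr();
      for (int c = 0; c < Cout; ++c) {
        float acc = 0.0f;
        const double *gsrc = gyd + (size_t)c * Ho * Wo;
        const double *ysrc = yd2 + (size_t)c * Ho * Wo;
        float *dst = gyf + (size_t)c * Ho * Wo;
        for (size_t p = 0; p < (size_t)Ho * Wo; ++p) {
          float v = (float)gsrc[p] * act_deriv((float)ysrc[p], act);
          dst[p] = v;
          acc += v;
        }
        gbf[c] += acc;
      }
      direct3_gw(xf, gyf, H, W, C, Cout, gw.begin());
      direct3_gx(gyf, H, W, Cout, wT_ws.memptr(), C, acc_ws.memptr(),
                 gx.begin() + (size_t)n * HWC);
    }
    for (int c = 0; c < Cout; ++c) gb[c] = (double)gbf[c];
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  static arma::fmat colT, gys, gcolT;
  const size_t rows = HoWo * (size_t)N;
  colT.set_size(rows, kkC);
  gys.set_size(rows, Cout);
  gcolT.set_size(rows, kkC);
  arma::fvec gbf(Cout, arma::fill::zeros);

  for (int n = 0; n < N; ++n) {
    im2col_f(x.begin() + (size_t)n * H * W * C, H, W, C, k, stride, pad,
             Ho, Wo, colT, (size_t)n * HoWo);
    const double *gyd = gy.begin() + (size_t)n * HoWo * Cout;
    const double *yd = y.begin() + (size_t)n * HoWo * Cout;
    for (int c = 0; c < Cout; ++c) {
      float *dst = gys.colptr(c) + (size_t)n * HoWo;
      const double *gsrc = gyd + (size_t)c * HoWo;
      const double *ysrc = yd + (size_t)c * HoWo;
      float acc = 0.0f;
      for (size_t p = 0; p < HoWo; ++p) {
        float v = (float)gsrc[p] * act_deriv((float)ysrc[p], act);
        dst[p] = v;
        acc += v;
      }
      gbf[c] += acc;
    }
  }
  arma::fmat gWf = colT.t() * gys;
  gcolT = gys * Wf.t();
  for (int n = 0; n < N; ++n) {
    col2im_f(gcolT, H, W, C, k, stride, pad, Ho, Wo,
             gx.begin() + (size_t)n * H * W * C, (size_t)n * HoWo);
  }
  {
    const float *pf = gWf.memptr();
    double *pd = gw.begin();
    for (size_t i = 0; i < kkC * (size_t)Cout; ++i) pd[i] = (double)pf[i];
    for (int c = 0; c < Cout; ++c) gb[c] = (double)gbf[c];
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; returns values and 0-based argmax indices
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  int d[4];
  get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("field size must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector idx(y.size());

  const double *px = x.begin();
  double *py = y.begin(), *pi = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t i00 = base + (size_t)(2 * wo) * H + 2 * ho;
          size_t best = i00;
          double v = px[i00];
          if (px[i00 + 1] > v) { v = px[i00 + 1]; best = i00 + 1; }
          if (px[i00 + H] > v) { v = px[i00 + H]; best = i00 + H; }
          if (px[i00 + H + 1] > v) { v = px[i00 + H + 1]; best = i00 + H + 1; }
          size_t oy = ((size_t)n * C + c) * Ho * Wo + (size_t)wo * Ho + ho;
          py[oy] = v;
          pi[oy] = (double)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector gy, NumericVector idx,
                           IntegerVector in_dim) {
  NumericVector gx(static_cast<R_xlen_t>(in_dim[0]) * in_dim[1] * in_dim[2] * in_dim[3]);
  gx.attr("dim") = in_dim;
  const double *pg = gy.begin(), *pi = idx.begin();
  double *px = gx.begin();
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) px[(size_t)pi[i]] += pg[i];
  return gx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x) {
  int d[4];
  get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *px = x.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bi = ((size_t)n * C + c) * H * W;
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double v = px[bi + (size_t)w * H + h];
          size_t o00 = bo + (size_t)(2 * w) * Ho + 2 * h;
          py[o00] = v;
          py[o00 + 1] = v;
          py[o00 + Ho] = v;
          py[o00 + Ho + 1] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector gy) {
  int d[4];
  get_dims4(gy, d);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  if (Ho % 2 || Wo % 2) stop("gradient size must be even");
  const int H = Ho / 2, W = Wo / 2;
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double *pg = gy.begin();
  double *px = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      const size_t bi = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          size_t o00 = bo + (size_t)(2 * w) * Ho + 2 * h;
          px[bi + (size_t)w * H + h] =
              pg[o00] + pg[o00 + 1] + pg[o00 + Ho] + pg[o00 + Ho + 1];
        }
    }
  return gx;
}

// channel-wise concatenation of two (H, W, C, N) arrays
// [[Rcpp::export]]
NumericVector concat_chan(NumericVector a, NumericVector b) {
  int da[4], db[4];
  get_dims4(a, da);
  get_dims4(b, db);
  if (da[0] != db[0] || da[1] != db[1] || da[3] != db[3]) {
    stop("concat: spatial/batch dims differ");
  }
  const size_t HW = (size_t)da[0] * da[1];
  const int Ca = da[2], Cb = db[2], N = da[3];
  NumericVector y(static_cast<R_xlen_t>(HW) * (Ca + Cb) * N);
  y.attr("dim") = IntegerVector::create(da[0], da[1], Ca + Cb, N);
  double *py = y.begin();
  for (int n = 0; n < N; ++n) {
    std::memcpy(py + (size_t)n * HW * (Ca + Cb), a.begin() + (size_t)n * HW * Ca,
                sizeof(double) * HW * Ca);
    std::memcpy(py + (size_t)n * HW * (Ca + Cb) + HW * Ca,
                b.begin() + (size_t)n * HW * Cb, sizeof(double) * HW * Cb);
  }
  return y;
}
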