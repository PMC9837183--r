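// Data-movement primitives of the U-Net engine. Matrix products stay in R
// (BLAS); these routines handle the layout transforms that dominate the
// interpreted implementation. Column matrices are pixel-major
// (H*W*N rows) so that im2col reduces to contiguous segment copies and
// array <-> matrix conversions to per-channel block copies.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// The convolution kernels are compiled with function multiversioning: the
// toolchain's baseline (-march=nocona) stays the fallback, and an AVX2/FMA
// clone is dispatched at load time on CPUs that support it.
#if defined(__GNUC__) && defined(__x86_64__) && !defined(__clang__)
#define VESICA_MULTIARCH __attribute__((target_clones("default", "arch=haswell")))
#else
#define VESICA_MULTIARCH
#endif

static NumericVector num4(int H, int W, int C, int N) {
  NumericVector v((R_xlen_t)H * W * C * N);
  v.attr("dim") = IntegerVector::create(H, W, C, N);
  return v;
}

static IntegerVector int4(int H, int W, int C, int N) {
  IntegerVector v((R_xlen_t)H * W * C * N);
  v.attr("dim") = IntegerVector::create(H, W, C, N);
  return v;
}

// (H, W, C, N) array -> (H*W*N, C) pixel-major matrix (block copies).
// [[Rcpp::export]]
NumericMatrix cpp_arr_to_pix(NumericVector x, int H, int W, int C, int N) {
  const size_t HW = (size_t)H * W;
  NumericMatrix out(HW * N, C);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      std::memcpy(po + (size_t)c * HW * N + (size_t)n * HW,
                  px + ((size_t)n * C + c) * HW, sizeof(double) * HW);
    }
  }
  return out;
}

// (H*W*N, C) pixel-major matrix -> (H, W, C, N) array.
// [[Rcpp::export]]
NumericVector cpp_pix_to_arr(NumericMatrix m, int H, int W, int C, int N) {
  const size_t HW = (size_t)H * W;
  NumericVector out = num4(H, W, C, N);
  const double* pm = m.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int n = 0; n < N; ++n) {
      std::memcpy(po + ((size_t)n * C + c) * HW,
                  pm + (size_t)c * HW * N + (size_t)n * HW,
                  sizeof(double) * HW);
    }
  }
  return out;
}

// 2x2 max pooling; returns pooled array and argmax code 0..3 (a + 2*b).
// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = num4(Ho, Wo, C, N);
  IntegerVector which = int4(Ho, Wo, C, N);
  const double* px = x.begin();
  double* py = y.begin();
  int* pw = which.begin();
  const size_t HW = (size_t)H * W;
  const size_t HWo = (size_t)Ho * Wo;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xc = px + (size_t)cn * HW;
    double* yc = py + (size_t)cn * HWo;
    int* wc = pw + (size_t)cn * HWo;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const int i = 2 * io, j = 2 * jo;
        double best = xc[(size_t)j * H + i];
        int arg = 0;
        double v = xc[(size_t)j * H + i + 1];
        if (v > best) { best = v; arg = 1; }
        v = xc[(size_t)(j + 1) * H + i];
        if (v > best) { best = v; arg = 2; }
        v = xc[(size_t)(j + 1) * H + i + 1];
        if (v > best) { best = v; arg = 3; }
        yc[(size_t)jo * Ho + io] = best;
        wc[(size_t)jo * Ho + io] = arg;
      }
    }
  }
  return List::create(_["y"] = y, _["which"] = which);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dy, IntegerVector which,
                             int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx = num4(H, W, C, N);
  const double* pdy = dy.begin();
  const int* pw = which.begin();
  double* pdx = dx.begin();
  const size_t HW = (size_t)H * W;
  const size_t HWo = (size_t)Ho * Wo;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* dyc = pdy + (size_t)cn * HWo;
    const int* wc = pw + (size_t)cn * HWo;
    double* dxc = pdx + (size_t)cn * HW;
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        const int arg = wc[(size_t)jo * Ho + io];
        const int i = 2 * io + (arg & 1);
        const int j = 2 * jo + (arg >> 1);
        dxc[(size_t)j * H + i] = dyc[(size_t)jo * Ho + io];
      }
    }
  }
  return dx;
}

// (H*W*N, 4F) pixel-major with columns (a fastest, b, f) -> (2H, 2W, F, N).
// [[Rcpp::export]]
NumericVector cpp_up_to_spatial(NumericMatrix m, int H, int W, int F, int N) {
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y = num4(Ho, Wo, F, N);
  const double* pm = m.begin();
  double* py = y.begin();
  const size_t HW = (size_t)H * W;
  const size_t HWN = HW * N;
  const size_t HWo = (size_t)Ho * Wo;
  for (int f = 0; f < F; ++f) {
    for (int ab = 0; ab < 4; ++ab) {
      const double* col = pm + (size_t)(4 * f + ab) * HWN;
      const int oi = ab & 1, oj = ab >> 1;
      for (int n = 0; n < N; ++n) {
        double* yf = py + ((size_t)n * F + f) * HWo;
        const double* src = col + (size_t)n * HW;
        for (int j = 0; j < W; ++j) {
          double* dst = yf + (size_t)(2 * j + oj) * Ho + oi;
          const double* s = src + (size_t)j * H;
          for (int i = 0; i < H; ++i) dst[2 * i] = s[i];
        }
      }
    }
  }
  return y;
}

// Adjoint of cpp_up_to_spatial.
// [[Rcpp::export]]
NumericMatrix cpp_spatial_to_up(NumericVector dy, int H, int W, int F, int N) {
  const int Ho = 2 * H, Wo = 2 * W;
  const size_t HW = (size_t)H * W;
  const size_t HWN = HW * N;
  const size_t HWo = (size_t)Ho * Wo;
  NumericMatrix m(HWN, 4 * F);
  const double* py = dy.begin();
  double* pm = m.begin();
  for (int f = 0; f < F; ++f) {
    for (int ab = 0; ab < 4; ++ab) {
      double* col = pm + (size_t)(4 * f + ab) * HWN;
      const int oi = ab & 1, oj = ab >> 1;
      for (int n = 0; n < N; ++n) {
        const double* yf = py + ((size_t)n * F + f) * HWo;
        double* dst = col + (size_t)n * HW;
        for (int j = 0; j < W; ++j) {
          const double* s = yf + (size_t)(2 * j + oj) * Ho + oi;
          double* d = dst + (size_t)j * H;
          for (int i = 0; i < H; ++i) d[i] = s[2 * i];
        }
      }
    }
  }
  return m;
}

// Fused ReLU: y = max(x, 0) in place-like fashion (returns new array).
// [[Rcpp::export]]
NumericVector cpp_relu_fw(NumericVector x) {
  NumericVector y = clone(x);
  double* p = y.begin();
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
  return y;
}

// dy masked by (y > 0).
// [[Rcpp::export]]
NumericVector cpp_relu_bw(NumericVector dy, NumericVector y) {
  NumericVector dx = clone(dy);
  double* p = dx.begin();
  const double* q = y.begin();
  const R_xlen_t n = dx.size();
  for (R_xlen_t i = 0; i < n; ++i) if (q[i] <= 0) p[i] = 0;
  return dx;
}

// Direct 3x3 same-padding convolution. w: (9C x Fo), row order
// (di fastest, dj, c). y[i,j,f,n] = b[f] + sum w * x[i+di, j+dj, c, n].
// [[Rcpp::export]]
NumericVector cpp_conv3_fw(NumericVector x, NumericMatrix w, NumericVector b,
                           int H, int W, int C, int N) {
  const int Fo = w.ncol();
  NumericVector y = num4(H, W, Fo, N);
  const size_t HW = (size_t)H * W;
  const double* px = x.begin();
  const double* pw = w.begin();
  double* py = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int f = 0; f < Fo; ++f) {
      double* yf = py + ((size_t)n * Fo + f) * HW;
      const double bf = b[f];
      for (size_t p = 0; p < HW; ++p) yf[p] = bf;
      const double* wf = pw + (size_t)f * 9 * C;
      for (int c = 0; c < C; ++c) {
        const double* xc = px + ((size_t)n * C + c) * HW;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const double wv = wf[(di + 1) + 3 * (dj + 1) + 9 * c];
            if (wv == 0.0) continue;
            const int lo = (di < 0) ? 1 : 0;
            const int hi = (di > 0) ? H - 1 : H;
            for (int j = 0; j < W; ++j) {
              const int jj = j + dj;
              if (jj < 0 || jj >= W) continue;
              double* __restrict__ yc = yf + (size_t)j * H;
              const double* __restrict__ xs = xc + (size_t)jj * H + di;
              for (int i = lo; i < hi; ++i) yc[i] += wv * xs[i];
            }
          }
        }
      }
    }
  }
  return y;
}

// Gradient w.r.t. the convolution input (correlation with flipped kernel).
// [[Rcpp::export]]
NumericVector cpp_conv3_bw_x(NumericVector dy, NumericMatrix w,
                             int H, int W, int C, int N) {
  const int Fo = w.ncol();
  NumericVector dx = num4(H, W, C, N);
  const size_t HW = (size_t)H * W;
  const double* pdy = dy.begin();
  const double* pw = w.begin();
  double* pdx = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double* xc = pdx + ((size_t)n * C + c) * HW;
      for (int f = 0; f < Fo; ++f) {
        const double* yf = pdy + ((size_t)n * Fo + f) * HW;
        const double* wf = pw + (size_t)f * 9 * C;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const double wv = wf[(di + 1) + 3 * (dj + 1) + 9 * c];
            if (wv == 0.0) continue;
            // dx[i+di, j+dj] += wv * dy[i, j]  ==>
            // dx[a, b] += wv * dy[a-di, b-dj]
            const int lo = (di > 0) ? 1 : 0;
            const int hi = (di < 0) ? H - 1 : H;
            for (int b2 = 0; b2 < W; ++b2) {
              const int j = b2 - dj;
              if (j < 0 || j >= W) continue;
              double* __restrict__ xcol = xc + (size_t)b2 * H;
              const double* __restrict__ ys = yf + (size_t)j * H - di;
              for (int a = lo; a < hi; ++a) xcol[a] += wv * ys[a];
            }
          }
        }
      }
    }
  }
  return dx;
}

// Gradient w.r.t. the convolution weights; also returns the bias gradient.
// [[Rcpp::export]]
List cpp_conv3_bw_w(NumericVector x, NumericVector dy,
                    int H, int W, int C, int N, int Fo) {
  NumericMatrix dW(9 * C, Fo);
  NumericVector db(Fo);
  const size_t HW = (size_t)H * W;
  const double* px = x.begin();
  const double* pdy = dy.begin();
  for (int n = 0; n < N; ++n) {
    for (int f = 0; f < Fo; ++f) {
      const double* yf = pdy + ((size_t)n * Fo + f) * HW;
      double sb = 0.0;
      for (size_t p = 0; p < HW; ++p) sb += yf[p];
      db[f] += sb;
      for (int c = 0; c < C; ++c) {
        const double* xc = px + ((size_t)n * C + c) * HW;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int lo = (di < 0) ? 1 : 0;
            const int hi = (di > 0) ? H - 1 : H;
            double a0 = 0.0, a1 = 0.0, a2 = 0.0, a3 = 0.0;
            for (int j = 0; j < W; ++j) {
              const int jj = j + dj;
              if (jj < 0 || jj >= W) continue;
              const double* __restrict__ yc = yf + (size_t)j * H;
              const double* __restrict__ xs = xc + (size_t)jj * H + di;
              int i = lo;
              for (; i + 3 < hi; i += 4) {
                a0 += yc[i] * xs[i];
                a1 += yc[i + 1] * xs[i + 1];
                a2 += yc[i + 2] * xs[i + 2];
                a3 += yc[i + 3] * xs[i + 3];
              }
              for (; i < hi; ++i) a0 += yc[i] * xs[i];
            }
            dW((di + 1) + 3 * (dj + 1) + 9 * c, f) += a0 + a1 + a2 + a3;
          }
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db);
}

// Fused batch normalization (training mode): per-channel batch statistics,
// normalized output and cached xhat in two passes.
// [[Rcpp::export]]
List cpp_bn_fw(NumericVector x, NumericVector gamma, NumericVector beta,
               double eps, int HW, int C, int N) {
  NumericVector mu(C), var(C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = px + ((size_t)n * C + c) * HW;
      for (int p = 0; p < HW; ++p) { s += xc[p]; s2 += xc[p] * xc[p]; }
    }
    const double M = (double)HW * N;
    mu[c] = s / M;
    double v = s2 / M - mu[c] * mu[c];
    var[c] = v > 0 ? v : 0;
  }
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = x.attr("dim");
  xhat.attr("dim") = x.attr("dim");
  double* pyv = y.begin();
  double* ph = xhat.begin();
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c], bt = beta[c], m = mu[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double* xc = px + off;
      double* hc = ph + off;
      double* yc = pyv + off;
      for (int p = 0; p < HW; ++p) {
        const double h = (xc[p] - m) * inv;
        hc[p] = h;
        yc[p] = g * h + bt;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["var"] = var);
}

// Fused batch-norm backward pass.
// [[Rcpp::export]]
List cpp_bn_bw(NumericVector dy, NumericVector xhat, NumericVector gamma,
               NumericVector inv, int HW, int C, int N) {
  NumericVector dgamma(C), dbeta(C);
  const double* pdy = dy.begin();
  const double* ph = xhat.begin();
  for (int c = 0; c < C; ++c) {
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double* dc = pdy + off;
      const double* hc = ph + off;
      for (int p = 0; p < HW; ++p) { sg += dc[p] * hc[p]; sb += dc[p]; }
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
  }
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  double* pdx = dx.begin();
  const double M = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    const double gi = gamma[c] * inv[c];
    const double t1 = dbeta[c] / M;
    const double t2 = dgamma[c] / M;
    for (int n = 0; n < N; ++n) {
      const size_t off = ((size_t)n * C + c) * HW;
      const double* dc = pdy + off;
      const double* hc = ph + off;
      double* xc = pdx + off;
      for (int p = 0; p < HW; ++p) xc[p] = gi * (dc[p] - t1 - hc[p] * t2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ---- single-precision convolution kernels -------------------------------
// CNN training is robust to reduced precision; the 3x3 convolutions (the
// compute bottleneck) run internally in float via im2col + BLAS sgemm,
// with double interfaces.

extern "C" void sgemm_(const char*, const char*, const int*, const int*,
                       const int*, const float*, const float*, const int*,
                       const float*, const int*, const float*, float*,
                       const int*);

static void sgemm(char ta, char tb, int m, int n, int k, const float* a,
                  int lda, const float* b, int ldb, float beta, float* c,
                  int ldc) {
  const float alpha = 1.0f;
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c, &ldc);
}

// float im2col: x (H,W,C,N) doubles -> cols (HWN x 9C) floats,
// column r = (di fastest, dj, c), rows pixel-major (i, j, n).
VESICA_MULTIARCH
static void im2col_f(const double* px, float* pc, int H, int W, int C,
                     int N) {
  const size_t HW = (size_t)H * W;
  const size_t HWN = HW * N;
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int r = (di + 1) + 3 * (dj + 1) + 9 * c;
        float* colr = pc + (size_t)r * HWN;
        for (int n = 0; n < N; ++n) {
          const double* xc = px + ((size_t)n * C + c) * HW;
          float* dst0 = colr + (size_t)n * HW;
          for (int j = 0; j < W; ++j) {
            const int jj = j + dj;
            float* __restrict__ dst = dst0 + (size_t)j * H;
            if (jj < 0 || jj >= W) {
              for (int i = 0; i < H; ++i) dst[i] = 0.0f;
              continue;
            }
            const double* __restrict__ src = xc + (size_t)jj * H + di;
            const int lo = (di < 0) ? 1 : 0;
            const int hi = (di > 0) ? H - 1 : H;
            if (lo > 0) dst[0] = 0.0f;
            if (hi < H) dst[H - 1] = 0.0f;
            for (int i = lo; i < hi; ++i) dst[i] = (float)src[i];
          }
        }
      }
    }
  }
}

// adjoint scatter-add of im2col_f into a double (H,W,C,N) array
VESICA_MULTIARCH
static void col2im_f(const float* pc, double* pdx, int H, int W, int C,
                     int N) {
  const size_t HW = (size_t)H * W;
  const size_t HWN = HW * N;
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int r = (di + 1) + 3 * (dj + 1) + 9 * c;
        const float* colr = pc + (size_t)r * HWN;
        for (int n = 0; n < N; ++n) {
          double* xc = pdx + ((size_t)n * C + c) * HW;
          const float* src0 = colr + (size_t)n * HW;
          for (int j = 0; j < W; ++j) {
            const int jj = j + dj;
            if (jj < 0 || jj >= W) continue;
            const float* __restrict__ src = src0 + (size_t)j * H;
            double* __restrict__ dst = xc + (size_t)jj * H + di;
            const int lo = (di < 0) ? 1 : 0;
            const int hi = (di > 0) ? H - 1 : H;
            for (int i = lo; i < hi; ++i) dst[i] += src[i];
          }
        }
      }
    }
  }
}

// Forward: y = conv(x, w) + b; returns y (double) and the cached float
// column matrix for the backward pass.
// [[Rcpp::export]]
List cpp_conv3f_fw(NumericVector x, NumericMatrix w, NumericVector b,
                   int H, int W, int C, int N) {
  const int Fo = w.ncol();
  const size_t HW = (size_t)H * W;
  const size_t HWN = HW * N;
  RawVector cols_raw(sizeof(float) * HWN * 9 * C);
  float* cols = (float*)RAW(cols_raw);
  im2col_f(x.begin(), cols, H, W, C, N);
  std::vector<float> wf(9 * C * Fo);
  for (size_t i = 0; i < wf.size(); ++i) wf[i] = (float)w.begin()[i];
  std::vector<float> yf(HWN * Fo);
  sgemm('N', 'N', (int)HWN, Fo, 9 * C, cols, (int)HWN, wf.data(), 9 * C,
        0.0f, yf.data(), (int)HWN);
  NumericVector y = num4(H, W, Fo, N);
  double* py = y.begin();
  for (int f = 0; f < Fo; ++f) {
    const double bf = b[f];
    for (int n = 0; n < N; ++n) {
      const float* src = yf.data() + (size_t)f * HWN + (size_t)n * HW;
      double* dst = py + ((size_t)n * Fo + f) * HW;
      for (size_t p = 0; p < HW; ++p) dst[p] = src[p] + bf;
    }
  }
  return List::create(_["y"] = y, _["xf"] = cols_raw);
}

// Fused backward: input, weight and bias gradients from the cached
// column matrix.
// [[Rcpp::export]]
List cpp_conv3f_bw(RawVector cols_raw, NumericVector dy, NumericMatrix w,
                   int H, int W, int C, int N) {
  const int Fo = w.ncol();
  const size_t HW = (size_t)H * W;
  const size_t HWN = HW * N;
  const float* cols = (const float*)RAW(cols_raw);
  std::vector<float> dyf(HWN * Fo);
  NumericVector db(Fo);
  for (int f = 0; f < Fo; ++f) {
    double sb = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* src = dy.begin() + ((size_t)n * Fo + f) * HW;
      float* dst = dyf.data() + (size_t)f * HWN + (size_t)n * HW;
      for (size_t p = 0; p < HW; ++p) {
        dst[p] = (float)src[p];
        sb += src[p];
      }
    }
    db[f] = sb;
  }
  std::vector<float> wf(9 * C * Fo);
  for (size_t i = 0; i < wf.size(); ++i) wf[i] = (float)w.begin()[i];
  std::vector<float> dWf((size_t)9 * C * Fo);
  sgemm('T', 'N', 9 * C, Fo, (int)HWN, cols, (int)HWN, dyf.data(),
        (int)HWN, 0.0f, dWf.data(), 9 * C);
  NumericMatrix dW(9 * C, Fo);
  for (size_t i = 0; i < dWf.size(); ++i) dW.begin()[i] = dWf[i];
  std::vector<float> dcols(HWN * 9 * C);
  sgemm('N', 'T', (int)HWN, 9 * C, Fo, dyf.data(), (int)HWN, wf.data(),
        9 * C, 0.0f, dcols.data(), (int)HWN);
  NumericVector dx = num4(H, W, C, N);
  col2im_f(dcols.data(), dx.begin(), H, W, C, N);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
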