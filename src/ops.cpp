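// Low-level numerical kernels for the segmentation networks.
//
// Tensor layout (column-major R arrays):
//   activations  x : dim (H, W, C, N)
//   conv weights w : dim (k, k, C_in, C_out); flattened column-major this is a
//                    (k*k*C_in) x C_out matrix whose row index is
//                    u + k*v + k*k*c  (u = row offset, v = col offset).
// All heavy arithmetic runs in single precision through BLAS GEMM; inputs and
// outputs cross the R boundary as doubles.

#include <RcppArmadillo.h>
#include <cfloat>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::fmat as_fmat(const NumericVector& v, int nrow, int ncol) {
  arma::fmat out(nrow, ncol);
  const double* p = v.begin();
  float* q = out.memptr();
  const R_xlen_t n = (R_xlen_t)nrow * ncol;
  for (R_xlen_t i = 0; i < n; ++i) q[i] = (float)p[i];
  return out;
}

static NumericVector to_num(const arma::fmat& m, IntegerVector dim) {
  NumericVector out(m.n_elem);
  const float* q = m.memptr();
  for (R_xlen_t i = 0; i < (R_xlen_t)m.n_elem; ++i) out[i] = (double)q[i];
  out.attr("dim") = dim;
  return out;
}

// im2col for one sample into a destination with arbitrary leading dimension:
// column index u + k*v + k*k*c of the k*k*C-wide block holds
// x[h+u-pad, w+v-pad, c] for output pixel (h, w). `dst0` points at the first
// row this sample occupies; `ld` is the distance between columns. The caller
// zero-fills beforehand.
static void im2col(const float* xs, int H, int W, int C, int k, int pad,
                   float* dst0, R_xlen_t ld) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const float* xc = xs + (R_xlen_t)c * HW;
    for (int v = 0; v < k; ++v) {
      for (int u = 0; u < k; ++u) {
        float* dst = dst0 + ld * ((R_xlen_t)c * k * k + v * k + u);
        for (int w = 0; w < W; ++w) {
          const int iw = w + v - pad;
          if (iw < 0 || iw >= W) continue;
          const int h0 = std::max(0, pad - u);
          const int h1 = std::min(H, H + pad - u);
          const float* src = xc + (R_xlen_t)iw * H + (h0 + u - pad);
          std::copy(src, src + (h1 - h0), dst + (R_xlen_t)w * H + h0);
        }
      }
    }
  }
}

// transpose of im2col: scatter-add a strided column block back into dx_s
// (H*W x C view). `src0`/`ld` mirror the im2col destination convention.
static void col2im(const float* src00, R_xlen_t ld, int H, int W, int C,
                   int k, int pad, float* dxs) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    float* xc = dxs + (R_xlen_t)c * HW;
    for (int v = 0; v < k; ++v) {
      for (int u = 0; u < k; ++u) {
        const float* src0 = src00 + ld * ((R_xlen_t)c * k * k + v * k + u);
        for (int w = 0; w < W; ++w) {
          const int iw = w + v - pad;
          if (iw < 0 || iw >= W) continue;
          const int h0 = std::max(0, pad - u);
          const int h1 = std::min(H, H + pad - u);
          float* dst = xc + (R_xlen_t)iw * H + (h0 + u - pad);
          const float* src = src0 + (R_xlen_t)w * H + h0;
          for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// Shared-kernel 2-D convolution, stride 1, zero padding.
// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, IntegerVector xdim,
                            NumericVector w, int k, int pad,
                            Nullable<NumericVector> bias) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], N = xdim[3];
  const int HW = H * W;
  const int KK = k * k * Ci;
  const int Co = (int)(w.size() / KK);
  arma::fmat xf = as_fmat(x, HW * Ci, N);
  arma::fmat Wm = as_fmat(w, KK, Co);
  arma::frowvec b(Co, arma::fill::zeros);
  if (bias.isNotNull()) {
    NumericVector bb(bias);
    for (int o = 0; o < Co; ++o) b[o] = (float)bb[o];
  }
  arma::fmat y(HW * Co, N);
  arma::fmat cols(HW, KK);
  for (int n = 0; n < N; ++n) {
    cols.zeros();
    im2col(xf.colptr(n), H, W, Ci, k, pad, cols.memptr(), HW);
    arma::fmat yn = cols * Wm;           // HW x Co
    yn.each_row() += b;
    std::copy(yn.memptr(), yn.memptr() + (R_xlen_t)HW * Co, y.colptr(n));
  }
  return to_num(y, IntegerVector::create(H, W, Co, N));
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, IntegerVector xdim,
                   NumericVector w, int k, int pad,
                   NumericVector dy, bool need_dx, bool has_bias) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], N = xdim[3];
  const int HW = H * W;
  const int KK = k * k * Ci;
  const int Co = (int)(w.size() / KK);
  arma::fmat xf = as_fmat(x, HW * Ci, N);
  arma::fmat Wm = as_fmat(w, KK, Co);
  arma::fmat dyf = as_fmat(dy, HW * Co, N);
  arma::fmat dW(KK, Co, arma::fill::zeros);
  arma::frowvec db(Co, arma::fill::zeros);
  arma::fmat dx;
  if (need_dx) dx.zeros(HW * Ci, N);
  arma::fmat cols(HW, KK);
  for (int n = 0; n < N; ++n) {
    cols.zeros();
    im2col(xf.colptr(n), H, W, Ci, k, pad, cols.memptr(), HW);
    arma::fmat dyn(dyf.colptr(n), HW, Co, false, true);
    dW += cols.t() * dyn;
    if (has_bias) db += arma::sum(dyn, 0);
    if (need_dx) {
      arma::fmat dcols = dyn * Wm.t();   // HW x KK
      col2im(dcols.memptr(), HW, H, W, Ci, k, pad, dx.colptr(n));
    }
  }
  List out = List::create(
    _["dw"] = to_num(dW, IntegerVector::create(k, k, Ci, Co)),
    _["db"] = has_bias ? (SEXP)to_num(db.t(), IntegerVector::create(Co))
                       : (SEXP)R_NilValue,
    _["dx"] = need_dx ? (SEXP)to_num(dx, IntegerVector::create(H, W, Ci, N))
                      : (SEXP)R_NilValue);
  return out;
}

// Per-sample kernel: W_n[r, o] = lam[o, n] * W0[r, o] + M[j, o, n] / Ci,
// where r = c*k*k + j decomposes into input channel c and kernel element j.
static void assemble_kernel(const arma::fmat& W0, const float* lam,
                            const float* M, int k, int Ci, int Co,
                            arma::fmat& Wn) {
  const int kk = k * k;
  const float inv = 1.0f / (float)Ci;
  for (int o = 0; o < Co; ++o) {
    const float l = lam[o];
    const float* Mo = M + (R_xlen_t)o * kk;
    const float* w0 = W0.colptr(o);
    float* wn = Wn.colptr(o);
    for (int c = 0; c < Ci; ++c)
      for (int j = 0; j < kk; ++j)
        wn[c * kk + j] = l * w0[c * kk + j] + Mo[j] * inv;
  }
}

// Dynamic-kernel convolution: each sample is convolved with its own kernel.
// lam: (Co, N); M: (k*k, Co, N) dynamic residual in kernel-element space.
// [[Rcpp::export]]
NumericVector cpp_dcd_conv_fw(NumericVector x, IntegerVector xdim,
                              NumericVector w0, NumericVector lam,
                              NumericVector M, int k, int pad) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], N = xdim[3];
  const int HW = H * W, kk = k * k, KK = kk * Ci;
  const int Co = (int)(w0.size() / KK);
  arma::fmat xf = as_fmat(x, HW * Ci, N);
  arma::fmat W0 = as_fmat(w0, KK, Co);
  arma::fmat lamf = as_fmat(lam, Co, N);
  arma::fmat Mf = as_fmat(M, kk * Co, N);
  arma::fmat y(HW * Co, N);
  arma::fmat cols(HW, KK), Wn(KK, Co);
  for (int n = 0; n < N; ++n) {
    assemble_kernel(W0, lamf.colptr(n), Mf.colptr(n), k, Ci, Co, Wn);
    cols.zeros();
    im2col(xf.colptr(n), H, W, Ci, k, pad, cols.memptr(), HW);
    arma::fmat yn = cols * Wn;
    std::copy(yn.memptr(), yn.memptr() + (R_xlen_t)HW * Co, y.colptr(n));
  }
  return to_num(y, IntegerVector::create(H, W, Co, N));
}

// [[Rcpp::export]]
List cpp_dcd_conv_bw(NumericVector x, IntegerVector xdim,
                     NumericVector w0, NumericVector lam, NumericVector M,
                     int k, int pad, NumericVector dy, bool need_dx) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], N = xdim[3];
  const int HW = H * W, kk = k * k, KK = kk * Ci;
  const int Co = (int)(w0.size() / KK);
  arma::fmat xf = as_fmat(x, HW * Ci, N);
  arma::fmat W0 = as_fmat(w0, KK, Co);
  arma::fmat lamf = as_fmat(lam, Co, N);
  arma::fmat Mf = as_fmat(M, kk * Co, N);
  arma::fmat dyf = as_fmat(dy, HW * Co, N);
  arma::fmat dW0(KK, Co, arma::fill::zeros);
  arma::fmat dlam(Co, N, arma::fill::zeros);
  arma::fmat dM(kk * Co, N, arma::fill::zeros);
  arma::fmat dx;
  if (need_dx) dx.zeros(HW * Ci, N);
  arma::fmat cols(HW, KK), Wn(KK, Co);
  const float inv = 1.0f / (float)Ci;
  for (int n = 0; n < N; ++n) {
    cols.zeros();
    im2col(xf.colptr(n), H, W, Ci, k, pad, cols.memptr(), HW);
    arma::fmat dyn(dyf.colptr(n), HW, Co, false, true);
    arma::fmat dWn = cols.t() * dyn;     // KK x Co, gradient w.r.t. W_n
    const float* ln = lamf.colptr(n);
    float* dMn = dM.colptr(n);
    for (int o = 0; o < Co; ++o) {
      const float* dwo = dWn.colptr(o);
      const float* w0o = W0.colptr(o);
      float* dW0o = dW0.colptr(o);
      float acc = 0.0f;
      float* dMo = dMn + (R_xlen_t)o * kk;
      for (int c = 0; c < Ci; ++c) {
        for (int j = 0; j < kk; ++j) {
          const float g = dwo[c * kk + j];
          acc += g * w0o[c * kk + j];
          dW0o[c * kk + j] += ln[o] * g;
          dMo[j] += g * inv;
        }
      }
      dlam(o, n) = acc;
    }
    if (need_dx) {
      assemble_kernel(W0, ln, Mf.colptr(n), k, Ci, Co, Wn);
      arma::fmat dcols = dyn * Wn.t();
      col2im(dcols.memptr(), HW, H, W, Ci, k, pad, dx.colptr(n));
    }
  }
  return List::create(
    _["dw0"] = to_num(dW0, IntegerVector::create(k, k, Ci, Co)),
    _["dlam"] = to_num(dlam, IntegerVector::create(Co, N)),
    _["dM"] = to_num(dM, IntegerVector::create(kk, Co, N)),
    _["dx"] = need_dx ? (SEXP)to_num(dx, IntegerVector::create(H, W, Ci, N))
                      : (SEXP)R_NilValue);
}

// 2x2 max pooling, stride 2. Returns pooled values and the argmax slot (0..3,
// order: (0,0),(1,0),(0,1),(1,1) in (h,w) offsets; ties go to the first).
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  const R_xlen_t plane = (R_xlen_t)H * W;
  const R_xlen_t oplane = (R_xlen_t)Ho * Wo;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx(y.size());
  const double* px = x.begin();
  for (R_xlen_t s = 0; s < (R_xlen_t)C * N; ++s) {
    const double* xs = px + s * plane;
    double* ys = y.begin() + s * oplane;
    int* is = idx.begin() + s * oplane;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const double v0 = xs[(R_xlen_t)(2 * w) * H + 2 * h];
        const double v1 = xs[(R_xlen_t)(2 * w) * H + 2 * h + 1];
        const double v2 = xs[(R_xlen_t)(2 * w + 1) * H + 2 * h];
        const double v3 = xs[(R_xlen_t)(2 * w + 1) * H + 2 * h + 1];
        double m = v0; int a = 0;
        if (v1 > m) { m = v1; a = 1; }
        if (v2 > m) { m = v2; a = 2; }
        if (v3 > m) { m = v3; a = 3; }
        ys[(R_xlen_t)w * Ho + h] = m;
        is[(R_xlen_t)w * Ho + h] = a;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(IntegerVector idx, NumericVector dy,
                              IntegerVector ydim, int H, int W) {
  const int Ho = ydim[0], Wo = ydim[1], C = ydim[2], N = ydim[3];
  const R_xlen_t plane = (R_xlen_t)H * W;
  const R_xlen_t oplane = (R_xlen_t)Ho * Wo;
  NumericVector dx((R_xlen_t)H * W * C * N);
  for (R_xlen_t s = 0; s < (R_xlen_t)C * N; ++s) {
    const double* ds = dy.begin() + s * oplane;
    const int* is = idx.begin() + s * oplane;
    double* xs = dx.begin() + s * plane;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const int a = is[(R_xlen_t)w * Ho + h];
        const int hh = 2 * h + (a & 1);
        const int ww = 2 * w + (a >> 1);
        xs[(R_xlen_t)ww * H + hh] += ds[(R_xlen_t)w * Ho + h];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Channel-wise batch-norm statistics over (H, W, N).
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const R_xlen_t plane = (R_xlen_t)H * W;
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + ((R_xlen_t)n * C + c) * plane;
      for (R_xlen_t i = 0; i < plane; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s / ((double)plane * N);
    mu[c] = m;
    var[c] = s2 / ((double)plane * N) - m * m;
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// y = gamma * (x - mu) / sqrt(var + eps) + beta
// [[Rcpp::export]]
NumericVector cpp_bn_fw(NumericVector x, IntegerVector xdim,
                        NumericVector mu, NumericVector var,
                        NumericVector gamma, NumericVector beta, double eps) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const R_xlen_t plane = (R_xlen_t)H * W;
  NumericVector y(x.size());
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c] * inv, b = beta[c] - gamma[c] * inv * mu[c];
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + ((R_xlen_t)n * C + c) * plane;
      double* q = y.begin() + ((R_xlen_t)n * C + c) * plane;
      for (R_xlen_t i = 0; i < plane; ++i) q[i] = g * p[i] + b;
    }
  }
  y.attr("dim") = xdim;
  return y;
}

// Standard batch-norm backward through the batch statistics.
// [[Rcpp::export]]
List cpp_bn_bw(NumericVector x, IntegerVector xdim,
               NumericVector mu, NumericVector var,
               NumericVector gamma, NumericVector dy, double eps) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const R_xlen_t plane = (R_xlen_t)H * W;
  const double m = (double)plane * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    double sdy = 0.0, sdyx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + ((R_xlen_t)n * C + c) * plane;
      const double* pd = dy.begin() + ((R_xlen_t)n * C + c) * plane;
      for (R_xlen_t i = 0; i < plane; ++i) {
        sdy += pd[i];
        sdyx += pd[i] * (px[i] - mu[c]) * inv;
      }
    }
    dbeta[c] = sdy;
    dgamma[c] = sdyx;
    const double g = gamma[c];
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + ((R_xlen_t)n * C + c) * plane;
      const double* pd = dy.begin() + ((R_xlen_t)n * C + c) * plane;
      double* q = dx.begin() + ((R_xlen_t)n * C + c) * plane;
      for (R_xlen_t i = 0; i < plane; ++i) {
        const double xh = (px[i] - mu[c]) * inv;
        q[i] = g * inv * (pd[i] - sdy / m - xh * sdyx / m);
      }
    }
  }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ---- batched fast paths -----------------------------------------------------
//
// The training layers batch the im2col matrices of all samples into one tall
// GEMM. For DCD the per-sample kernel W_n = diag(lam_n) W0 + broadcast(M_n)
// is never materialized: columns of (COLS x W0) are scaled by lam afterwards,
// and the residual contracts through the channel-summed columns
// RED[p, j] = sum_c COLS[p, c*k*k + j], so
//   Y_n = (COLS_n x W0) diag(lam_n) + RED_n (M_n / C_in).

static void build_cols(const arma::fmat& xf, int H, int W, int Ci, int k,
                       int pad, int N, arma::fmat& COLS) {
  const int HW = H * W;
  COLS.zeros();
  for (int n = 0; n < N; ++n)
    im2col(xf.colptr(n), H, W, Ci, k, pad,
           COLS.memptr() + (R_xlen_t)n * HW, (R_xlen_t)COLS.n_rows);
}

static void reduce_channels(const arma::fmat& COLS, int k, int Ci,
                            arma::fmat& RED) {
  const int kk = k * k;
  RED.zeros();
  for (int c = 0; c < Ci; ++c)
    RED += COLS.cols((arma::uword)c * kk, (arma::uword)(c + 1) * kk - 1);
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw_b(NumericVector x, IntegerVector xdim,
                              NumericVector w, int k, int pad,
                              Nullable<NumericVector> bias) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], N = xdim[3];
  const int HW = H * W, KK = k * k * Ci;
  const int Co = (int)(w.size() / KK);
  arma::fmat xf = as_fmat(x, HW * Ci, N);
  arma::fmat Wm = as_fmat(w, KK, Co);
  arma::fmat COLS((arma::uword)N * HW, KK);
  build_cols(xf, H, W, Ci, k, pad, N, COLS);
  arma::fmat Y = COLS * Wm;
  if (bias.isNotNull()) {
    NumericVector bb(bias);
    arma::frowvec b(Co);
    for (int o = 0; o < Co; ++o) b[o] = (float)bb[o];
    Y.each_row() += b;
  }
  NumericVector y((R_xlen_t)HW * Co * N);
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Co; ++o) {
      const float* src = Y.colptr(o) + (arma::uword)n * HW;
      double* dst = y.begin() + ((R_xlen_t)n * Co + o) * HW;
      for (int i = 0; i < HW; ++i) dst[i] = (double)src[i];
    }
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  return y;
}

// dy gathered into (N*HW, Co) column-major order
static arma::fmat gather_dy(const NumericVector& dy, int HW, int Co, int N) {
  arma::fmat DY((arma::uword)N * HW, Co);
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Co; ++o) {
      const double* src = dy.begin() + ((R_xlen_t)n * Co + o) * HW;
      float* dst = DY.colptr(o) + (arma::uword)n * HW;
      for (int i = 0; i < HW; ++i) dst[i] = (float)src[i];
    }
  return DY;
}

// [[Rcpp::export]]
List cpp_conv2d_bw_b(NumericVector x, IntegerVector xdim, NumericVector w,
                     int k, int pad, NumericVector dy, bool need_dx,
                     bool has_bias) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], N = xdim[3];
  const int HW = H * W, KK = k * k * Ci;
  const int Co = (int)(w.size() / KK);
  arma::fmat xf = as_fmat(x, HW * Ci, N);
  arma::fmat Wm = as_fmat(w, KK, Co);
  arma::fmat COLS((arma::uword)N * HW, KK);
  build_cols(xf, H, W, Ci, k, pad, N, COLS);
  arma::fmat DY = gather_dy(dy, HW, Co, N);
  arma::fmat dW = COLS.t() * DY;
  List out = List::create(
    _["dw"] = to_num(dW, IntegerVector::create(k, k, Ci, Co)),
    _["db"] = R_NilValue, _["dx"] = R_NilValue);
  if (has_bias) {
    arma::frowvec db = arma::sum(DY, 0);
    out["db"] = to_num(arma::fmat(db.t()), IntegerVector::create(Co));
  }
  if (need_dx) {
    arma::fmat DCOLS = DY * Wm.t();
    arma::fmat dx((arma::uword)HW * Ci, N, arma::fill::zeros);
    for (int n = 0; n < N; ++n)
      col2im(DCOLS.memptr() + (R_xlen_t)n * HW, (R_xlen_t)DCOLS.n_rows,
             H, W, Ci, k, pad, dx.colptr(n));
    out["dx"] = to_num(dx, IntegerVector::create(H, W, Ci, N));
  }
  return out;
}

// Returns y plus the pre-scale static response A = COLS x W0 (cached by the
// layer for the backward pass).
// [[Rcpp::export]]
List cpp_dcd_conv_fw_b(NumericVector x, IntegerVector xdim, NumericVector w0,
                       NumericVector lam, NumericVector M, int k, int pad) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], N = xdim[3];
  const int HW = H * W, kk = k * k, KK = kk * Ci;
  const int Co = (int)(w0.size() / KK);
  arma::fmat xf = as_fmat(x, HW * Ci, N);
  arma::fmat W0 = as_fmat(w0, KK, Co);
  arma::fmat lamf = as_fmat(lam, Co, N);
  arma::fmat Mf = as_fmat(M, kk * Co, N);
  arma::fmat COLS((arma::uword)N * HW, KK);
  build_cols(xf, H, W, Ci, k, pad, N, COLS);
  arma::fmat A = COLS * W0;
  arma::fmat RED((arma::uword)N * HW, kk);
  reduce_channels(COLS, k, Ci, RED);
  const float inv = 1.0f / (float)Ci;
  NumericVector y((R_xlen_t)HW * Co * N), av(y.size());
  for (int n = 0; n < N; ++n) {
    arma::fmat Mn(Mf.colptr(n), kk, Co, false, true);
    arma::fmat Rn = RED.rows((arma::uword)n * HW,
                             (arma::uword)(n + 1) * HW - 1) * Mn;  // HW x Co
    for (int o = 0; o < Co; ++o) {
      const float l = lamf(o, n);
      const float* a = A.colptr(o) + (arma::uword)n * HW;
      const float* r = Rn.colptr(o);
      double* dst = y.begin() + ((R_xlen_t)n * Co + o) * HW;
      double* adst = av.begin() + ((R_xlen_t)n * Co + o) * HW;
      for (int i = 0; i < HW; ++i) {
        dst[i] = (double)(l * a[i] + inv * r[i]);
        adst[i] = (double)a[i];
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, Co, N);
  av.attr("dim") = IntegerVector::create(H, W, Co, N);
  return List::create(_["y"] = y, _["A"] = av);
}

// [[Rcpp::export]]
List cpp_dcd_conv_bw_b(NumericVector x, IntegerVector xdim, NumericVector w0,
                       NumericVector lam, NumericVector M, NumericVector A,
                       int k, int pad, NumericVector dy, bool need_dx) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], N = xdim[3];
  const int HW = H * W, kk = k * k, KK = kk * Ci;
  const int Co = (int)(w0.size() / KK);
  arma::fmat xf = as_fmat(x, HW * Ci, N);
  arma::fmat W0 = as_fmat(w0, KK, Co);
  arma::fmat lamf = as_fmat(lam, Co, N);
  arma::fmat Mf = as_fmat(M, kk * Co, N);
  arma::fmat COLS((arma::uword)N * HW, KK);
  build_cols(xf, H, W, Ci, k, pad, N, COLS);
  arma::fmat RED((arma::uword)N * HW, kk);
  reduce_channels(COLS, k, Ci, RED);
  arma::fmat DY = gather_dy(dy, HW, Co, N);
  // lam-scaled dy for the static-kernel terms
  arma::fmat DYs = DY;
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Co; ++o) {
      float* p = DYs.colptr(o) + (arma::uword)n * HW;
      const float l = lamf(o, n);
      for (int i = 0; i < HW; ++i) p[i] *= l;
    }
  arma::fmat dW0 = COLS.t() * DYs;
  // dlam[o, n] = <A_n[, o], DY_n[, o]>
  arma::fmat dlam(Co, N);
  const double* ap = A.begin();
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Co; ++o) {
      const float* d = DY.colptr(o) + (arma::uword)n * HW;
      const double* a = ap + ((R_xlen_t)n * Co + o) * HW;
      float acc = 0.0f;
      for (int i = 0; i < HW; ++i) acc += d[i] * (float)a[i];
      dlam(o, n) = acc;
    }
  // dM_n = RED_n^T DY_n / Ci
  const float inv = 1.0f / (float)Ci;
  arma::fmat dM(kk * Co, N);
  for (int n = 0; n < N; ++n) {
    arma::fmat t = RED.rows((arma::uword)n * HW,
                            (arma::uword)(n + 1) * HW - 1).t() *
      DY.rows((arma::uword)n * HW, (arma::uword)(n + 1) * HW - 1);
    t *= inv;
    std::copy(t.memptr(), t.memptr() + (arma::uword)kk * Co, dM.colptr(n));
  }
  List out = List::create(
    _["dw0"] = to_num(dW0, IntegerVector::create(k, k, Ci, Co)),
    _["dlam"] = to_num(dlam, IntegerVector::create(Co, N)),
    _["dM"] = to_num(dM, IntegerVector::create(kk, Co, N)),
    _["dx"] = R_NilValue);
  if (need_dx) {
    arma::fmat DCOLS = DYs * W0.t();          // static part
    arma::fmat dx((arma::uword)HW * Ci, N, arma::fill::zeros);
    const R_xlen_t ld = (R_xlen_t)DCOLS.n_rows;
    for (int n = 0; n < N; ++n) {
      arma::fmat Mn(Mf.colptr(n), kk, Co, false, true);
      arma::fmat t = DY.rows((arma::uword)n * HW,
                             (arma::uword)(n + 1) * HW - 1) * Mn.t();  // HW x kk
      t *= inv;
      for (int c = 0; c < Ci; ++c)
        for (int j = 0; j < kk; ++j) {
          float* dst = DCOLS.memptr() + (R_xlen_t)n * HW +
            ld * ((R_xlen_t)c * kk + j);
          const float* src = t.colptr(j);
          for (int i = 0; i < HW; ++i) dst[i] += src[i];
        }
      col2im(DCOLS.memptr() + (R_xlen_t)n * HW, ld, H, W, Ci, k, pad,
             dx.colptr(n));
    }
    out["dx"] = to_num(dx, IntegerVector::create(H, W, Ci, N));
  }
  return out;
}

// Fused in-place Adam update on double storage owned by the caller.
// [[Rcpp::export]]
void cpp_adam_update(NumericVector p, NumericVector g, NumericVector m,
                     NumericVector v, double lr, double beta1, double beta2,
                     double eps, double c1, double c2) {
  const R_xlen_t n = p.size();
  double* pp = p.begin();
  const double* pg = g.begin();
  double* pm = m.begin();
  double* pv = v.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = beta1 * pm[i] + (1 - beta1) * pg[i];
    pv[i] = beta2 * pv[i] + (1 - beta2) * pg[i] * pg[i];
    pp[i] -= lr * (pm[i] / c1) / (std::sqrt(pv[i] / c2) + eps);
  }
}

// ---- fused triplet-attention kernels ---------------------------------------
//
// Branch planes for an (H, W, C, N) tensor:
//   mode 0 (spatial):        plane (H, W), pooled axis C
//   mode 1 (channel-height): plane (H, C), pooled axis W
//   mode 2 (channel-width):  plane (C, W), pooled axis H
// The axis permutations of the rotation-based formulation are realized as
// index arithmetic; no tensor is ever physically permuted.

static inline void ta_dims(int mode, int H, int W, int C,
                           int& D1, int& D2, int& Dp) {
  if (mode == 0) { D1 = H; D2 = W; Dp = C; }
  else if (mode == 1) { D1 = H; D2 = C; Dp = W; }
  else { D1 = C; D2 = W; Dp = H; }
}

static inline R_xlen_t ta_plane_idx(int mode, int h, int w, int c,
                                    int D1) {
  if (mode == 0) return (R_xlen_t)w * D1 + h;
  if (mode == 1) return (R_xlen_t)c * D1 + h;
  return (R_xlen_t)w * D1 + c;
}

// Z-Pool over the branch's pooled axis: channel 0 max, channel 1 mean.
// [[Rcpp::export]]
List cpp_ta_pool(NumericVector x, IntegerVector xdim, int mode) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int D1, D2, Dp; ta_dims(mode, H, W, C, D1, D2, Dp);
  const R_xlen_t plane = (R_xlen_t)D1 * D2;
  NumericVector zp(plane * 2 * N);
  IntegerVector am(plane * N);
  for (int n = 0; n < N; ++n) {
    double* zmax = zp.begin() + (R_xlen_t)n * 2 * plane;
    double* zmean = zmax + plane;
    int* a = am.begin() + (R_xlen_t)n * plane;
    for (R_xlen_t i = 0; i < plane; ++i) { zmax[i] = -DBL_MAX; zmean[i] = 0; }
    const double* xn = x.begin() + (R_xlen_t)n * H * W * C;
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w) {
        const double* col = xn + ((R_xlen_t)c * W + w) * H;
        for (int h = 0; h < H; ++h) {
          const R_xlen_t pi = ta_plane_idx(mode, h, w, c, D1);
          const double v = col[h];
          zmean[pi] += v;
          if (v > zmax[pi]) {
            zmax[pi] = v;
            a[pi] = (mode == 0) ? c : (mode == 1 ? w : h);
          }
        }
      }
    for (R_xlen_t i = 0; i < plane; ++i) zmean[i] /= Dp;
  }
  zp.attr("dim") = IntegerVector::create(D1, D2, 2, N);
  am.attr("dim") = IntegerVector::create(D1, D2, N);
  return List::create(_["zp"] = zp, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_ta_pool_bw(NumericVector dzp, IntegerVector am,
                             IntegerVector xdim, int mode) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int D1, D2, Dp; ta_dims(mode, H, W, C, D1, D2, Dp);
  const R_xlen_t plane = (R_xlen_t)D1 * D2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  for (int n = 0; n < N; ++n) {
    const double* dmax = dzp.begin() + (R_xlen_t)n * 2 * plane;
    const double* dmean = dmax + plane;
    const int* a = am.begin() + (R_xlen_t)n * plane;
    double* dxn = dx.begin() + (R_xlen_t)n * H * W * C;
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w) {
        double* col = dxn + ((R_xlen_t)c * W + w) * H;
        for (int h = 0; h < H; ++h) {
          const R_xlen_t pi = ta_plane_idx(mode, h, w, c, D1);
          double g = dmean[pi] / Dp;
          const int slot = (mode == 0) ? c : (mode == 1 ? w : h);
          if (slot == a[pi]) g += dmax[pi];
          col[h] += g;
        }
      }
  }
  dx.attr("dim") = xdim;
  return dx;
}

// y = x * gate, with the single-channel gate indexed through the branch plane.
// [[Rcpp::export]]
NumericVector cpp_ta_gate_fw(NumericVector x, IntegerVector xdim,
                             NumericVector g, int mode) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int D1, D2, Dp; ta_dims(mode, H, W, C, D1, D2, Dp);
  const R_xlen_t plane = (R_xlen_t)D1 * D2;
  NumericVector y(x.size());
  for (int n = 0; n < N; ++n) {
    const double* gn = g.begin() + (R_xlen_t)n * plane;
    const double* xn = x.begin() + (R_xlen_t)n * H * W * C;
    double* yn = y.begin() + (R_xlen_t)n * H * W * C;
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w) {
        const R_xlen_t base = ((R_xlen_t)c * W + w) * H;
        for (int h = 0; h < H; ++h)
          yn[base + h] = xn[base + h] *
            gn[ta_plane_idx(mode, h, w, c, D1)];
      }
  }
  y.attr("dim") = xdim;
  return y;
}

// [[Rcpp::export]]
List cpp_ta_gate_bw(NumericVector x, IntegerVector xdim, NumericVector g,
                    NumericVector dy, int mode) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int D1, D2, Dp; ta_dims(mode, H, W, C, D1, D2, Dp);
  const R_xlen_t plane = (R_xlen_t)D1 * D2;
  NumericVector dx(x.size()), dg(plane * N);
  for (int n = 0; n < N; ++n) {
    const double* gn = g.begin() + (R_xlen_t)n * plane;
    double* dgn = dg.begin() + (R_xlen_t)n * plane;
    const double* xn = x.begin() + (R_xlen_t)n * H * W * C;
    const double* dyn = dy.begin() + (R_xlen_t)n * H * W * C;
    double* dxn = dx.begin() + (R_xlen_t)n * H * W * C;
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w) {
        const R_xlen_t base = ((R_xlen_t)c * W + w) * H;
        for (int h = 0; h < H; ++h) {
          const R_xlen_t pi = ta_plane_idx(mode, h, w, c, D1);
          dxn[base + h] = dyn[base + h] * gn[pi];
          dgn[pi] += dyn[base + h] * xn[base + h];
        }
      }
  }
  dx.attr("dim") = xdim;
  dg.attr("dim") = IntegerVector::create(D1, D2, 1, N);
  return List::create(_["dx"] = dx, _["dg"] = dg);
}

// ---- fused batch-norm + rectification --------------------------------------

// [[Rcpp::export]]
NumericVector cpp_bn_relu_fw(NumericVector x, IntegerVector xdim,
                             NumericVector mu, NumericVector var,
                             NumericVector gamma, NumericVector beta,
                             double eps) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const R_xlen_t plane = (R_xlen_t)H * W;
  NumericVector y(x.size());
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    const double g = gamma[c] * inv, b = beta[c] - gamma[c] * inv * mu[c];
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + ((R_xlen_t)n * C + c) * plane;
      double* q = y.begin() + ((R_xlen_t)n * C + c) * plane;
      for (R_xlen_t i = 0; i < plane; ++i) {
        const double v = g * p[i] + b;
        q[i] = v > 0 ? v : 0;
      }
    }
  }
  y.attr("dim") = xdim;
  return y;
}

// Backward through rectification (mask from the cached output y) and the
// batch statistics in one fused pass.
// [[Rcpp::export]]
List cpp_bn_relu_bw(NumericVector x, IntegerVector xdim,
                    NumericVector mu, NumericVector var,
                    NumericVector gamma, NumericVector dy, NumericVector y,
                    double eps) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const R_xlen_t plane = (R_xlen_t)H * W;
  const double m = (double)plane * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double inv = 1.0 / std::sqrt(var[c] + eps);
    double sdy = 0.0, sdyx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + ((R_xlen_t)n * C + c) * plane;
      const double* pd = dy.begin() + ((R_xlen_t)n * C + c) * plane;
      const double* py = y.begin() + ((R_xlen_t)n * C + c) * plane;
      for (R_xlen_t i = 0; i < plane; ++i) {
        if (py[i] <= 0) continue;
        sdy += pd[i];
        sdyx += pd[i] * (px[i] - mu[c]) * inv;
      }
    }
    dbeta[c] = sdy;
    dgamma[c] = sdyx;
    const double g = gamma[c];
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + ((R_xlen_t)n * C + c) * plane;
      const double* pd = dy.begin() + ((R_xlen_t)n * C + c) * plane;
      const double* py = y.begin() + ((R_xlen_t)n * C + c) * plane;
      double* q = dx.begin() + ((R_xlen_t)n * C + c) * plane;
      for (R_xlen_t i = 0; i < plane; ++i) {
        const double d = py[i] > 0 ? pd[i] : 0.0;
        const double xh = (px[i] - mu[c]) * inv;
        q[i] = g * inv * (d - sdy / m - xh * sdyx / m);
      }
    }
  }
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
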