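// 2-D convolution kernels for the attention ResNet.
//
// Layout: batch tensors are R arrays dim (H, W, C, N), column-major, either
// native double or float32 packed in R integer vectors (see tensor_ops.cpp);
// outputs match the input kind. Kernels are arrays dim (kh, kw, Cin, Cout).
// "Same" zero padding of floor(k/2) per side, so the output size is
// floor((H + 2p - k)/s) + 1. The im2col matrix is built position-major
// (P x K, P = Ho*Wo, K = kh*kw*Cin) so the GEMM output (P x Cout) is
// exactly the column-major output slice of one image; a chunk of images is
// stacked into one matrix so each layer runs a few large GEMMs. GEMM runs
// in single precision: activations are O(1) after batch normalization and
// the optimizer is plain SGD, so float accumulation is ample.

#include <RcppArmadillo.h>
#include <vector>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const float* x, int H, int W, int C,
                   int kh, int kw, int stride, int ph, int pw,
                   int Ho, int Wo, arma::fmat& col, std::size_t row_off) {
  // col: P x K, column k = dh + kh*dw + kh*kw*c; the interior depth range
  // is copied branch-free, only the padded fringe is bounds-checked
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (std::size_t)c * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        float* dst = col.colptr(dh + kh * dw + kh * kw * c) + row_off;
        const int off = dh - ph;
        int lo = 0;
        while (lo < Ho && lo * stride + off < 0) ++lo;
        int hi = Ho - 1;
        while (hi >= 0 && hi * stride + off > H - 1) --hi;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pw + dw;
          float* d = dst + (std::size_t)wo * Ho;
          if (wi < 0 || wi >= W) {
            std::fill(d, d + Ho, 0.0f);
            continue;
          }
          const float* xcol = xc + (std::size_t)wi * H;
          for (int ho = 0; ho < lo; ++ho) d[ho] = 0.0f;
          if (stride == 1) {
            std::memcpy(d + lo, xcol + lo + off,
                        (hi - lo + 1) * sizeof(float));
          } else {
            for (int ho = lo; ho <= hi; ++ho)
              d[ho] = xcol[ho * stride + off];
          }
          for (int ho = hi + 1; ho < Ho; ++ho) d[ho] = 0.0f;
        }
      }
    }
  }
}

static void col2im_acc(float* gx, int H, int W, int C,
                       int kh, int kw, int stride, int ph, int pw,
                       int Ho, int Wo, const arma::fmat& gcol,
                       std::size_t row_off) {
  for (int c = 0; c < C; ++c) {
    float* xc = gx + (std::size_t)c * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const float* src = gcol.colptr(dh + kh * dw + kh * kw * c) + row_off;
        const int off = dh - ph;
        int lo = 0;
        while (lo < Ho && lo * stride + off < 0) ++lo;
        int hi = Ho - 1;
        while (hi >= 0 && hi * stride + off > H - 1) --hi;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pw + dw;
          if (wi < 0 || wi >= W) continue;
          const float* s = src + (std::size_t)wo * Ho;
          float* xcol = xc + (std::size_t)wi * H;
          if (stride == 1) {
            float* dd = xcol + lo + off;
            for (int ho = lo; ho <= hi; ++ho) dd[ho - lo] += s[ho];
          } else {
            for (int ho = lo; ho <= hi; ++ho)
              xcol[ho * stride + off] += s[ho];
          }
        }
      }
    }
  }
}

static R_xlen_t tdims(SEXP x, int* d4) {
  SEXP dim = Rf_getAttrib(x, R_DimSymbol);
  if (Rf_isNull(dim) || Rf_length(dim) != 4)
    stop("expected a 4-d (H, W, C, N) array");
  const int* d = INTEGER(dim);
  R_xlen_t n = 1;
  for (int i = 0; i < 4; ++i) { d4[i] = d[i]; n *= d[i]; }
  return n;
}

static bool f32p(SEXP x) { return TYPEOF(x) == INTSXP; }

static const float* view_f32(SEXP x, std::vector<float>& tmp) {
  if (f32p(x)) return reinterpret_cast<const float*>(INTEGER(x));
  const double* d = REAL(x);
  const R_xlen_t n = XLENGTH(x);
  tmp.resize(n);
  for (R_xlen_t i = 0; i < n; ++i) tmp[i] = (float)d[i];
  return tmp.data();
}

static arma::fmat as_fmat(const double* p, std::size_t nr, std::size_t nc) {
  arma::fmat m(nr, nc);
  std::size_t n = nr * nc;
  float* q = m.memptr();
  for (std::size_t i = 0; i < n; ++i) q[i] = (float)p[i];
  return m;
}

// persistent grow-only workspaces: R is single-threaded, and reusing these
// avoids first-touch page faults on every layer call
static float* ws_get(int which, std::size_t need) {
  static std::vector<float> ws[4];
  if (ws[which].size() < need) ws[which].resize(need);
  return ws[which].data();
}

// [[Rcpp::export(name = ".conv2d_fw")]]
SEXP conv2d_fw(SEXP x, NumericVector w, int stride) {
  int dx[4], dw_[4];
  tdims(x, dx);
  tdims(w, dw_);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw_[0], kw = dw_[1], Cin = dw_[2], Cout = dw_[3];
  if (Cin != C) stop("channel mismatch: input has %d, kernel expects %d", C, Cin);
  const int ph = kh / 2, pw = kw / 2;
  const int Ho = (H + 2 * ph - kh) / stride + 1;
  const int Wo = (W + 2 * pw - kw) / stride + 1;
  const std::size_t P = (std::size_t)Ho * Wo, K = (std::size_t)kh * kw * C;

  std::vector<float> xtmp;
  const float* xp = view_f32(x, xtmp);
  arma::fmat Wm = as_fmat(REAL(w), K, Cout);
  const bool f32out = f32p(x);
  SEXP y = PROTECT(Rf_allocVector(f32out ? INTSXP : REALSXP,
                                  (R_xlen_t)(P * Cout) * N));
  SEXP ydim = PROTECT(Rf_allocVector(INTSXP, 4));
  INTEGER(ydim)[0] = Ho; INTEGER(ydim)[1] = Wo;
  INTEGER(ydim)[2] = Cout; INTEGER(ydim)[3] = N;
  Rf_setAttrib(y, R_DimSymbol, ydim);
  float* yf = f32out ? reinterpret_cast<float*>(INTEGER(y)) : nullptr;
  double* yd = f32out ? nullptr : REAL(y);

  int B = (int)std::max((std::size_t)1,
                        std::min((std::size_t)N, 6000000 / (P * K)));
  for (int n0 = 0; n0 < N; n0 += B) {
    const int nb = std::min(B, N - n0);
    arma::fmat col(ws_get(0, (std::size_t)nb * P * K),
                   (std::size_t)nb * P, K, false, true);
    arma::fmat out(ws_get(1, (std::size_t)nb * P * Cout),
                   (std::size_t)nb * P, Cout, false, true);
    for (int b = 0; b < nb; ++b)
      im2col(xp + (std::size_t)(n0 + b) * H * W * C, H, W, C,
             kh, kw, stride, ph, pw, Ho, Wo, col, (std::size_t)b * P);
    out = col * Wm;
    for (int b = 0; b < nb; ++b) {
      const R_xlen_t base = (R_xlen_t)(n0 + b) * P * Cout;
      for (int co = 0; co < Cout; ++co) {
        const float* op = out.colptr(co) + (std::size_t)b * P;
        if (yf) {
          std::memcpy(yf + base + (R_xlen_t)co * P, op, P * sizeof(float));
        } else {
          double* yq = yd + base + (R_xlen_t)co * P;
          for (std::size_t i = 0; i < P; ++i) yq[i] = (double)op[i];
        }
      }
    }
  }
  UNPROTECT(2);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(SEXP x, NumericVector w, SEXP gy, int stride,
               bool need_gx = true) {
  int dx[4], dw_[4], dy[4];
  tdims(x, dx);
  tdims(w, dw_);
  tdims(gy, dy);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw_[0], kw = dw_[1], Cout = dw_[3];
  const int ph = kh / 2, pw = kw / 2;
  const int Ho = dy[0], Wo = dy[1];
  const std::size_t P = (std::size_t)Ho * Wo, K = (std::size_t)kh * kw * C;

  std::vector<float> xtmp, gtmp;
  const float* xp = view_f32(x, xtmp);
  const float* gp = view_f32(gy, gtmp);
  arma::fmat Wm = as_fmat(REAL(w), K, Cout);
  arma::fmat gWm(K, Cout, arma::fill::zeros);

  const bool f32out = f32p(x);
  SEXP gx = R_NilValue;
  float* gxf = nullptr;
  std::vector<float> gx_tmp;
  int nprot = 0;
  if (need_gx) {
    gx = PROTECT(Rf_allocVector(f32out ? INTSXP : REALSXP, XLENGTH(x)));
    ++nprot;
    Rf_setAttrib(gx, R_DimSymbol, Rf_getAttrib(x, R_DimSymbol));
    if (f32out) {
      gxf = reinterpret_cast<float*>(INTEGER(gx));
      std::memset(gxf, 0, XLENGTH(x) * sizeof(float));
    } else {
      gx_tmp.assign(XLENGTH(x), 0.0f);
      gxf = gx_tmp.data();
    }
  }

  int B = (int)std::max((std::size_t)1,
                        std::min((std::size_t)N, 6000000 / (P * K)));
  for (int n0 = 0; n0 < N; n0 += B) {
    const int nb = std::min(B, N - n0);
    arma::fmat col(ws_get(0, (std::size_t)nb * P * K),
                   (std::size_t)nb * P, K, false, true);
    arma::fmat Gy(ws_get(1, (std::size_t)nb * P * Cout),
                  (std::size_t)nb * P, Cout, false, true);
    for (int b = 0; b < nb; ++b) {
      im2col(xp + (std::size_t)(n0 + b) * H * W * C, H, W, C,
             kh, kw, stride, ph, pw, Ho, Wo, col, (std::size_t)b * P);
      const float* gs = gp + (std::size_t)(n0 + b) * P * Cout;
      for (int co = 0; co < Cout; ++co)
        std::memcpy(Gy.colptr(co) + (std::size_t)b * P,
                    gs + (std::size_t)co * P, P * sizeof(float));
    }
    gWm += col.t() * Gy;
    if (need_gx) {
      arma::fmat gcol(ws_get(2, (std::size_t)nb * P * K),
                      (std::size_t)nb * P, K, false, true);
      gcol = Gy * Wm.t();
      for (int b = 0; b < nb; ++b)
        col2im_acc(gxf + (std::size_t)(n0 + b) * H * W * C, H, W, C,
                   kh, kw, stride, ph, pw, Ho, Wo, gcol,
                   (std::size_t)b * P);
    }
  }
  if (need_gx && !f32out) {
    double* gd = REAL(gx);
    const R_xlen_t n = XLENGTH(gx);
    for (R_xlen_t i = 0; i < n; ++i) gd[i] = (double)gxf[i];
  }
  NumericVector gw(no_init(XLENGTH(w)));
  gw.attr("dim") = Rf_getAttrib(w, R_DimSymbol);
  const float* gq = gWm.memptr();
  for (std::size_t i = 0; i < K * (std::size_t)Cout; ++i)
    gw[i] = (double)gq[i];
  List out = List::create(_["gx"] = gx, _["gw"] = gw);
  if (nprot) UNPROTECT(nprot);
  return out;
}
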