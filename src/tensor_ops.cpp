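// Single-pass tensor kernels for batch-norm, ReLU, attention gating and
// the global average pool.
//
// Tensors are R arrays dim (H, W, C, N). Two storage kinds are accepted:
// native double arrays, and float32 tensors packed into R integer vectors
// (4 bytes per element, produced by .to_f32). The training path keeps all
// large activations in float32 — halving memory traffic, which is what
// bounds throughput on one CPU — while parameters and reductions stay in
// double. Each kernel returns the kind it was given.

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

static R_xlen_t dims_of(SEXP x, int* d4) {
  SEXP dim = Rf_getAttrib(x, R_DimSymbol);
  if (Rf_isNull(dim) || Rf_length(dim) != 4)
    stop("expected a 4-d (H, W, C, N) array");
  const int* d = INTEGER(dim);
  R_xlen_t n = 1;
  for (int i = 0; i < 4; ++i) { d4[i] = d[i]; n *= d[i]; }
  return n;
}

static bool is_f32(SEXP x) { return TYPEOF(x) == INTSXP; }

// view or convert an input tensor as float*
static const float* in_f32(SEXP x, std::vector<float>& tmp) {
  if (is_f32(x)) return reinterpret_cast<const float*>(INTEGER(x));
  const double* d = REAL(x);
  const R_xlen_t n = XLENGTH(x);
  tmp.resize(n);
  for (R_xlen_t i = 0; i < n; ++i) tmp[i] = (float)d[i];
  return tmp.data();
}

// allocate an output tensor of the same kind/shape as proto
static SEXP out_like(SEXP proto, float*& fp, double*& dp) {
  SEXP out = PROTECT(Rf_allocVector(TYPEOF(proto), XLENGTH(proto)));
  Rf_setAttrib(out, R_DimSymbol, Rf_getAttrib(proto, R_DimSymbol));
  if (is_f32(proto)) { fp = reinterpret_cast<float*>(INTEGER(out)); dp = nullptr; }
  else { dp = REAL(out); fp = nullptr; }
  UNPROTECT(1);
  return out;
}

static inline void emit(float* fp, double* dp, R_xlen_t i, float v) {
  if (fp) fp[i] = v; else dp[i] = (double)v;
}

// [[Rcpp::export(name = ".to_f32")]]
SEXP to_f32(NumericVector x) {
  IntegerVector out(no_init(x.size()));
  float* p = reinterpret_cast<float*>(INTEGER(out));
  const double* d = x.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) p[i] = (float)d[i];
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export(name = ".from_f32")]]
SEXP from_f32(SEXP x) {
  if (!is_f32(x)) return x;
  const float* p = reinterpret_cast<const float*>(INTEGER(x));
  const R_xlen_t n = XLENGTH(x);
  NumericVector out(no_init(n));
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (double)p[i];
  out.attr("dim") = Rf_getAttrib(x, R_DimSymbol);
  return out;
}

// per-channel sum and sum of squares in one pass (double accumulators)
// [[Rcpp::export(name = ".chan_stats")]]
List chan_stats(SEXP x) {
  int d[4]; dims_of(x, d);
  const R_xlen_t hw = (R_xlen_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  std::vector<float> tmp;
  const float* xp = in_f32(x, tmp);
  NumericVector s(C), sq(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float* xs = xp + ((R_xlen_t)n * C + c) * hw;
      double a = 0, b = 0;
      for (R_xlen_t i = 0; i < hw; ++i) {
        const double v = xs[i];
        a += v; b += v * v;
      }
      s[c] += a; sq[c] += b;
    }
  return List::create(_["sum"] = s, _["sumsq"] = sq);
}

// fused batch-norm + ReLU forward:
// xhat = (x - mu) * istd, h = max(xhat * g + b, 0), one pass
// [[Rcpp::export(name = ".bn_relu_fw")]]
List bn_relu_fw(SEXP x, NumericVector mu, NumericVector istd,
                NumericVector g, NumericVector b) {
  int d[4]; dims_of(x, d);
  const R_xlen_t hw = (R_xlen_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  std::vector<float> tmp;
  const float* xp = in_f32(x, tmp);
  float *xf, *hf; double *xd, *hd;
  SEXP xhat = PROTECT(out_like(x, xf, xd));
  SEXP h = PROTECT(out_like(x, hf, hd));
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float m = (float)mu[c], is = (float)istd[c];
      const float gc = (float)g[c], bc = (float)b[c];
      const R_xlen_t off = ((R_xlen_t)n * C + c) * hw;
      const float* xs = xp + off;
      if (xf) {                                 // branch-free float path
        float* xo = xf + off; float* ho = hf + off;
        for (R_xlen_t i = 0; i < hw; ++i) {
          const float xh = (xs[i] - m) * is;
          xo[i] = xh;
          const float y = xh * gc + bc;
          ho[i] = y > 0 ? y : 0.0f;
        }
      } else {
        for (R_xlen_t i = 0; i < hw; ++i) {
          const float xh = (xs[i] - m) * is;
          xd[off + i] = xh;
          const float y = xh * gc + bc;
          hd[off + i] = y > 0 ? y : 0.0f;
        }
      }
    }
  UNPROTECT(2);
  return List::create(_["xhat"] = xhat, _["h"] = h);
}

// fused backward through ReLU + batch norm (training = batch statistics)
// [[Rcpp::export(name = ".bn_relu_bw")]]
List bn_relu_bw(SEXP gy, SEXP h, SEXP xhat, NumericVector gamma,
                NumericVector istd, bool training) {
  int d[4]; dims_of(gy, d);
  const R_xlen_t hw = (R_xlen_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  std::vector<float> t1, t2, t3;
  const float* gp = in_f32(gy, t1);
  const float* hp = in_f32(h, t2);
  const float* xp = in_f32(xhat, t3);
  NumericVector gg(C), gb(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = ((R_xlen_t)n * C + c) * hw;
      const float* gs = gp + off; const float* hs = hp + off;
      const float* xs = xp + off;
      double a = 0, b = 0;
      for (R_xlen_t i = 0; i < hw; ++i)
        if (hs[i] > 0) { a += (double)gs[i] * xs[i]; b += gs[i]; }
      gg[c] += a; gb[c] += b;
    }
  float* of; double* od;
  SEXP gx = PROTECT(out_like(gy, of, od));
  const double m = (double)hw * N;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float gc = (float)gamma[c], is = (float)istd[c];
      const float ac = training ? (float)(gamma[c] * gg[c] / m) : 0.0f;
      const float bc = training ? (float)(gamma[c] * gb[c] / m) : 0.0f;
      const R_xlen_t off = ((R_xlen_t)n * C + c) * hw;
      const float* gs = gp + off; const float* hs = hp + off;
      const float* xs = xp + off;
      if (of) {
        float* oo = of + off;
        for (R_xlen_t i = 0; i < hw; ++i) {
          const float ga = hs[i] > 0 ? gs[i] * gc : 0.0f;
          oo[i] = (ga - xs[i] * ac - bc) * is;
        }
      } else {
        for (R_xlen_t i = 0; i < hw; ++i) {
          const float ga = hs[i] > 0 ? gs[i] * gc : 0.0f;
          od[off + i] = (double)((ga - xs[i] * ac - bc) * is);
        }
      }
    }
  UNPROTECT(1);
  return List::create(_["gx"] = gx, _["ggamma"] = gg, _["gbeta"] = gb);
}

// [[Rcpp::export(name = ".relu_fw")]]
SEXP relu_fw(SEXP x) {
  std::vector<float> tmp;
  const float* xp = in_f32(x, tmp);
  float* fp; double* dp;
  SEXP y = PROTECT(out_like(x, fp, dp));
  const R_xlen_t n = XLENGTH(x);
  if (fp) for (R_xlen_t i = 0; i < n; ++i) fp[i] = xp[i] > 0 ? xp[i] : 0.0f;
  else for (R_xlen_t i = 0; i < n; ++i) dp[i] = xp[i] > 0 ? xp[i] : 0.0;
  UNPROTECT(1);
  return y;
}

// gy masked by (h > 0)
// [[Rcpp::export(name = ".relu_bw")]]
SEXP relu_bw(SEXP gy, SEXP h) {
  std::vector<float> t1, t2;
  const float* gp = in_f32(gy, t1);
  const float* hp = in_f32(h, t2);
  float* fp; double* dp;
  SEXP y = PROTECT(out_like(gy, fp, dp));
  const R_xlen_t n = XLENGTH(gy);
  if (fp) for (R_xlen_t i = 0; i < n; ++i) fp[i] = hp[i] > 0 ? gp[i] : 0.0f;
  else for (R_xlen_t i = 0; i < n; ++i) dp[i] = hp[i] > 0 ? gp[i] : 0.0;
  UNPROTECT(1);
  return y;
}

// elementwise a + b
// [[Rcpp::export(name = ".tensor_add")]]
SEXP tensor_add(SEXP a, SEXP b) {
  if (XLENGTH(a) != XLENGTH(b)) stop("size mismatch");
  std::vector<float> t1, t2;
  const float* ap = in_f32(a, t1);
  const float* bp = in_f32(b, t2);
  float* fp; double* dp;
  SEXP y = PROTECT(out_like(a, fp, dp));
  const R_xlen_t n = XLENGTH(a);
  if (fp) for (R_xlen_t i = 0; i < n; ++i) fp[i] = ap[i] + bp[i];
  else for (R_xlen_t i = 0; i < n; ++i) dp[i] = (double)(ap[i] + bp[i]);
  UNPROTECT(1);
  return y;
}

// attention gate forward: y = t * (1 + alpha * sigmoid(a2)); also returns M
// [[Rcpp::export(name = ".att_gate_fw")]]
List att_gate_fw(SEXP t, SEXP a2, double alpha) {
  if (XLENGTH(t) != XLENGTH(a2)) stop("size mismatch");
  std::vector<float> t1, t2;
  const float* tp = in_f32(t, t1);
  const float* ap = in_f32(a2, t2);
  float *mf, *yf; double *md, *yd;
  SEXP M = PROTECT(out_like(t, mf, md));
  SEXP y = PROTECT(out_like(t, yf, yd));
  const float al = (float)alpha;
  const R_xlen_t n = XLENGTH(t);
  for (R_xlen_t i = 0; i < n; ++i) {
    const float m = 1.0f / (1.0f + std::exp(-ap[i]));
    emit(mf, md, i, m);
    emit(yf, yd, i, tp[i] * (1.0f + al * m));
  }
  UNPROTECT(2);
  return List::create(_["M"] = M, _["y"] = y);
}

// attention gate backward: gt = gy * (1 + alpha M);
// ga2 = gy * t * alpha * M (1 - M); galpha = sum(gy * t * M)
// [[Rcpp::export(name = ".att_gate_bw")]]
List att_gate_bw(SEXP gy, SEXP t, SEXP M, double alpha) {
  std::vector<float> t1, t2, t3;
  const float* gp = in_f32(gy, t1);
  const float* tp = in_f32(t, t2);
  const float* mp = in_f32(M, t3);
  float *gtf, *gaf; double *gtd, *gad;
  SEXP gt = PROTECT(out_like(gy, gtf, gtd));
  SEXP ga2 = PROTECT(out_like(gy, gaf, gad));
  const float al = (float)alpha;
  double galpha = 0;
  const R_xlen_t n = XLENGTH(gy);
  for (R_xlen_t i = 0; i < n; ++i) {
    const float m = mp[i];
    emit(gtf, gtd, i, gp[i] * (1.0f + al * m));
    const float gtm = gp[i] * tp[i];
    galpha += (double)gtm * m;
    emit(gaf, gad, i, gtm * al * m * (1.0f - m));
  }
  UNPROTECT(2);
  return List::create(_["gt"] = gt, _["ga2"] = ga2, _["galpha"] = galpha);
}

// global average pool: (H, W, C, N) -> (C, N) double means
// [[Rcpp::export(name = ".gap_fw")]]
NumericMatrix gap_fw(SEXP x) {
  int d[4]; dims_of(x, d);
  const R_xlen_t hw = (R_xlen_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  std::vector<float> tmp;
  const float* xp = in_f32(x, tmp);
  NumericMatrix m(C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float* xs = xp + ((R_xlen_t)n * C + c) * hw;
      double acc = 0;
      for (R_xlen_t i = 0; i < hw; ++i) acc += xs[i];
      m(c, n) = acc / hw;
    }
  return m;
}

// expand per-channel values over space: out[., ., c, n] = v[c, n],
// kind/shape taken from proto
// [[Rcpp::export(name = ".gap_expand")]]
SEXP gap_expand(NumericMatrix v, SEXP proto) {
  int d[4]; dims_of(proto, d);
  const R_xlen_t hw = (R_xlen_t)d[0] * d[1];
  const int C = d[2], N = d[3];
  float* fp; double* dp;
  SEXP out = PROTECT(out_like(proto, fp, dp));
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float val = (float)v(c, n);
      const R_xlen_t off = ((R_xlen_t)n * C + c) * hw;
      for (R_xlen_t i = 0; i < hw; ++i) emit(fp, dp, off + i, val);
    }
  UNPROTECT(1);
  return out;
}

#ifdef __GLIBC__
#include <malloc.h>
#endif

// Large tensors are allocated and freed once per layer call; with glibc's
// default mmap threshold every one of them round-trips through mmap/munmap
// and the copy costs a page fault per 4 KiB. Raising the threshold keeps
// these buffers in the heap arena for reuse.
// [[Rcpp::export(name = ".tune_allocator")]]
bool tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
  return true;
#else
  return false;
#endif
}
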