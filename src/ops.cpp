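// Low-level tensor kernels for the detection networks.
// Activation maps are R arrays with dim c(N, C, H, W) (column-major, batch
// fastest). Conv weights have dim c(CO, CI, K, K). All math in double
// precision; matrix products go through Armadillo/BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline R_xlen_t idx4(int i1, int i2, int i3, int i4,
                            int d1, int d2, int d3) {
  return (R_xlen_t)i1 + (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * (i3 + (R_xlen_t)d3 * i4));
}

static void im2col_all(const double* x, int N, int C, int H, int W,
                       int K, int stride, int pad, int HO, int WO,
                       arma::fmat& col) {
  // col is (C*K*K) x (N*HO*WO); column index n + N*(ho + HO*wo)
  col.zeros();
  for (int wo = 0; wo < WO; ++wo) {
    for (int ho = 0; ho < HO; ++ho) {
      for (int n = 0; n < N; ++n) {
        float* cp = col.colptr(n + (R_xlen_t)N * (ho + HO * wo));
        for (int kw = 0; kw < K; ++kw) {
          const int w = wo * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            const int h = ho * stride - pad + kh;
            if (h < 0 || h >= H) continue;
            const double* xc = x + idx4(n, 0, h, w, N, C, H);
            float* cpr = cp + C * (kh + K * kw);
            for (int i = 0; i < C; ++i) cpr[i] = (float)xc[(R_xlen_t)N * i];
          }
        }
      }
    }
  }
}

static arma::fmat weight_to_fmat(const NumericVector& w) {
  IntegerVector wd = w.attr("dim");
  const int CO = wd[0], CI = wd[1], K = wd[2];
  arma::fmat Wm(CO, CI * K * K);
  for (int kw = 0; kw < K; ++kw)
    for (int kh = 0; kh < K; ++kh)
      for (int i = 0; i < CI; ++i)
        for (int o = 0; o < CO; ++o)
          Wm(o, i + CI * (kh + K * kw)) = (float)w[idx4(o, i, kh, kw, CO, CI, K)];
  return Wm;
}

// [[Rcpp::export(name = ".cpp_conv2d_fw")]]
SEXP cpp_conv2d_fw(NumericVector x, NumericVector w,
                   Nullable<NumericVector> bias,
                   int stride, int pad, bool keep_col = false) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int CO = wd[0], CI = wd[1], K = wd[2];
  if (CI != C) stop("conv2d: input has %d channels, kernel expects %d", C, CI);
  const int HO = (H + 2 * pad - K) / stride + 1;
  const int WO = (W + 2 * pad - K) / stride + 1;

  arma::fmat Wm = weight_to_fmat(w);
  arma::fmat* col = new arma::fmat(CI * K * K, (R_xlen_t)N * HO * WO);
  im2col_all(REAL(x), N, C, H, W, K, stride, pad, HO, WO, *col);
  arma::fmat out = Wm * (*col);      // CO x (N*HO*WO)

  NumericVector y(((R_xlen_t)N) * CO * HO * WO);
  y.attr("dim") = IntegerVector::create(N, CO, HO, WO);
  double* yp = REAL(y);
  arma::fvec b;
  bool has_b = bias.isNotNull();
  if (has_b) {
    NumericVector bb(bias.get());
    b = arma::fvec(CO);
    for (int o = 0; o < CO; ++o) b[o] = (float)bb[o];
  }
  for (int wo = 0; wo < WO; ++wo)
    for (int ho = 0; ho < HO; ++ho)
      for (int n = 0; n < N; ++n) {
        const float* oc = out.colptr(n + (R_xlen_t)N * (ho + HO * wo));
        double* yc = yp + idx4(n, 0, ho, wo, N, CO, HO);
        if (has_b)
          for (int o = 0; o < CO; ++o) yc[(R_xlen_t)N * o] = oc[o] + b[o];
        else
          for (int o = 0; o < CO; ++o) yc[(R_xlen_t)N * o] = oc[o];
      }
  if (!keep_col) { delete col; return y; }
  XPtr<arma::fmat> ptr(col, true);
  return List::create(_["y"] = y, _["col"] = ptr);
}

// [[Rcpp::export(name = ".cpp_conv2d_bw")]]
List cpp_conv2d_bw(SEXP col_ptr, IntegerVector xdim, NumericVector w,
                   NumericVector gy, int stride, int pad, bool has_bias,
                   bool need_gx = true) {
  XPtr<arma::fmat> col(col_ptr);
  IntegerVector wd = w.attr("dim"), gd = gy.attr("dim");
  const int N = xdim[0], C = xdim[1], H = xdim[2], W = xdim[3];
  const int CO = wd[0], CI = wd[1], K = wd[2];
  const int HO = gd[2], WO = gd[3];

  arma::fmat gyn(CO, (R_xlen_t)N * HO * WO);
  const double* gp = REAL(gy);
  for (int wo = 0; wo < WO; ++wo)
    for (int ho = 0; ho < HO; ++ho)
      for (int n = 0; n < N; ++n) {
        float* gc = gyn.colptr(n + (R_xlen_t)N * (ho + HO * wo));
        const double* gs = gp + idx4(n, 0, ho, wo, N, CO, HO);
        for (int o = 0; o < CO; ++o) gc[o] = (float)gs[(R_xlen_t)N * o];
      }

  arma::fmat GW = gyn * col->t();
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  for (int kw = 0; kw < K; ++kw)
    for (int kh = 0; kh < K; ++kh)
      for (int i = 0; i < CI; ++i)
        for (int o = 0; o < CO; ++o)
          gw[idx4(o, i, kh, kw, CO, CI, K)] = GW(o, i + CI * (kh + K * kw));

  RObject gb = R_NilValue;
  if (has_bias) {
    arma::fvec GB = arma::sum(gyn, 1);
    NumericVector gbv(CO);
    for (int o = 0; o < CO; ++o) gbv[o] = GB[o];
    gb = gbv;                      // RObject keeps its own protection
  }

  RObject gxs = R_NilValue;
  if (need_gx) {
    arma::fmat Wm = weight_to_fmat(w);
    arma::fmat gcol = Wm.t() * gyn;    // (CI*K*K) x (N*HO*WO)
    NumericVector gx((R_xlen_t)N * C * H * W);
    gx.attr("dim") = xdim;
    double* gxp = REAL(gx);
    const int ld = gcol.n_rows;
    for (int wo = 0; wo < WO; ++wo) {
      for (int ho = 0; ho < HO; ++ho) {
        for (int kw = 0; kw < K; ++kw) {
          const int wp = wo * stride - pad + kw;
          if (wp < 0 || wp >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            const int hp = ho * stride - pad + kh;
            if (hp < 0 || hp >= H) continue;
            const float* gcp = gcol.colptr((R_xlen_t)N * (ho + HO * wo)) +
              (0 + C * (kh + K * kw));
            double* gxs2 = gxp + idx4(0, 0, hp, wp, N, C, H);
            for (int i = 0; i < C; ++i) {
              const float* gci = gcp + i;
              double* gxc = gxs2 + (R_xlen_t)N * i;
              for (int n = 0; n < N; ++n) gxc[n] += gci[n * ld];
            }
          }
        }
      }
    }
    gxs = gx;
  }
  // the column cache is no longer needed after the backward pass
  col->reset();
  return List::create(_["gx"] = gxs, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export(name = ".cpp_maxpool_fw")]]
List cpp_maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int HO = (H + 2 * pad - k) / stride + 1;
  const int WO = (W + 2 * pad - k) / stride + 1;
  NumericVector y(((R_xlen_t)N) * C * HO * WO);
  IntegerVector am(y.size());               // linear index h + H*w of the max
  y.attr("dim") = IntegerVector::create(N, C, HO, WO);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int wo = 0; wo < WO; ++wo)
    for (int ho = 0; ho < HO; ++ho)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double best = R_NegInf; int barg = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int w = wo * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = ho * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              const double v = xp[idx4(n, c, h, w, N, C, H)];
              if (v > best) { best = v; barg = h + H * w; }
            }
          }
          const R_xlen_t oi = idx4(n, c, ho, wo, N, C, HO);
          yp[oi] = best;
          am[oi] = barg;
        }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export(name = ".cpp_maxpool_bw")]]
NumericVector cpp_maxpool_bw(NumericVector gy, IntegerVector argmax,
                             IntegerVector xdim) {
  const int N = xdim[0], C = xdim[1], H = xdim[2];
  IntegerVector gd = gy.attr("dim");
  const int HO = gd[2], WO = gd[3];
  NumericVector gx((R_xlen_t)N * C * H * xdim[3]);
  gx.attr("dim") = xdim;
  double* gxp = REAL(gx);
  const double* gp = REAL(gy);
  for (int wo = 0; wo < WO; ++wo)
    for (int ho = 0; ho < HO; ++ho)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          const R_xlen_t oi = idx4(n, c, ho, wo, N, C, HO);
          const int lin = argmax[oi];
          if (lin < 0) continue;
          const int h = lin % H, w = lin / H;
          gxp[idx4(n, c, h, w, N, C, H)] += gp[oi];
        }
  return gx;
}

// [[Rcpp::export(name = ".cpp_upsample2_fw")]]
NumericVector cpp_upsample2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector y((R_xlen_t)N * C * 2 * H * 2 * W);
  y.attr("dim") = IntegerVector::create(N, C, 2 * H, 2 * W);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int w = 0; w < 2 * W; ++w)
    for (int h = 0; h < 2 * H; ++h)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n)
          yp[idx4(n, c, h, w, N, C, 2 * H)] = xp[idx4(n, c, h / 2, w / 2, N, C, H)];
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample2_bw")]]
NumericVector cpp_upsample2_bw(NumericVector gy) {
  IntegerVector gd = gy.attr("dim");
  const int N = gd[0], C = gd[1], H2 = gd[2], W2 = gd[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector gx((R_xlen_t)N * C * H * W);
  gx.attr("dim") = IntegerVector::create(N, C, H, W);
  double* gxp = REAL(gx);
  const double* gp = REAL(gy);
  for (int w = 0; w < W2; ++w)
    for (int h = 0; h < H2; ++h)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n)
          gxp[idx4(n, c, h / 2, w / 2, N, C, H)] += gp[idx4(n, c, h, w, N, C, H2)];
  return gx;
}

// IEEE 754 binary16 packing, used for half-precision checkpoint size accounting.
static uint16_t double_to_half(double dv) {
  float f = (float)dv;
  uint32_t bits;
  std::memcpy(&bits, &f, 4);
  uint32_t sign = (bits >> 16) & 0x8000u;
  int32_t expo = (int32_t)((bits >> 23) & 0xFF) - 127 + 15;
  uint32_t mant = bits & 0x7FFFFFu;
  if (expo >= 31) return (uint16_t)(sign | 0x7C00u);           // overflow -> inf
  if (expo <= 0) {                                              // subnormal / zero
    if (expo < -10) return (uint16_t)sign;
    mant |= 0x800000u;
    uint32_t shift = (uint32_t)(14 - expo);
    return (uint16_t)(sign | (mant >> shift));
  }
  return (uint16_t)(sign | ((uint32_t)expo << 10) | (mant >> 13));
}

static double half_to_double(uint16_t h) {
  uint32_t sign = (uint32_t)(h & 0x8000u) << 16;
  uint32_t expo = (h >> 10) & 0x1F;
  uint32_t mant = h & 0x3FFu;
  uint32_t bits;
  if (expo == 0) {
    if (mant == 0) bits = sign;
    else {
      int e = -1;
      do { mant <<= 1; ++e; } while (!(mant & 0x400u));
      mant &= 0x3FFu;
      bits = sign | ((uint32_t)(127 - 15 - e) << 23) | (mant << 13);
    }
  } else if (expo == 31) {
    bits = sign | 0x7F800000u | (mant << 13);
  } else {
    bits = sign | ((expo - 15 + 127) << 23) | (mant << 13);
  }
  float f;
  std::memcpy(&f, &bits, 4);
  return (double)f;
}

// [[Rcpp::export(name = ".cpp_pack_half")]]
RawVector cpp_pack_half(NumericVector x) {
  RawVector out(2 * (R_xlen_t)x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    uint16_t h = double_to_half(x[i]);
    out[2 * i] = (Rbyte)(h & 0xFF);
    out[2 * i + 1] = (Rbyte)(h >> 8);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_unpack_half")]]
NumericVector cpp_unpack_half(RawVector r) {
  NumericVector out(r.size() / 2);
  for (R_xlen_t i = 0; i < out.size(); ++i) {
    uint16_t h = (uint16_t)r[2 * i] | ((uint16_t)r[2 * i + 1] << 8);
    out[i] = half_to_double(h);
  }
  return out;
}

// ---- batch norm (training mode) over (N, C, H, W), per-channel ----

// [[Rcpp::export(name = ".cpp_bn_fw")]]
List cpp_bn_fw(NumericVector x, NumericVector gamma, NumericVector beta,
               double eps) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const R_xlen_t per = (R_xlen_t)N * H * W;
  NumericVector mu(C), va(C);
  const double* xp = REAL(x);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        const double* col = xp + idx4(0, c, h, w, N, C, H);
        double s = 0;
        for (int n = 0; n < N; ++n) s += col[n];
        mu[c] += s;
      }
  for (int c = 0; c < C; ++c) mu[c] /= per;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        const double* col = xp + idx4(0, c, h, w, N, C, H);
        double s = 0;
        for (int n = 0; n < N; ++n) { double d = col[n] - mu[c]; s += d * d; }
        va[c] += s;
      }
  for (int c = 0; c < C; ++c) va[c] /= per;
  NumericVector xh(x.size()), y(x.size());
  xh.attr("dim") = xd; y.attr("dim") = xd;
  NumericVector inv(C);
  for (int c = 0; c < C; ++c) inv[c] = 1.0 / std::sqrt(va[c] + eps);
  double* xhp = REAL(xh); double* yp = REAL(y);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        const R_xlen_t off = idx4(0, c, h, w, N, C, H);
        const double m = mu[c], iv = inv[c], g = gamma[c], b = beta[c];
        for (int n = 0; n < N; ++n) {
          double v = (xp[off + n] - m) * iv;
          xhp[off + n] = v;
          yp[off + n] = g * v + b;
        }
      }
  return List::create(_["y"] = y, _["xh"] = xh, _["inv"] = inv,
                      _["mu"] = mu, _["va"] = va);
}

// [[Rcpp::export(name = ".cpp_bn_bw")]]
List cpp_bn_bw(NumericVector xh, NumericVector inv, NumericVector gamma,
               NumericVector gy) {
  IntegerVector xd = xh.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const R_xlen_t per = (R_xlen_t)N * H * W;
  NumericVector ggamma(C), gbeta(C), mg(C), mgx(C);
  const double* xp = REAL(xh); const double* gp = REAL(gy);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        const R_xlen_t off = idx4(0, c, h, w, N, C, H);
        double s1 = 0, s2 = 0;
        for (int n = 0; n < N; ++n) {
          s1 += gp[off + n];
          s2 += gp[off + n] * xp[off + n];
        }
        gbeta[c] += s1; ggamma[c] += s2;
      }
  for (int c = 0; c < C; ++c) {
    mg[c] = gbeta[c] * gamma[c] / per;
    mgx[c] = ggamma[c] * gamma[c] / per;
  }
  NumericVector gx(xh.size());
  gx.attr("dim") = xd;
  double* gxp = REAL(gx);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        const R_xlen_t off = idx4(0, c, h, w, N, C, H);
        const double g = gamma[c], iv = inv[c], m1 = mg[c], m2 = mgx[c];
        for (int n = 0; n < N; ++n)
          gxp[off + n] = (gp[off + n] * g - m1 - xp[off + n] * m2) * iv;
      }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// ---- group norm over (N, C, H, W): statistics per sample and group ----

// [[Rcpp::export(name = ".cpp_gn_fw")]]
List cpp_gn_fw(NumericVector x, NumericVector gamma, NumericVector beta,
               int groups, double eps) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int cpg = C / groups;
  const double per = (double)cpg * H * W;
  NumericMatrix mu(N, groups), inv(N, groups);
  const double* xp = REAL(x);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        const int g = c / cpg;
        const R_xlen_t off = idx4(0, c, h, w, N, C, H);
        for (int n = 0; n < N; ++n) mu(n, g) += xp[off + n];
      }
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) mu(n, g) /= per;
  NumericMatrix va(N, groups);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        const int g = c / cpg;
        const R_xlen_t off = idx4(0, c, h, w, N, C, H);
        for (int n = 0; n < N; ++n) {
          double d = xp[off + n] - mu(n, g);
          va(n, g) += d * d;
        }
      }
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g)
      inv(n, g) = 1.0 / std::sqrt(va(n, g) / per + eps);
  NumericVector xh(x.size()), y(x.size());
  xh.attr("dim") = xd; y.attr("dim") = xd;
  double* xhp = REAL(xh); double* yp = REAL(y);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        const int g = c / cpg;
        const R_xlen_t off = idx4(0, c, h, w, N, C, H);
        const double gm = gamma[c], bt = beta[c];
        for (int n = 0; n < N; ++n) {
          double v = (xp[off + n] - mu(n, g)) * inv(n, g);
          xhp[off + n] = v;
          yp[off + n] = gm * v + bt;
        }
      }
  return List::create(_["y"] = y, _["xh"] = xh, _["inv"] = inv);
}

// [[Rcpp::export(name = ".cpp_gn_bw")]]
List cpp_gn_bw(NumericVector xh, NumericMatrix inv, NumericVector gamma,
               NumericVector gy, int groups) {
  IntegerVector xd = xh.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int cpg = C / groups;
  const double per = (double)cpg * H * W;
  NumericVector ggamma(C), gbeta(C);
  NumericMatrix mg(N, groups), mgx(N, groups);
  const double* xp = REAL(xh); const double* gp = REAL(gy);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        const int g = c / cpg;
        const R_xlen_t off = idx4(0, c, h, w, N, C, H);
        const double gm = gamma[c];
        double s1 = 0, s2 = 0;
        for (int n = 0; n < N; ++n) {
          const double gv = gp[off + n];
          s1 += gv; s2 += gv * xp[off + n];
          mg(n, g) += gv * gm;
          mgx(n, g) += gv * gm * xp[off + n];
        }
        gbeta[c] += s1; ggamma[c] += s2;
      }
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      mg(n, g) /= per; mgx(n, g) /= per;
    }
  NumericVector gx(xh.size());
  gx.attr("dim") = xd;
  double* gxp = REAL(gx);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int c = 0; c < C; ++c) {
        const int g = c / cpg;
        const R_xlen_t off = idx4(0, c, h, w, N, C, H);
        const double gm = gamma[c];
        for (int n = 0; n < N; ++n)
          gxp[off + n] = (gp[off + n] * gm - mg(n, g) -
                          xp[off + n] * mgx(n, g)) * inv(n, g);
      }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// ---- SiLU ----

// [[Rcpp::export(name = ".cpp_silu_fw")]]
NumericVector cpp_silu_fw(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-x[i]));
    y[i] = x[i] * s;
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_silu_bw")]]
NumericVector cpp_silu_bw(NumericVector x, NumericVector gy) {
  NumericVector g(x.size());
  g.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-x[i]));
    g[i] = gy[i] * s * (1.0 + x[i] * (1.0 - s));
  }
  return g;
}


// [[Rcpp::export(name = ".cpp_silu_fw_t")]]
List cpp_silu_fw_t(NumericVector x) {
  NumericVector y(x.size()), s(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double sv = 1.0 / (1.0 + std::exp(-x[i]));
    s[i] = sv;
    y[i] = x[i] * sv;
  }
  return List::create(_["y"] = y, _["s"] = s);
}

// [[Rcpp::export(name = ".cpp_silu_bw_s")]]
NumericVector cpp_silu_bw_s(NumericVector x, NumericVector s,
                            NumericVector gy) {
  NumericVector g(x.size());
  g.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    g[i] = gy[i] * s[i] * (1.0 + x[i] * (1.0 - s[i]));
  return g;
}
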