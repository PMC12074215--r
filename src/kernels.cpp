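#include <Rcpp.h>
#include <cstring>
#include <cmath>
using namespace Rcpp;

// Feature maps are stored in R as (H*W) x C matrices, spatial index
// s = h + H*w (column-major over the image plane, channels in columns).
// im2col produces a (Ho*Wo) x (k*k*C) matrix whose column order is
// (ki + k*kj) + k*k*c, so each channel's k*k patch columns are contiguous
// (required by grouped/depthwise convolution). With this layout the inner
// spatial loop copies contiguous runs.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericMatrix x, int H, int W, int k, int stride,
                         int pad) {
  const int C = x.ncol();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix cols(Ho * Wo, C * k * k);
  const double* xp = REAL(x);
  double* cp = REAL(cols);
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t HoWo = (R_xlen_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + c * HW;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* col = cp + ((R_xlen_t)(ki + k * kj + k * k * c)) * HoWo;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          double* dst = col + (R_xlen_t)wo * Ho;
          if (wi < 0 || wi >= W) continue;
          const double* src = xc + (R_xlen_t)wi * H;
          // valid range of ho: 0 <= ho*stride - pad + ki < H
          int ho0 = 0;
          while (ho0 * stride - pad + ki < 0) ++ho0;
          int ho1 = Ho - 1;
          while (ho1 * stride - pad + ki >= H) --ho1;
          if (ho1 < ho0) continue;
          if (stride == 1) {
            std::memcpy(dst + ho0, src + (ho0 - pad + ki),
                        (ho1 - ho0 + 1) * sizeof(double));
          } else {
            for (int ho = ho0; ho <= ho1; ++ho) {
              dst[ho] = src[ho * stride - pad + ki];
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(NumericMatrix cols, int C, int H, int W, int k,
                         int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix x((R_xlen_t)H * W, C);
  const double* cp = REAL(cols);
  double* xp = REAL(x);
  const R_xlen_t HW = (R_xlen_t)H * W;
  const R_xlen_t HoWo = (R_xlen_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    double* xc = xp + c * HW;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* col = cp + ((R_xlen_t)(ki + k * kj + k * k * c)) * HoWo;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          double* dst = xc + (R_xlen_t)wi * H;
          const double* src = col + (R_xlen_t)wo * Ho;
          int ho0 = 0;
          while (ho0 * stride - pad + ki < 0) ++ho0;
          int ho1 = Ho - 1;
          while (ho1 * stride - pad + ki >= H) --ho1;
          for (int ho = ho0; ho <= ho1; ++ho) {
            dst[ho * stride - pad + ki] += src[ho];
          }
        }
      }
    }
  }
  return x;
}

// Max pooling, stride 1, "same" zero padding (used by SPPF). Returns the
// pooled map and the 0-based argmax spatial index per output cell.
// [[Rcpp::export]]
List cpp_maxpool_same(NumericMatrix x, int H, int W, int k) {
  const int C = x.ncol();
  const int pad = k / 2;
  NumericMatrix y((R_xlen_t)H * W, C);
  IntegerMatrix arg((R_xlen_t)H * W, C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ap = INTEGER(arg);
  const R_xlen_t HW = (R_xlen_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + c * HW;
    double* yc = yp + c * HW;
    int* ac = ap + c * HW;
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double best = -1e300;
        int bi = -1;
        for (int kj = 0; kj < k; ++kj) {
          const int wi = w - pad + kj;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < k; ++ki) {
            const int hi = h - pad + ki;
            if (hi < 0 || hi >= H) continue;
            const double v = xc[hi + H * wi];
            if (v > best) { best = v; bi = hi + H * wi; }
          }
        }
        yc[h + H * w] = best;
        ac[h + H * w] = bi;
      }
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_same_backward(NumericMatrix dy, IntegerMatrix arg) {
  const int C = dy.ncol();
  const R_xlen_t S = dy.nrow();
  NumericMatrix dx(S, C);
  const double* dp = REAL(dy);
  const int* ap = INTEGER(arg);
  double* xp = REAL(dx);
  for (int c = 0; c < C; ++c) {
    const double* dc = dp + c * S;
    const int* ac = ap + c * S;
    double* xc = xp + c * S;
    for (R_xlen_t s = 0; s < S; ++s) {
      if (ac[s] >= 0) xc[ac[s]] += dc[s];
    }
  }
  return dx;
}

// SiLU forward and backward fused in C++ (hot elementwise op)
// [[Rcpp::export]]
NumericMatrix cpp_silu(NumericMatrix x) {
  NumericMatrix y(x.nrow(), x.ncol());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  for (R_xlen_t i = 0; i < n; ++i) {
    yp[i] = xp[i] / (1.0 + std::exp(-xp[i]));
  }
  return y;
}

// [[Rcpp::export]]
NumericMatrix cpp_silu_backward(NumericMatrix x, NumericMatrix dy) {
  NumericMatrix dx(x.nrow(), x.ncol());
  const double* xp = REAL(x);
  const double* dp = REAL(dy);
  double* gp = REAL(dx);
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double s = 1.0 / (1.0 + std::exp(-xp[i]));
    gp[i] = dp[i] * s * (1.0 + xp[i] * (1.0 - s));
  }
  return dx;
}

// Fused batch-norm forward: y = (x - mu) * istd * gamma + beta, per column
// [[Rcpp::export]]
NumericMatrix cpp_bn_forward(NumericMatrix x, NumericVector mu,
                             NumericVector istd, NumericVector gamma,
                             NumericVector beta) {
  const R_xlen_t S = x.nrow();
  const int C = x.ncol();
  NumericMatrix y(S, C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    const double a = istd[c] * gamma[c];
    const double b = beta[c] - mu[c] * a;
    const double* xc = xp + c * S;
    double* yc = yp + c * S;
    for (R_xlen_t s = 0; s < S; ++s) yc[s] = xc[s] * a + b;
  }
  return y;
}

// Fused batch-norm backward (training-mode statistics). Returns
// list(dx, dgamma, dbeta).
// [[Rcpp::export]]
List cpp_bn_backward(NumericMatrix x, NumericMatrix dy, NumericVector mu,
                     NumericVector istd, NumericVector gamma, bool training) {
  const R_xlen_t S = x.nrow();
  const int C = x.ncol();
  NumericMatrix dx(S, C);
  NumericVector dg(C), db(C);
  const double* xp = REAL(x);
  const double* dp = REAL(dy);
  double* op = REAL(dx);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + c * S;
    const double* dc = dp + c * S;
    double* oc = op + c * S;
    const double is = istd[c], g = gamma[c], m = mu[c];
    double s_dy = 0, s_dyxh = 0;
    for (R_xlen_t s = 0; s < S; ++s) {
      const double xh = (xc[s] - m) * is;
      s_dy += dc[s];
      s_dyxh += dc[s] * xh;
    }
    dg[c] = s_dyxh;
    db[c] = s_dy;
    if (training) {
      const double m1 = g * s_dy / S;       // mean of dxhat
      const double m2 = g * s_dyxh / S;     // mean of dxhat * xhat
      for (R_xlen_t s = 0; s < S; ++s) {
        const double xh = (xc[s] - m) * is;
        oc[s] = (dc[s] * g - m1 - xh * m2) * is;
      }
    } else {
      const double a = g * is;
      for (R_xlen_t s = 0; s < S; ++s) oc[s] = dc[s] * a;
    }
  }
  return List::create(_["dx"] = dx, _["dg"] = dg, _["db"] = db);
}

// column means and mean squares in one pass (for the BN statistics)
// [[Rcpp::export]]
List cpp_col_stats(NumericMatrix x) {
  const R_xlen_t S = x.nrow();
  const int C = x.ncol();
  NumericVector mu(C), va(C);
  const double* xp = REAL(x);
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + c * S;
    double s1 = 0, s2 = 0;
    for (R_xlen_t s = 0; s < S; ++s) {
      s1 += xc[s];
      s2 += xc[s] * xc[s];
    }
    mu[c] = s1 / S;
    const double v = s2 / S - mu[c] * mu[c];
    va[c] = v > 0 ? v : 0;
  }
  return List::create(_["mu"] = mu, _["va"] = va);
}
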