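// Numeric kernels for the sequence classifiers and the tracker.
//
// Layout convention for image batches: a numeric array with dim (H, W, C, N),
// column-major, so element (h, w, c, n) sits at h + H*(w + W*(c + C*n)).
// Convolution weights are (F x C*kh*kw) matrices whose column index is
// c*(kh*kw) + ki*kw + kj for kernel offset (ki, kj).
//
// GEMMs run in single precision (arma::fmat): training these models is
// GEMM-bound and float32 is the customary precision for convolutional nets.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Gather im2col patches of x (H,W,C,N) into P (C*kh*kw x Ho*Wo*N), float.
static void im2col(const double* x, int H, int W, int C, int N,
                   int kh, int kw, int s, int p, arma::fmat& P) {
  const int Ho = out_dim(H, kh, s, p), Wo = out_dim(W, kw, s, p);
  P.zeros(C * kh * kw, (size_t)Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        float* pc = P.colptr(col);
        for (int c = 0; c < C; ++c) {
          const size_t base = (size_t)H * (W * ((size_t)c + (size_t)C * n));
          for (int ki = 0; ki < kh; ++ki) {
            const int h = ho * s - p + ki;
            for (int kj = 0; kj < kw; ++kj) {
              const int w = wo * s - p + kj;
              const size_t r = (size_t)c * kh * kw + (size_t)ki * kw + kj;
              if (h >= 0 && h < H && w >= 0 && w < W)
                pc[r] = (float)x[(size_t)h + H * ((size_t)w) + base];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                           int kh, int kw, int s, int p) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int F = w.nrow();
  if (w.ncol() != C * kh * kw) stop("conv weight shape does not match input channels");
  const int Ho = out_dim(H, kh, s, p), Wo = out_dim(W, kw, s, p);
  if (Ho < 1 || Wo < 1) stop("conv output would be empty");

  arma::fmat P;
  im2col(REAL(x), H, W, C, N, kh, kw, s, p, P);
  arma::fmat fW(F, w.ncol());
  std::copy(w.begin(), w.end(), fW.memptr());
  arma::fmat Y = fW * P;  // F x (Ho*Wo*N)

  NumericVector y((size_t)Ho * Wo * F * N);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        const float* yc = Y.colptr(col);
        for (int f = 0; f < F; ++f)
          yp[(size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (f + (size_t)F * n))] =
            (double)yc[f] + b[f];
      }
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericMatrix w, NumericVector dy,
                  int kh, int kw, int s, int p, bool need_dx) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int F = w.nrow();
  const int Ho = out_dim(H, kh, s, p), Wo = out_dim(W, kw, s, p);

  arma::fmat P;
  im2col(REAL(x), H, W, C, N, kh, kw, s, p, P);

  // Regather dy (Ho,Wo,F,N) into (F x Ho*Wo*N)
  arma::fmat dY(F, (size_t)Ho * Wo * N);
  const double* dyp = REAL(dy);
  for (int n = 0; n < N; ++n)
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        float* dc = dY.colptr(col);
        for (int f = 0; f < F; ++f)
          dc[f] = (float)dyp[(size_t)ho +
                             (size_t)Ho * (wo + (size_t)Wo * (f + (size_t)F * n))];
      }

  arma::fmat dW = dY * P.t();
  NumericMatrix dw(F, C * kh * kw);
  std::copy(dW.begin(), dW.end(), dw.begin());
  NumericVector db(F);
  arma::fvec dbf = arma::sum(dY, 1);
  for (int f = 0; f < F; ++f) db[f] = dbf[f];

  NumericVector dx;
  if (need_dx) {
    arma::fmat fW(F, w.ncol());
    std::copy(w.begin(), w.end(), fW.memptr());
    arma::fmat dP = fW.t() * dY;  // (C*kh*kw) x (Ho*Wo*N)
    std::vector<float> dxf((size_t)H * W * C * N, 0.f);
    for (int n = 0; n < N; ++n)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const size_t col = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
          const float* pc = dP.colptr(col);
          for (int c = 0; c < C; ++c) {
            const size_t base = (size_t)H * (W * ((size_t)c + (size_t)C * n));
            for (int ki = 0; ki < kh; ++ki) {
              const int h = ho * s - p + ki;
              if (h < 0 || h >= H) continue;
              for (int kj = 0; kj < kw; ++kj) {
                const int ww = wo * s - p + kj;
                if (ww < 0 || ww >= W) continue;
                dxf[(size_t)h + H * ((size_t)ww) + base] +=
                  pc[(size_t)c * kh * kw + (size_t)ki * kw + kj];
              }
            }
          }
        }
    dx = NumericVector((size_t)H * W * C * N);
    for (size_t i = 0; i < dxf.size(); ++i) dx[i] = dxf[i];
    dx.attr("dim") = d;
  }
  return List::create(_["dw"] = dw, _["db"] = db, _["dx"] = dx);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k, int s, int p) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = out_dim(H, k, s, p), Wo = out_dim(W, k, s, p);
  if (Ho < 1 || Wo < 1) stop("pool output would be empty");
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx(y.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);

  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * ((size_t)c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; size_t bi = 0;
          for (int ki = 0; ki < k; ++ki) {
            const int h = ho * s - p + ki;
            if (h < 0 || h >= H) continue;
            for (int kj = 0; kj < k; ++kj) {
              const int w = wo * s - p + kj;
              if (w < 0 || w >= W) continue;
              const size_t i = (size_t)h + (size_t)H * w + base;
              if (xp[i] > best) { best = xp[i]; bi = i; }
            }
          }
          const size_t oi =
            (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * (c + (size_t)C * n));
          yp[oi] = best;
          idx[oi] = (int)bi + 1;  // 1-based into x

        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  size_t len = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(len);
  double* dxp = REAL(dx);
  const double* dyp = REAL(dy);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dxp[idx[i] - 1] += dyp[i];
  dx.attr("dim") = xdim;
  return dx;
}

// In-place Adam update with bias correction; w, m, v are modified.
// [[Rcpp::export]]
void cpp_adam_step(NumericVector w, NumericVector g, NumericVector m,
                   NumericVector v, double lr, double b1, double b2,
                   double eps, int t) {
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  double* wp = REAL(w); const double* gp = REAL(g);
  double* mp = REAL(m); double* vp = REAL(v);
  const R_xlen_t n = w.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
    wp[i] -= lr * (mp[i] / c1) / (std::sqrt(vp[i] / c2) + eps);
  }
}

// Single-precision matrix product with optional transposes, for the large
// recurrent-input projections (the transpose is fused into the GEMM).
// [[Rcpp::export]]
NumericMatrix cpp_sgemm(NumericMatrix a, NumericMatrix b,
                        bool ta = false, bool tb = false) {
  arma::fmat A(a.nrow(), a.ncol()), B(b.nrow(), b.ncol());
  std::copy(a.begin(), a.end(), A.memptr());
  std::copy(b.begin(), b.end(), B.memptr());
  arma::fmat C;
  if (!ta && !tb) C = A * B;
  else if (ta && !tb) C = A.t() * B;
  else if (!ta && tb) C = A * B.t();
  else C = A.t() * B.t();
  NumericMatrix out(C.n_rows, C.n_cols);
  std::copy(C.begin(), C.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = REAL(x); double* yp = REAL(y);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector x) {
  NumericVector dx(dy.size());
  const double* dp = REAL(dy); const double* xp = REAL(x);
  double* op = REAL(dx);
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = xp[i] > 0 ? dp[i] : 0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// Brute-force integer-shift normalized cross-correlation between two equal-size
// frames. Returns (sx, sy, cc) where b(h + sy, w + sx) best matches a(h, w),
// i.e. the content moved by (+sx, +sy) from a to b. Constant overlaps score
// -Inf; the zero shift is the tie-break default.
// [[Rcpp::export]]
NumericVector cpp_best_shift(NumericMatrix a, NumericMatrix b, int max_shift) {
  const int H = a.nrow(), W = a.ncol();
  if (b.nrow() != H || b.ncol() != W) stop("frames must share dimensions");
  auto ncc = [&](int sx, int sy) -> double {
    int h0 = std::max(0, -sy), h1 = std::min(H, H - sy);
    int w0 = std::max(0, -sx), w1 = std::min(W, W - sx);
    if (h1 - h0 < 3 || w1 - w0 < 3) return -std::numeric_limits<double>::infinity();
    double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0; int n = 0;
    for (int w = w0; w < w1; ++w)
      for (int h = h0; h < h1; ++h) {
        const double va = a(h, w), vb = b(h + sy, w + sx);
        sa += va; sb += vb; saa += va * va; sbb += vb * vb; sab += va * vb; ++n;
      }
    const double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
    if (va <= 1e-12 || vb <= 1e-12) return -std::numeric_limits<double>::infinity();
    return (sab - sa * sb / n) / std::sqrt(va * vb);
  };
  int bx = 0, by = 0;
  double best = ncc(0, 0);
  for (int sy = -max_shift; sy <= max_shift; ++sy)
    for (int sx = -max_shift; sx <= max_shift; ++sx) {
      if (sx == 0 && sy == 0) continue;
      const double cc = ncc(sx, sy);
      if (cc > best) { best = cc; bx = sx; by = sy; }
    }
  return NumericVector::create(bx, by, best);
}
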