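// Convolution and pooling kernels for the reconstruction network.
// Tensors use R column-major layout with dim (H, W, C, N).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-D array (H, W, C, N)");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// im2col for one sample: output K x (Ho*Wo), K = kh*kw*C with row index
// ordered (kh, kw, c) to match the R array layout of the weights.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int row = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              v = xc[hi + (size_t)H * wi];
            col(row, ho + (size_t)Ho * wo) = v;
          }
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& col, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int row = i + kh * (j + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + i;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)H * wi] += col(row, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad) {
  int dx[4]; get_dims(x, dx);
  IntegerVector dw = w.attr("dim"); // (kh, kw, Cin, Cout)
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int kh = dw[0], kw = dw[1], Cin = dw[2], Cout = dw[3];
  if (Cin != C) stop("channel mismatch in conv2d");
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * C;
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat col(K, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    arma::mat Ym(y.begin() + (size_t)n * Ho * Wo * Cout,
                 (size_t)Ho * Wo, Cout, false, true);
    Ym = col.t() * Wm;
    for (int o = 0; o < Cout; ++o) Ym.col(o) += b[o];
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                  int stride, int pad) {
  int dx4[4]; get_dims(x, dx4);
  IntegerVector dw = w.attr("dim");
  int H = dx4[0], W = dx4[1], C = dx4[2], N = dx4[3];
  int kh = dw[0], kw = dw[1], Cout = dw[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int K = kh * kw * C;
  NumericVector dxv((R_xlen_t)H * W * C * N);
  dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dwv((R_xlen_t)kh * kw * C * Cout);
  dwv.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  NumericVector dbv(Cout);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat dWm(dwv.begin(), K, Cout, false, true);
  arma::vec dbm(dbv.begin(), Cout, false, true);
  arma::mat col(K, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col);
    arma::mat dYm(dy.begin() + (size_t)n * Ho * Wo * Cout,
                  (size_t)Ho * Wo, Cout, false, true);
    dWm += col * dYm;
    dbm += arma::sum(dYm, 0).t();
    arma::mat dcol = Wm * dYm.t();
    col2im_acc(dcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
               dxv.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export]]
List nn_maxpool_fw(NumericVector x, int k, int stride, int pad) {
  int d[4]; get_dims(x, d);
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N); // linear index into x
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(n * C + c) * H * W;
      size_t base = (size_t)(n * C + c) * H * W;
      size_t obase = (size_t)(n * C + c) * Ho * Wo;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL; int besti = -1;
          for (int j = 0; j < k; ++j) {
            int wi = wo * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = ho * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              double v = xc[hi + (size_t)H * wi];
              if (v > best) { best = v; besti = hi + H * wi; }
            }
          }
          y[obase + ho + (size_t)Ho * wo] = (besti < 0) ? 0.0 : best;
          idx[obase + ho + (size_t)Ho * wo] = (besti < 0) ? -1 : (int)(base + besti);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_bw(NumericVector dy, IntegerVector idx,
                            IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (R_xlen_t t = 0; t < dy.size(); ++t) {
    int p = idx[t];
    if (p >= 0) dx[p] += dy[t];
  }
  return dx;
}

// In-place Adam update: param, m and v are modified directly (they are
// owned by the training loop).
// [[Rcpp::export]]
void nn_adam_step(NumericVector param, NumericVector grad,
                  NumericVector m, NumericVector v,
                  double lr, double beta1, double beta2, double eps,
                  int t, double wd) {
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  R_xlen_t n = param.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double g = grad[i] + wd * param[i];
    m[i] = beta1 * m[i] + (1.0 - beta1) * g;
    v[i] = beta2 * v[i] + (1.0 - beta2) * g * g;
    param[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
  }
}

// Channel-indexed helpers for (H, W, C, N) arrays flattened as
// (HW) x (C*N): entry i belongs to channel (i / HW) % C.

// Per-channel sums of x and, when y is given, of x*y.
// [[Rcpp::export]]
List nn_chan_sums(NumericVector x, Nullable<NumericVector> y,
                  int HW, int C, int N) {
  NumericVector s1(C), s2(C);
  bool has_y = y.isNotNull();
  NumericVector yy;
  if (has_y) yy = y.get();
  R_xlen_t i = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double a = 0.0, b = 0.0;
      if (has_y) {
        for (int k = 0; k < HW; ++k, ++i) { a += x[i]; b += x[i] * yy[i]; }
      } else {
        for (int k = 0; k < HW; ++k, ++i) { a += x[i]; b += x[i] * x[i]; }
      }
      s1[c] += a; s2[c] += b;
    }
  }
  return List::create(_["s1"] = s1, _["s2"] = s2);
}

// y[i] = x[i] * a[c] + b[c]
// [[Rcpp::export]]
NumericVector nn_chan_affine(NumericVector x, NumericVector a,
                             NumericVector b, int HW, int C, int N) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  R_xlen_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double aa = a[c], bb = b[c];
      for (int k = 0; k < HW; ++k, ++i) y[i] = x[i] * aa + bb;
    }
  return y;
}

// dx[i] = (dy[i] - a1[c] - xhat[i] * a2[c]) * s[c]
// [[Rcpp::export]]
NumericVector nn_bn_bw_fuse(NumericVector dy, NumericVector xhat,
                            NumericVector a1, NumericVector a2,
                            NumericVector s, int HW, int C, int N) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  R_xlen_t i = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double u1 = a1[c], u2 = a2[c], ss = s[c];
      for (int k = 0; k < HW; ++k, ++i)
        dx[i] = (dy[i] - u1 - xhat[i] * u2) * ss;
    }
  return dx;
}

// [[Rcpp::export]]
NumericVector nn_relu(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return y;
}

// dx = dy where y > 0 (y is the ReLU output)
// [[Rcpp::export]]
NumericVector nn_relu_bw(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[i] = y[i] > 0 ? dy[i] : 0.0;
  return dx;
}

// y = x1 + x2 elementwise (residual merge without R allocation chains)
// [[Rcpp::export]]
NumericVector nn_add(NumericVector x1, NumericVector x2) {
  NumericVector y(x1.size());
  y.attr("dim") = x1.attr("dim");
  for (R_xlen_t i = 0; i < x1.size(); ++i) y[i] = x1[i] + x2[i];
  return y;
}
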