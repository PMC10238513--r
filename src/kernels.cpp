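// Dense kernels for the audio CNN. Tensors are R arrays in column-major
// order with dim (C, H, W, N): channel fastest, sample slowest. Convolution
// weights are matrices of shape (C_out, C_in * 9) with row ordering
// r = c_in * 9 + kh * 3 + kw, kh/kw in {0,1,2} indexing the 3x3 offsets
// (dh, dw) = (kh - 1, kw - 1). Stride 1, zero padding 1.
//
// The 3x3 convolution is computed as nine full-batch GEMMs (one per kernel
// offset) followed by boundary-aware shifted accumulation, which keeps all
// arithmetic inside BLAS instead of scalar im2col loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Extract the (Cout x Cin) weight slice for kernel offset (kh, kw).
static arma::mat weight_slice(const arma::mat& W, int Cin, int kh, int kw) {
  arma::mat Wk(W.n_rows, Cin);
  for (int c = 0; c < Cin; ++c) Wk.col(c) = W.col(c * 9 + kh * 3 + kw);
  return Wk;
}

// y(:, h, w, n) += p(:, h + dh, w + dw, n) over the valid region.
// Both y and p have channel count C and spatial grid (H, W, N).
static void shift_add(double* y, const double* p, int C, int H, int W, int N,
                      int dh, int dw) {
  const int h0 = std::max(0, -dh), h1 = H - 1 - std::max(0, dh);
  const int w0 = std::max(0, -dw), w1 = W - 1 - std::max(0, dw);
  if (h1 < h0 || w1 < w0) return;
  const R_xlen_t len = (R_xlen_t)C * (h1 - h0 + 1);
  for (int n = 0; n < N; ++n) {
    for (int w = w0; w <= w1; ++w) {
      double* yp = y + (R_xlen_t)C * (h0 + (R_xlen_t)H * (w + (R_xlen_t)W * n));
      const double* pp = p + (R_xlen_t)C *
        (h0 + dh + (R_xlen_t)H * (w + dw + (R_xlen_t)W * n));
      for (R_xlen_t i = 0; i < len; ++i) yp[i] += pp[i];
    }
  }
}

// xs(:, h, w, n) = x(:, h + dh, w + dw, n) on the valid region, 0 elsewhere.
static void shift_copy(double* xs, const double* x, int C, int H, int W, int N,
                       int dh, int dw) {
  std::fill(xs, xs + (R_xlen_t)C * H * W * N, 0.0);
  const int h0 = std::max(0, -dh), h1 = H - 1 - std::max(0, dh);
  const int w0 = std::max(0, -dw), w1 = W - 1 - std::max(0, dw);
  if (h1 < h0 || w1 < w0) return;
  const R_xlen_t len = (R_xlen_t)C * (h1 - h0 + 1);
  for (int n = 0; n < N; ++n) {
    for (int w = w0; w <= w1; ++w) {
      double* dst = xs + (R_xlen_t)C * (h0 + (R_xlen_t)H * (w + (R_xlen_t)W * n));
      const double* src = x + (R_xlen_t)C *
        (h0 + dh + (R_xlen_t)H * (w + dw + (R_xlen_t)W * n));
      std::copy(src, src + len, dst);
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix wmat, NumericVector b) {
  IntegerVector d = x.attr("dim");
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  const int Cout = wmat.nrow();
  if (wmat.ncol() != C * 9) stop("weight/input channel mismatch");
  const R_xlen_t M = (R_xlen_t)H * W * N;
  arma::mat Wm(wmat.begin(), Cout, C * 9, false);
  arma::mat Xm(x.begin(), C, M, false);

  NumericVector y((R_xlen_t)Cout * M);
  y.attr("dim") = IntegerVector::create(Cout, H, W, N);
  // initialize with the bias
  double* yp = y.begin();
  for (R_xlen_t j = 0; j < M; ++j)
    for (int c = 0; c < Cout; ++c) yp[c + (R_xlen_t)Cout * j] = b[c];

  for (int kh = 0; kh < 3; ++kh) {
    for (int kw = 0; kw < 3; ++kw) {
      arma::mat P = weight_slice(Wm, C, kh, kw) * Xm;   // Cout x M
      shift_add(yp, P.memptr(), Cout, H, W, N, kh - 1, kw - 1);
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericMatrix wmat, NumericVector dy) {
  IntegerVector d = x.attr("dim");
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  const int Cout = wmat.nrow();
  const R_xlen_t M = (R_xlen_t)H * W * N;
  arma::mat Wm(wmat.begin(), Cout, C * 9, false);
  arma::mat DY(dy.begin(), Cout, M, false);

  NumericVector dx(x.size());
  dx.attr("dim") = d;
  NumericMatrix dwmat(Cout, C * 9);
  arma::mat dW(dwmat.begin(), Cout, C * 9, false);
  arma::vec db = arma::sum(DY, 1);

  arma::mat Xs(C, M);                                   // shifted input buffer
  for (int kh = 0; kh < 3; ++kh) {
    for (int kw = 0; kw < 3; ++kw) {
      const int dh = kh - 1, dw_ = kw - 1;
      shift_copy(Xs.memptr(), x.begin(), C, H, W, N, dh, dw_);
      arma::mat dWk = DY * Xs.t();                      // Cout x C
      for (int c = 0; c < C; ++c) dW.col(c * 9 + kh * 3 + kw) = dWk.col(c);
      arma::mat Q = weight_slice(Wm, C, kh, kw).t() * DY;   // C x M
      // dx(:, h + dh, w + dw, n) += Q(:, h, w, n)  <=>  reverse shift-add
      shift_add(dx.begin(), Q.memptr(), C, H, W, N, -dh, -dw_);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dwmat,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 average pooling, stride 2, ceil mode; edge cells average over the
// inputs actually covered (no zero-count padding).
// [[Rcpp::export(name = ".avgpool2_fwd")]]
NumericVector avgpool2_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int C = d[0], H = d[1], W = d[2], N = d[3];
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  NumericVector y((R_xlen_t)C * Ho * Wo * N);
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (R_xlen_t)n * C * H * W;
    double* yp = y.begin() + (R_xlen_t)n * C * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = 2 * wo, wn = std::min(2, W - w0);
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = 2 * ho, hn = std::min(2, H - h0);
        const double inv = 1.0 / (wn * hn);
        for (int c = 0; c < C; ++c) {
          double s = 0.0;
          for (int dw = 0; dw < wn; ++dw)
            for (int dh = 0; dh < hn; ++dh)
              s += xp[c + (R_xlen_t)C * ((h0 + dh) + (R_xlen_t)H * (w0 + dw))];
          yp[c + (R_xlen_t)C * (ho + (R_xlen_t)Ho * wo)] = s * inv;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".avgpool2_bwd")]]
NumericVector avgpool2_bwd(NumericVector dy, int H, int W) {
  IntegerVector d = dy.attr("dim");
  const int C = d[0], Ho = d[1], Wo = d[2], N = d[3];
  NumericVector dx((R_xlen_t)C * H * W * N);
  dx.attr("dim") = IntegerVector::create(C, H, W, N);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + (R_xlen_t)n * C * Ho * Wo;
    double* dxp = dx.begin() + (R_xlen_t)n * C * H * W;
    for (int wo = 0; wo < Wo; ++wo) {
      const int w0 = 2 * wo, wn = std::min(2, W - w0);
      for (int ho = 0; ho < Ho; ++ho) {
        const int h0 = 2 * ho, hn = std::min(2, H - h0);
        const double inv = 1.0 / (wn * hn);
        for (int c = 0; c < C; ++c) {
          const double g = dyp[c + (R_xlen_t)C * (ho + (R_xlen_t)Ho * wo)] * inv;
          for (int dw = 0; dw < wn; ++dw)
            for (int dh = 0; dh < hn; ++dh)
              dxp[c + (R_xlen_t)C * ((h0 + dh) + (R_xlen_t)H * (w0 + dw))] += g;
        }
      }
    }
  }
  return dx;
}

// Time smoothing over feature sequences (C, T, N): max pooling and average
// pooling of size 3, stride 1, padding 1, summed. The average divides by 3
// regardless of padding; the max ignores padded positions. Returns the summed
// output and the argmax offsets needed for the backward pass.
// [[Rcpp::export(name = ".timepool3_fwd")]]
List timepool3_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int C = d[0], T = d[1], N = d[2];
  NumericVector y(x.size());
  y.attr("dim") = d;
  IntegerVector amax(x.size());           // absolute t-index of the max
  amax.attr("dim") = d;
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (R_xlen_t)n * C * T;
    double* yp = y.begin() + (R_xlen_t)n * C * T;
    int* ap = amax.begin() + (R_xlen_t)n * C * T;
    for (int t = 0; t < T; ++t) {
      const int t0 = std::max(0, t - 1), t1 = std::min(T - 1, t + 1);
      for (int c = 0; c < C; ++c) {
        double s = 0.0, m = xp[c + (R_xlen_t)C * t0];
        int mi = t0;
        for (int u = t0; u <= t1; ++u) {
          const double v = xp[c + (R_xlen_t)C * u];
          s += v;
          if (v > m) { m = v; mi = u; }
        }
        yp[c + (R_xlen_t)C * t] = m + s / 3.0;
        ap[c + (R_xlen_t)C * t] = mi;
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".timepool3_bwd")]]
NumericVector timepool3_bwd(NumericVector dy, IntegerVector amax) {
  IntegerVector d = dy.attr("dim");
  const int C = d[0], T = d[1], N = d[2];
  NumericVector dx(dy.size());
  dx.attr("dim") = d;
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + (R_xlen_t)n * C * T;
    const int* ap = amax.begin() + (R_xlen_t)n * C * T;
    double* dxp = dx.begin() + (R_xlen_t)n * C * T;
    for (int t = 0; t < T; ++t) {
      const int t0 = std::max(0, t - 1), t1 = std::min(T - 1, t + 1);
      for (int c = 0; c < C; ++c) {
        const double g = dyp[c + (R_xlen_t)C * t];
        dxp[c + (R_xlen_t)C * ap[c + (R_xlen_t)C * t]] += g;   // max branch
        const double ga = g / 3.0;                              // average
        for (int u = t0; u <= t1; ++u) dxp[c + (R_xlen_t)C * u] += ga;
      }
    }
  }
  return dx;
}
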