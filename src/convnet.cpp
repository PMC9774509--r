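// Dense conv-net kernels. Tensor layout follows R's column-major arrays:
//   activations: dim (H, W, C, N)
//   conv weights: dim (KH, KW, Cin, Cout), bias length Cout
// Convolutions use zero padding; im2col + GEMM via Armadillo.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline arma::mat im2col_one(const double* x, int H, int W, int C,
                                   int KH, int KW, int stride, int pad,
                                   int OH, int OW) {
  arma::mat col(KH * KW * C, OH * OW, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (size_t)H * W * ci;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        int r = kh + KH * (kw + KW * ci);
        for (int ow = 0; ow < OW; ++ow) {
          int wi = ow * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          for (int oh = 0; oh < OH; ++oh) {
            int hi = oh * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            col(r, oh + OH * ow) = xc[hi + H * wi];
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: channel mismatch");
  int OH = (H + 2 * pad - KH) / stride + 1;
  int OW = (W + 2 * pad - KW) / stride + 1;
  if (OH < 1 || OW < 1) stop("conv2d: output size < 1");
  arma::mat Wm(const_cast<double*>(w.begin()), KH * KW * Cin, Cout, false);
  NumericVector y = alloc4(OH, OW, Cout, N);
  arma::vec bv(const_cast<double*>(b.begin()), Cout, false);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col_one(x.begin() + (size_t)H * W * C * n,
                               H, W, C, KH, KW, stride, pad, OH, OW);
    arma::mat ym = Wm.t() * col;            // Cout x (OH*OW)
    ym.each_col() += bv;
    double* yn = y.begin() + (size_t)OH * OW * Cout * n;
    for (int co = 0; co < Cout; ++co)
      for (int q = 0; q < OH * OW; ++q)
        yn[q + (size_t)OH * OW * co] = ym(co, q);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int KH = wd[0], KW = wd[1], Cin = wd[2], Cout = wd[3];
  int OH = yd[0], OW = yd[1];
  arma::mat Wm(const_cast<double*>(w.begin()), KH * KW * Cin, Cout, false);
  NumericVector dx = alloc4(H, W, C, N);
  arma::mat dW(KH * KW * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col_one(x.begin() + (size_t)H * W * C * n,
                               H, W, C, KH, KW, stride, pad, OH, OW);
    const double* dyn = dy.begin() + (size_t)OH * OW * Cout * n;
    arma::mat dym(Cout, OH * OW);
    for (int co = 0; co < Cout; ++co)
      for (int q = 0; q < OH * OW; ++q)
        dym(co, q) = dyn[q + (size_t)OH * OW * co];
    dW += col * dym.t();
    db += arma::sum(dym, 1);
    arma::mat dcol = Wm * dym;              // (KH*KW*Cin) x (OH*OW)
    double* dxn = dx.begin() + (size_t)H * W * C * n;
    for (int ci = 0; ci < C; ++ci) {
      double* dxc = dxn + (size_t)H * W * ci;
      for (int kw = 0; kw < KW; ++kw)
        for (int kh = 0; kh < KH; ++kh) {
          int r = kh + KH * (kw + KW * ci);
          for (int ow = 0; ow < OW; ++ow) {
            int wi = ow * stride - pad + kw;
            if (wi < 0 || wi >= W) continue;
            for (int oh = 0; oh < OH; ++oh) {
              int hi = oh * stride - pad + kh;
              if (hi < 0 || hi >= H) continue;
              dxc[hi + H * wi] += dcol(r, oh + OH * ow);
            }
          }
        }
    }
  }
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = IntegerVector::create(KH, KW, Cin, Cout);
  return List::create(_["dx"] = dx, _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, int win, int stride) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int OH = (H - win) / stride + 1, OW = (W - win) / stride + 1;
  if (OH < 1 || OW < 1) stop("maxpool: output size < 1");
  NumericVector y = alloc4(OH, OW, C, N);
  IntegerVector idx = alloc4i(OH, OW, C, N); // 0-based flat index into x
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh) {
          double best = -INFINITY; int bi = -1;
          for (int kw = 0; kw < win; ++kw)
            for (int kh = 0; kh < win; ++kh) {
              int hi = oh * stride + kh, wi = ow * stride + kw;
              double v = xc[hi + H * wi];
              if (v > best) { best = v; bi = hi + H * wi; }
            }
          size_t o = (size_t)oh + OH * (ow + (size_t)OW * (c + (size_t)C * n));
          y[o] = best;
          idx[o] = (int)(base + bi);
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(NumericVector dy, IntegerVector idx,
                                   IntegerVector xdim) {
  size_t tot = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx((R_xlen_t)tot);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}
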