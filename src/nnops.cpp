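// Minimal 2D convolution primitives for the neural estimators.
// Tensor layout everywhere: column-major R arrays (H, W, C, N).
// Convolutions are implemented as im2col / col2im plus GEMM, which maps
// the whole cost onto BLAS.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// im2col for one image x (H x W x C) -> (k*k*C) x (Ho*Wo),
// rows ordered (ki, kj, c), columns ordered (ho fastest, wo).
static void im2col(const double* x, int H, int W, int C, int k, int stride,
                   int pad, int Ho, int Wo, arma::mat& cols) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int row = ki + k * (kj + k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          int col0 = wo * Ho;
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) cols(row, col0 + ho) = 0.0;
            continue;
          }
          const double* xcw = xc + (size_t)wi * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki;
            cols(row, col0 + ho) = (hi >= 0 && hi < H) ? xcw[hi] : 0.0;
          }
        }
      }
    }
  }
}

// adjoint of im2col: accumulate columns back into an (H x W x C) image
static void col2im(const arma::mat& cols, int H, int W, int C, int k,
                   int stride, int pad, int Ho, int Wo, double* x) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int row = ki + k * (kj + k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          double* xcw = xc + (size_t)wi * H;
          int col0 = wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + ki;
            if (hi >= 0 && hi < H) xcw[hi] += cols(row, col0 + ho);
          }
        }
      }
    }
  }
}

static IntegerVector dim4(const NumericVector& a) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 4) stop("expected a 4D array");
  return d;
}

// forward convolution; w is (k, k, Cin, Cout), b length Cout
// [[Rcpp::export]]
NumericVector nn_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad) {
  IntegerVector xd = dim4(x), wd = dim4(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("channel mismatch");
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), k * k * C, Cout, false, true);
  arma::mat cols(k * k * C, Ho * Wo);
  for (int im = 0; im < N; ++im) {
    im2col(x.begin() + (size_t)im * H * W * C, H, W, C, k, stride, pad,
           Ho, Wo, cols);
    arma::mat Ym(y.begin() + (size_t)im * Ho * Wo * Cout, Ho * Wo, Cout,
                 false, true);
    Ym = cols.t() * Wm;
    for (int c = 0; c < Cout; ++c) Ym.col(c) += b[c];
  }
  return y;
}

// backward convolution: returns list(gx, gw, gb)
// [[Rcpp::export]]
List nn_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                  int stride, int pad) {
  IntegerVector xd = dim4(x), wd = dim4(w), gd = dim4(gy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int Ho = gd[0], Wo = gd[1];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  NumericVector gw((size_t)k * k * C * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat Wm(w.begin(), k * k * C, Cout, false, true);
  arma::mat Gw(gw.begin(), k * k * C, Cout, false, true);
  arma::mat cols(k * k * C, Ho * Wo);
  for (int im = 0; im < N; ++im) {
    im2col(x.begin() + (size_t)im * H * W * C, H, W, C, k, stride, pad,
           Ho, Wo, cols);
    arma::mat Gm((double*)gy.begin() + (size_t)im * Ho * Wo * Cout,
                 Ho * Wo, Cout, false, true);
    Gw += cols * Gm;
    for (int c = 0; c < Cout; ++c) gb[c] += arma::accu(Gm.col(c));
    arma::mat gcols = Wm * Gm.t();
    col2im(gcols, H, W, C, k, stride, pad, Ho, Wo,
           gx.begin() + (size_t)im * H * W * C);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// forward transposed convolution; w is (k, k, Cout, Cin), b length Cout.
// Output size Ho = (H-1)*stride - 2*pad + k + opad.
// [[Rcpp::export]]
NumericVector nn_convt2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad, int opad) {
  IntegerVector xd = dim4(x), wd = dim4(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[2];
  if (wd[3] != C) stop("channel mismatch");
  int Ho = (H - 1) * stride - 2 * pad + k + opad;
  int Wo = (W - 1) * stride - 2 * pad + k + opad;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wm(w.begin(), k * k * Cout, C, false, true);
  for (int im = 0; im < N; ++im) {
    arma::mat Xm((double*)x.begin() + (size_t)im * H * W * C, H * W, C,
                 false, true);
    arma::mat cols = Wm * Xm.t();  // (k*k*Cout) x (H*W)
    double* yp = y.begin() + (size_t)im * Ho * Wo * Cout;
    col2im(cols, Ho, Wo, Cout, k, stride, pad, H, W, yp);
    arma::mat Ym(yp, Ho * Wo, Cout, false, true);
    for (int c = 0; c < Cout; ++c) Ym.col(c) += b[c];
  }
  return y;
}

// backward transposed convolution: returns list(gx, gw, gb)
// [[Rcpp::export]]
List nn_convt2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  IntegerVector xd = dim4(x), wd = dim4(w), gd = dim4(gy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[2];
  int Ho = gd[0], Wo = gd[1];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  NumericVector gw((size_t)k * k * Cout * C);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat Wm(w.begin(), k * k * Cout, C, false, true);
  arma::mat Gw(gw.begin(), k * k * Cout, C, false, true);
  arma::mat gcols(k * k * Cout, H * W);
  for (int im = 0; im < N; ++im) {
    im2col(gy.begin() + (size_t)im * Ho * Wo * Cout, Ho, Wo, Cout, k, stride,
           pad, H, W, gcols);
    arma::mat Xm((double*)x.begin() + (size_t)im * H * W * C, H * W, C,
                 false, true);
    Gw += gcols * Xm;
    arma::mat Gm((double*)gy.begin() + (size_t)im * Ho * Wo * Cout,
                 Ho * Wo, Cout, false, true);
    for (int c = 0; c < Cout; ++c) gb[c] += arma::accu(Gm.col(c));
    arma::mat Gx = gcols.t() * Wm;  // (H*W) x C
    std::copy(Gx.begin(), Gx.end(), gx.begin() + (size_t)im * H * W * C);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
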