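// 2-D convolution kernels (im2col + GEMM), the only compiled hot path.
// Array layout follows R column-major convention: images are (H, W, C, B),
// kernels are (kh, kw, Cin, Cout). Patches for the whole batch are unrolled
// into one (N*B, K) matrix so each convolution is a single GEMM.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col, int rowOffset) {
  const int N = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int k = ki + kh * (kj + kw * c);
        double* ck = col.colptr(k) + rowOffset;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          double* dst = ck + (size_t)Ho * wo;
          if (wi < 0 || wi >= W) {
            std::fill(dst, dst + Ho, 0.0);
          } else if (stride == 1) {
            const double* xcol = xc + (size_t)wi * H;
            const int off = ki - pad;      // hi = ho + off
            int lo = std::max(0, -off), up = std::min(Ho, H - off);
            if (lo > 0) std::fill(dst, dst + lo, 0.0);
            if (up > lo) std::copy(xcol + lo + off, xcol + up + off, dst + lo);
            if (up < Ho) std::fill(dst + std::max(up, lo), dst + Ho, 0.0);
          } else {
            const double* xcol = xc + (size_t)wi * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + ki;
              dst[ho] = (hi >= 0 && hi < H) ? xcol[hi] : 0.0;
            }
          }
        }
      }
    }
    (void)N;
  }
}

static void col2im_add(double* x, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       int Ho, int Wo, const arma::mat& col, int rowOffset) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int k = ki + kh * (kj + kw * c);
        const double* ck = col.colptr(k) + rowOffset;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)wi * H;
          const double* src = ck + (size_t)Ho * wo;
          if (stride == 1) {
            const int off = ki - pad;
            int lo = std::max(0, -off), up = std::min(Ho, H - off);
            double* xd = xcol + off;
            for (int ho = lo; ho < up; ++ho) xd[ho] += src[ho];
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + ki;
              if (hi >= 0 && hi < H) xcol[hi] += src[ho];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector convForwardC(NumericVector x, NumericVector w, NumericVector bias,
                           int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != C) stop("channel mismatch between input and kernel");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C, N = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(N, K);
  NumericVector out((R_xlen_t)N * Cout * B);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (size_t)b * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col, 0);
    arma::mat o(out.begin() + (size_t)b * N * Cout, N, Cout, false, true);
    o = col * Wm;
    for (int c = 0; c < Cout; ++c) {
      const double bc = bias[c];
      double* dst = out.begin() + (size_t)b * N * Cout + (size_t)c * N;
      for (int n = 0; n < N; ++n) dst[n] += bc;
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  return out;
}

// [[Rcpp::export]]
List convBackwardC(NumericVector x, NumericVector w, NumericVector gout,
                   int stride, int pad, bool needGx) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector gd = gout.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = gd[0], Wo = gd[1];
  const int K = kh * kw * C, N = Ho * Wo;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector gw((R_xlen_t)K * Cout);
  NumericVector gb(Cout);
  arma::mat gWm(gw.begin(), K, Cout, false, true);
  arma::mat col(N, K);
  NumericVector gx(needGx ? (R_xlen_t)H * W * C * B : 0);
  for (int b = 0; b < B; ++b) {
    const double* gp = gout.begin() + (size_t)b * N * Cout;
    arma::mat Gb(const_cast<double*>(gp), N, Cout, false, true);
    im2col(x.begin() + (size_t)b * H * W * C, H, W, C, kh, kw, stride, pad,
           Ho, Wo, col, 0);
    gWm += col.t() * Gb;
    for (int c = 0; c < Cout; ++c) gb[c] += arma::accu(Gb.col(c));
    if (needGx) {
      arma::mat gcol = Gb * Wm.t();        // (N, K)
      col2im_add(gx.begin() + (size_t)b * H * W * C, H, W, C, kh, kw, stride,
                 pad, Ho, Wo, gcol, 0);
    }
  }
  gw.attr("dim") = wd;
  if (!needGx)
    return List::create(_["gx"] = R_NilValue, _["gw"] = gw, _["gb"] = gb);
  gx.attr("dim") = xd;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
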