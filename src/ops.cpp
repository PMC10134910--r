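// Small elementwise / broadcast helpers for the autodiff hot path.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector leakyFwdC(NumericVector x, double slope) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double v = x[i];
    y[i] = v > 0 ? v : slope * v;
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector leakyBwdC(NumericVector g, NumericVector x, double slope) {
  NumericVector gx(g.size());
  for (R_xlen_t i = 0; i < g.size(); ++i)
    gx[i] = x[i] > 0 ? g[i] : slope * g[i];
  gx.attr("dim") = g.attr("dim");
  return gx;
}

// broadcast a length-C vector over (H, W, C, B)
// [[Rcpp::export]]
NumericVector bcChannelC(NumericVector v, int HW, int C, int B) {
  NumericVector out((R_xlen_t)HW * C * B);
  double* o = out.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double val = v[c];
      std::fill(o, o + HW, val);
      o += HW;
    }
  return out;
}

// channel-wise sum of (H, W, C, B) -> length C
// [[Rcpp::export]]
NumericVector channelSumC(NumericVector x, int HW, int C, int B) {
  NumericVector out(C);
  const double* p = x.begin();
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      double s = 0;
      for (int i = 0; i < HW; ++i) s += p[i];
      out[c] += s;
      p += HW;
    }
  return out;
}

// broadcast a (C, B) matrix over (H, W, C, B)
// [[Rcpp::export]]
NumericVector bcInstC(NumericVector m, int HW) {
  const R_xlen_t CB = m.size();
  NumericVector out((R_xlen_t)HW * CB);
  double* o = out.begin();
  for (R_xlen_t j = 0; j < CB; ++j) {
    std::fill(o, o + HW, m[j]);
    o += HW;
  }
  return out;
}

// per (channel, sample) sum of (H, W, C, B) -> (C, B)
// [[Rcpp::export]]
NumericVector instSumC(NumericVector x, int HW, int C, int B) {
  NumericVector out((R_xlen_t)C * B);
  const double* p = x.begin();
  for (R_xlen_t j = 0; j < (R_xlen_t)C * B; ++j) {
    double s = 0;
    for (int i = 0; i < HW; ++i) s += p[i];
    out[j] = s;
    p += HW;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector fillValueC(double v, R_xlen_t n) {
  NumericVector out(n, v);
  return out;
}

// concatenate (H, W, Ci, B) arrays along the channel axis
// [[Rcpp::export]]
NumericVector concatChannelsC(List xs) {
  const int n = xs.size();
  std::vector<NumericVector> vs(n);
  std::vector<int> cs(n);
  IntegerVector d0 = as<NumericVector>(xs[0]).attr("dim");
  const int H = d0[0], W = d0[1], B = d0[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  int Ctot = 0;
  for (int i = 0; i < n; ++i) {
    vs[i] = as<NumericVector>(xs[i]);
    IntegerVector di = vs[i].attr("dim");
    cs[i] = di[2];
    Ctot += cs[i];
  }
  NumericVector out(HW * Ctot * B);
  for (int b = 0; b < B; ++b) {
    R_xlen_t at = (R_xlen_t)b * HW * Ctot;
    for (int i = 0; i < n; ++i) {
      const double* src = vs[i].begin() + (R_xlen_t)b * HW * cs[i];
      std::copy(src, src + HW * cs[i], out.begin() + at);
      at += HW * cs[i];
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, Ctot, B);
  return out;
}

// extract a contiguous channel range [from, from + n - 1] (1-based)
// [[Rcpp::export]]
NumericVector sliceChannelsC(NumericVector x, int from, int n) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector out(HW * n * B);
  for (int b = 0; b < B; ++b) {
    const double* src = x.begin() + (R_xlen_t)b * HW * C + (R_xlen_t)(from - 1) * HW;
    std::copy(src, src + HW * n, out.begin() + (R_xlen_t)b * HW * n);
  }
  out.attr("dim") = IntegerVector::create(H, W, n, B);
  return out;
}

// scatter a channel block back into a zero array of the original shape
// [[Rcpp::export]]
NumericVector unsliceChannelsC(NumericVector g, int from, int C) {
  IntegerVector d = g.attr("dim");
  const int H = d[0], W = d[1], n = d[2], B = d[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector out(HW * C * B);
  for (int b = 0; b < B; ++b) {
    const double* src = g.begin() + (R_xlen_t)b * HW * n;
    std::copy(src, src + HW * n,
              out.begin() + (R_xlen_t)b * HW * C + (R_xlen_t)(from - 1) * HW);
  }
  out.attr("dim") = IntegerVector::create(H, W, C, B);
  return out;
}
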