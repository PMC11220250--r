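#include <Rcpp.h>
using namespace Rcpp;

// Tensor layout throughout: column-major R arrays with dims
//   x  : (Cin,  H, W, B)   feature maps, spatial rows (EEG channels),
//                          spatial cols (time samples), batch
//   w  : (Cout, Cin/groups, KH, KW)
//   y  : (Cout, Ho, Wo, B)
// Cross-correlation (no kernel flip), stride 1, zero padding given per side.
// Grouped convolution covers depthwise layers (groups == Cin).
//
// All three kernels are written in an axpy/dot formulation: the innermost
// loop runs contiguously over the output maps of one group (y and w are
// both contiguous in that index), and the padding bounds are hoisted out of
// the hot loops, so the compiler can vectorize.

static inline int out_len(int n, int plo, int phi, int k) {
  return n + plo + phi - k + 1;
}

static inline void valid_range(int p_lo, int k_idx, int n_in, int n_out,
                               int &lo, int &hi) {
  // output positions j with 0 <= j - p_lo + k_idx < n_in
  lo = p_lo - k_idx;
  if (lo < 0) lo = 0;
  hi = n_in - 1 + p_lo - k_idx;
  if (hi > n_out - 1) hi = n_out - 1;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w, NumericVector bias,
                         int ph_lo, int ph_hi, int pw_lo, int pw_hi,
                         int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int Ci = xd[0], H = xd[1], W = xd[2], B = xd[3];
  const int Co = wd[0], Cig = wd[1], KH = wd[2], KW = wd[3];
  const int Ho = out_len(H, ph_lo, ph_hi, KH);
  const int Wo = out_len(W, pw_lo, pw_hi, KW);
  const int Cog = Co / groups;
  NumericVector y(static_cast<R_xlen_t>(Co) * Ho * Wo * B);
  y.attr("dim") = IntegerVector::create(Co, Ho, Wo, B);
  const double *px = x.begin(), *pw = w.begin(), *pb = bias.begin();
  double *py = y.begin();

  // initialize with bias
  for (R_xlen_t pos = 0; pos < static_cast<R_xlen_t>(Ho) * Wo * B; ++pos) {
    double *yo = py + pos * Co;
    for (int o = 0; o < Co; ++o) yo[o] = pb[o];
  }

  for (int b = 0; b < B; ++b)
    for (int kw = 0; kw < KW; ++kw) {
      int wlo, whi;
      valid_range(pw_lo, kw, W, Wo, wlo, whi);
      for (int kh = 0; kh < KH; ++kh) {
        int hlo, hhi;
        valid_range(ph_lo, kh, H, Ho, hlo, hhi);
        for (int g = 0; g < groups; ++g)
          for (int il = 0; il < Cig; ++il) {
            const double *wg = pw + g * Cog +
              (static_cast<R_xlen_t>(kw) * KH + kh) * Cig * Co +
              static_cast<R_xlen_t>(il) * Co;
            for (int wo = wlo; wo <= whi; ++wo) {
              const int wi = wo - pw_lo + kw;
              for (int ho = hlo; ho <= hhi; ++ho) {
                const int hi = ho - ph_lo + kh;
                const double s =
                  px[((static_cast<R_xlen_t>(b) * W + wi) * H + hi) * Ci +
                     g * Cig + il];
                double *yo = py +
                  ((static_cast<R_xlen_t>(b) * Wo + wo) * Ho + ho) * Co +
                  g * Cog;
                for (int ol = 0; ol < Cog; ++ol) yo[ol] += s * wg[ol];
              }
            }
          }
      }
    }
  return y;
}

// Gradient of the loss w.r.t. the convolution input.
// [[Rcpp::export]]
NumericVector cpp_conv2d_grad_input(NumericVector dy, NumericVector w,
                                    int H, int W,
                                    int ph_lo, int ph_hi, int pw_lo, int pw_hi,
                                    int groups) {
  IntegerVector yd = dy.attr("dim"), wd = w.attr("dim");
  const int Co = yd[0], Ho = yd[1], Wo = yd[2], B = yd[3];
  const int Cig = wd[1], KH = wd[2], KW = wd[3];
  const int Cog = Co / groups;
  const int Ci = Cig * groups;
  NumericVector dx(static_cast<R_xlen_t>(Ci) * H * W * B);
  dx.attr("dim") = IntegerVector::create(Ci, H, W, B);
  const double *pdy = dy.begin(), *pw = w.begin();
  double *pdx = dx.begin();

  for (int b = 0; b < B; ++b)
    for (int kw = 0; kw < KW; ++kw) {
      int wlo, whi;
      valid_range(pw_lo, kw, W, Wo, wlo, whi);
      for (int kh = 0; kh < KH; ++kh) {
        int hlo, hhi;
        valid_range(ph_lo, kh, H, Ho, hlo, hhi);
        for (int g = 0; g < groups; ++g)
          for (int il = 0; il < Cig; ++il) {
            const double *wg = pw + g * Cog +
              (static_cast<R_xlen_t>(kw) * KH + kh) * Cig * Co +
              static_cast<R_xlen_t>(il) * Co;
            for (int wo = wlo; wo <= whi; ++wo) {
              const int wi = wo - pw_lo + kw;
              for (int ho = hlo; ho <= hhi; ++ho) {
                const int hi = ho - ph_lo + kh;
                const double *dyo = pdy +
                  ((static_cast<R_xlen_t>(b) * Wo + wo) * Ho + ho) * Co +
                  g * Cog;
                double acc = 0.0;
                for (int ol = 0; ol < Cog; ++ol) acc += wg[ol] * dyo[ol];
                pdx[((static_cast<R_xlen_t>(b) * W + wi) * H + hi) * Ci +
                    g * Cig + il] += acc;
              }
            }
          }
      }
    }
  return dx;
}

// Gradient of the loss w.r.t. the convolution weights.
// [[Rcpp::export]]
NumericVector cpp_conv2d_grad_weights(NumericVector x, NumericVector dy,
                                      int KH, int KW,
                                      int ph_lo, int ph_hi,
                                      int pw_lo, int pw_hi, int groups) {
  IntegerVector xd = x.attr("dim"), yd = dy.attr("dim");
  const int Ci = xd[0], H = xd[1], W = xd[2], B = xd[3];
  const int Co = yd[0], Ho = yd[1], Wo = yd[2];
  const int Cig = Ci / groups, Cog = Co / groups;
  NumericVector dw(static_cast<R_xlen_t>(Co) * Cig * KH * KW);
  dw.attr("dim") = IntegerVector::create(Co, Cig, KH, KW);
  const double *px = x.begin(), *pdy = dy.begin();
  double *pdw = dw.begin();

  for (int b = 0; b < B; ++b)
    for (int kw = 0; kw < KW; ++kw) {
      int wlo, whi;
      valid_range(pw_lo, kw, W, Wo, wlo, whi);
      for (int kh = 0; kh < KH; ++kh) {
        int hlo, hhi;
        valid_range(ph_lo, kh, H, Ho, hlo, hhi);
        for (int g = 0; g < groups; ++g)
          for (int il = 0; il < Cig; ++il) {
            double *dwg = pdw + g * Cog +
              (static_cast<R_xlen_t>(kw) * KH + kh) * Cig * Co +
              static_cast<R_xlen_t>(il) * Co;
            for (int wo = wlo; wo <= whi; ++wo) {
              const int wi = wo - pw_lo + kw;
              for (int ho = hlo; ho <= hhi; ++ho) {
                const int hi = ho - ph_lo + kh;
                const double s =
                  px[((static_cast<R_xlen_t>(b) * W + wi) * H + hi) * Ci +
                     g * Cig + il];
                const double *dyo = pdy +
                  ((static_cast<R_xlen_t>(b) * Wo + wo) * Ho + ho) * Co +
                  g * Cog;
                for (int ol = 0; ol < Cog; ++ol) dwg[ol] += s * dyo[ol];
              }
            }
          }
      }
    }
  return dw;
}
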