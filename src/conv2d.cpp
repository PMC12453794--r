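// 2-D convolution kernels (forward + backward) via im2col and BLAS GEMM.
// Tensors are R arrays with dim (N, C, H, W), column-major, so the linear
// index of element (n, c, h, w) is n + N*(c + C*(h + H*w)) (all 0-based).
// Weights are arrays with dim (OC, ICg, KH, KW) where ICg = IC / groups;
// viewed as an OC x (ICg*KH*KW) matrix this layout matches the im2col rows.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// Fill `col` (ICg*KH*KW x N*OH*OW) with patches of input group g.
static void im2col_group(const double* x, int N, int C, int H, int W,
                         int ICg, int KH, int KW, int stride, int pad,
                         int OH, int OW, int g, arma::mat& col) {
  const int J = N * OH * OW;
  col.zeros();
  for (int ow = 0; ow < OW; ++ow) {
    for (int oh = 0; oh < OH; ++oh) {
      for (int n = 0; n < N; ++n) {
        const int j = n + N * (oh + OH * ow);
        double* cj = col.colptr(j);
        for (int kw = 0; kw < KW; ++kw) {
          const int w = ow * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < KH; ++kh) {
            const int h = oh * stride - pad + kh;
            if (h < 0 || h >= H) continue;
            for (int ic = 0; ic < ICg; ++ic) {
              const int c = g * ICg + ic;
              cj[ic + ICg * (kh + KH * kw)] =
                x[n + (size_t)N * (c + (size_t)C * (h + (size_t)H * w))];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias,
                             int stride, int pad, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int OC = wd[0], ICg = wd[1], KH = wd[2], KW = wd[3];
  if (C != ICg * groups) stop("conv2d: input channels (%d) != kernel channels (%d) * groups (%d)", C, ICg, groups);
  if (OC % groups != 0) stop("conv2d: output channels not divisible by groups");
  const int OH = out_size(H, KH, stride, pad), OW = out_size(W, KW, stride, pad);
  if (OH < 1 || OW < 1) stop("conv2d: spatial input too small for kernel/stride/padding");
  const int OCg = OC / groups, J = N * OH * OW, R = ICg * KH * KW;

  NumericVector y(N * (size_t)OC * OH * OW);
  y.attr("dim") = IntegerVector::create(N, OC, OH, OW);
  double* yp = y.begin();
  const double* bp = nullptr;
  NumericVector bv;
  if (bias.isNotNull()) { bv = bias.get(); bp = bv.begin(); }

  const arma::mat Wm(const_cast<double*>(w.begin()), OC, R, false, true);
  arma::mat col(R, J);
  for (int g = 0; g < groups; ++g) {
    im2col_group(x.begin(), N, C, H, W, ICg, KH, KW, stride, pad, OH, OW, g, col);
    arma::mat res = Wm.rows(g * OCg, (g + 1) * OCg - 1) * col;  // OCg x J
    for (int j = 0; j < J; ++j) {
      const int n = j % N, rest = j / N;
      const int oh = rest % OH, ow = rest / OH;
      for (int oc = 0; oc < OCg; ++oc) {
        const int c = g * OCg + oc;
        yp[n + (size_t)N * (c + (size_t)OC * (oh + (size_t)OH * ow))] =
          res(oc, j) + (bp ? bp[c] : 0.0);
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    bool has_bias, int stride, int pad, int groups,
                    bool need_gx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int OC = wd[0], ICg = wd[1], KH = wd[2], KW = wd[3];
  const int OH = out_size(H, KH, stride, pad), OW = out_size(W, KW, stride, pad);
  const int OCg = OC / groups, J = N * OH * OW, R = ICg * KH * KW;

  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(has_bias ? OC : 0);
  double* gxp = gx.begin();
  const double* gyp = gy.begin();

  arma::mat GWm(gw.begin(), OC, R, false, true);
  arma::mat col(R, J), gym(OCg, J);
  for (int g = 0; g < groups; ++g) {
    // gather gy for this group's output channels into OCg x J
    for (int j = 0; j < J; ++j) {
      const int n = j % N, rest = j / N;
      const int oh = rest % OH, ow = rest / OH;
      for (int oc = 0; oc < OCg; ++oc) {
        const int c = g * OCg + oc;
        gym(oc, j) = gyp[n + (size_t)N * (c + (size_t)OC * (oh + (size_t)OH * ow))];
      }
    }
    im2col_group(x.begin(), N, C, H, W, ICg, KH, KW, stride, pad, OH, OW, g, col);
    GWm.rows(g * OCg, (g + 1) * OCg - 1) = gym * col.t();
    if (has_bias)
      for (int oc = 0; oc < OCg; ++oc)
        gb[g * OCg + oc] = arma::accu(gym.row(oc));

    if (!need_gx) continue;
    // input gradient: scatter-add W^T * gy through the same patch geometry
    const arma::mat Wm(const_cast<double*>(w.begin()), OC, R, false, true);
    arma::mat gcol = Wm.rows(g * OCg, (g + 1) * OCg - 1).t() * gym;  // R x J
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        for (int n = 0; n < N; ++n) {
          const int j = n + N * (oh + OH * ow);
          const double* cj = gcol.colptr(j);
          for (int kw = 0; kw < KW; ++kw) {
            const int wpos = ow * stride - pad + kw;
            if (wpos < 0 || wpos >= W) continue;
            for (int kh = 0; kh < KH; ++kh) {
              const int h = oh * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              for (int ic = 0; ic < ICg; ++ic) {
                const int c = g * ICg + ic;
                gxp[n + (size_t)N * (c + (size_t)C * (h + (size_t)H * wpos))] +=
                  cj[ic + ICg * (kh + KH * kw)];
              }
            }
          }
        }
      }
    }
  }
  if (has_bias) return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  return List::create(_["gx"] = gx, _["gw"] = gw);
}
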