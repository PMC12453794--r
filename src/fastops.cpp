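// Specialized kernels for the hot paths: depthwise 3x3 (stride 1, pad 1)
// convolution, pointwise 1x1 convolution, and the exact erf-based GELU.
// Layout matches conv2d.cpp: arrays dim (N, C, H, W), column-major, so for a
// fixed spatial position (h, w) the N x C block is contiguous.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector dwconv3_fwd_cpp(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  const double* wp = w.begin();  // dim (C,1,3,3): w[c + C*(kh + 3*kw)]
  for (int ww = 0; ww < W; ++ww) {
    for (int h = 0; h < H; ++h) {
      for (int c = 0; c < C; ++c) {
        double* yrow = yp + (size_t)N * (c + (size_t)C * (h + (size_t)H * ww));
        const double bc = b[c];
        for (int n = 0; n < N; ++n) yrow[n] = bc;
        for (int kw = 0; kw < 3; ++kw) {
          const int win = ww - 1 + kw;
          if (win < 0 || win >= W) continue;
          for (int kh = 0; kh < 3; ++kh) {
            const int hin = h - 1 + kh;
            if (hin < 0 || hin >= H) continue;
            const double wk = wp[c + C * (kh + 3 * kw)];
            const double* xrow = xp + (size_t)N * (c + (size_t)C * (hin + (size_t)H * win));
            for (int n = 0; n < N; ++n) yrow[n] += wk * xrow[n];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv3_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(C);
  const double* xp = x.begin();
  const double* gyp = gy.begin();
  double* gxp = gx.begin();
  double* gwp = gw.begin();
  for (int ww = 0; ww < W; ++ww) {
    for (int h = 0; h < H; ++h) {
      for (int c = 0; c < C; ++c) {
        const double* grow = gyp + (size_t)N * (c + (size_t)C * (h + (size_t)H * ww));
        double acc = 0.0;
        for (int n = 0; n < N; ++n) acc += grow[n];
        gb[c] += acc;
        for (int kw = 0; kw < 3; ++kw) {
          const int win = ww - 1 + kw;
          if (win < 0 || win >= W) continue;
          for (int kh = 0; kh < 3; ++kh) {
            const int hin = h - 1 + kh;
            if (hin < 0 || hin >= H) continue;
            const double wk = w[c + C * (kh + 3 * kw)];
            const double* xrow = xp + (size_t)N * (c + (size_t)C * (hin + (size_t)H * win));
            double* gxrow = gxp + (size_t)N * (c + (size_t)C * (hin + (size_t)H * win));
            double wacc = 0.0;
            for (int n = 0; n < N; ++n) {
              wacc += grow[n] * xrow[n];
              gxrow[n] += wk * grow[n];
            }
            gwp[c + C * (kh + 3 * kw)] += wacc;
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Pointwise 1x1: for each spatial position the contiguous N x C input block
// is multiplied by t(W) (W is OC x C); one small GEMM per position.
// [[Rcpp::export]]
NumericVector pwconv_fwd_cpp(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int OC = wd[0];
  NumericVector y((size_t)N * OC * H * W);
  y.attr("dim") = IntegerVector::create(N, OC, H, W);
  const arma::mat Wm(const_cast<double*>(w.begin()), OC, C, false, true);
  const arma::mat Wt = Wm.t();                    // C x OC
  const arma::rowvec bv(const_cast<double*>(b.begin()), OC, false, true);
  const size_t HW = (size_t)H * W;
  for (size_t s = 0; s < HW; ++s) {
    const arma::mat Xs(const_cast<double*>(x.begin()) + (size_t)N * C * s, N, C, false, true);
    arma::mat Ys(y.begin() + (size_t)N * OC * s, N, OC, false, true);
    Ys = Xs * Wt;
    Ys.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List pwconv_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int OC = wd[0];
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gwv(w.size());
  gwv.attr("dim") = wd;
  NumericVector gb(OC);
  const arma::mat Wm(const_cast<double*>(w.begin()), OC, C, false, true);
  arma::mat GW(gwv.begin(), OC, C, false, true);
  arma::rowvec GB(gb.begin(), OC, false, true);
  const size_t HW = (size_t)H * W;
  for (size_t s = 0; s < HW; ++s) {
    const arma::mat Xs(const_cast<double*>(x.begin()) + (size_t)N * C * s, N, C, false, true);
    const arma::mat Gs(const_cast<double*>(gy.begin()) + (size_t)N * OC * s, N, OC, false, true);
    arma::mat GXs(gx.begin() + (size_t)N * C * s, N, C, false, true);
    GXs = Gs * Wm;
    GW += Gs.t() * Xs;
    GB += arma::sum(Gs, 0);
  }
  return List::create(_["gx"] = gx, _["gw"] = gwv, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector gelu_cpp(NumericVector x) {
  NumericVector y(x.size());
  if (!Rf_isNull(x.attr("dim"))) y.attr("dim") = x.attr("dim");
  const double inv_sqrt2 = 0.7071067811865475244;
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = 0.5 * x[i] * (1.0 + std::erf(x[i] * inv_sqrt2));
  return y;
}

// [[Rcpp::export]]
NumericVector gelu_grad_cpp(NumericVector x) {
  NumericVector y(x.size());
  if (!Rf_isNull(x.attr("dim"))) y.attr("dim") = x.attr("dim");
  const double inv_sqrt2 = 0.7071067811865475244;
  const double inv_sqrt2pi = 0.3989422804014326779;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double phi = 0.5 * (1.0 + std::erf(x[i] * inv_sqrt2));
    y[i] = phi + x[i] * inv_sqrt2pi * std::exp(-0.5 * x[i] * x[i]);
  }
  return y;
}

// Fused GELU: value and derivative in one pass (one erf + one exp).
// [[Rcpp::export]]
List gelu_fused_cpp(NumericVector x) {
  NumericVector y(x.size()), g(x.size());
  if (!Rf_isNull(x.attr("dim"))) { y.attr("dim") = x.attr("dim"); g.attr("dim") = x.attr("dim"); }
  const double inv_sqrt2 = 0.7071067811865475244;
  const double inv_sqrt2pi = 0.3989422804014326779;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double phi = 0.5 * (1.0 + std::erf(x[i] * inv_sqrt2));
    y[i] = x[i] * phi;
    g[i] = phi + x[i] * inv_sqrt2pi * std::exp(-0.5 * x[i] * x[i]);
  }
  return List::create(_["y"] = y, _["grad"] = g);
}

// Global response normalization, forward. Returns the output plus the
// per-(sample, channel) intermediates needed by the backward pass.
// [[Rcpp::export]]
List grn_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                 double eps) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1];
  const size_t HW = (size_t)xd[2] * xd[3], NC = (size_t)N * C;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  std::vector<double> ssq(NC, 0.0);
  const double* xp = x.begin();
  for (size_t s = 0; s < HW; ++s) {
    const double* blk = xp + NC * s;
    for (size_t i = 0; i < NC; ++i) ssq[i] += blk[i] * blk[i];
  }
  NumericVector G(NC), Nx(NC), mn(N);
  for (size_t i = 0; i < NC; ++i) G[i] = std::sqrt(ssq[i]);
  for (int n = 0; n < N; ++n) {
    double acc = 0.0;
    for (int c = 0; c < C; ++c) acc += G[n + (size_t)N * c];
    mn[n] = acc / C;
  }
  std::vector<double> gv(NC), bv(NC);
  for (size_t i = 0; i < NC; ++i) {
    const int c = (int)(i / N), n = (int)(i % N);
    Nx[i] = G[i] / (mn[n] + eps);
    gv[i] = gamma[c] * Nx[i];
    bv[i] = beta[c];
  }
  double* yp = y.begin();
  for (size_t s = 0; s < HW; ++s) {
    const double* xb = xp + NC * s;
    double* yb = yp + NC * s;
    for (size_t i = 0; i < NC; ++i) yb[i] = gv[i] * xb[i] + bv[i] + xb[i];
  }
  return List::create(_["y"] = y, _["G"] = G, _["mn"] = mn, _["Nx"] = Nx);
}

// [[Rcpp::export]]
List grn_bwd_cpp(NumericVector x, NumericVector gy, NumericVector gamma,
                 NumericVector G, NumericVector mn, NumericVector Nx,
                 double eps) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1];
  const size_t HW = (size_t)xd[2] * xd[3], NC = (size_t)N * C;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector ggamma(C), gbeta(C);
  const double* xp = x.begin();
  const double* gyp = gy.begin();

  std::vector<double> S(NC, 0.0), R(NC, 0.0);   // sum gy*x, sum gy per (n,c)
  for (size_t s = 0; s < HW; ++s) {
    const double* xb = xp + NC * s;
    const double* gb = gyp + NC * s;
    for (size_t i = 0; i < NC; ++i) { S[i] += gb[i] * xb[i]; R[i] += gb[i]; }
  }
  std::vector<double> A(NC), gv(NC);
  for (size_t i = 0; i < NC; ++i) {
    const int c = (int)(i / N);
    gbeta[c] += R[i];
    ggamma[c] += S[i] * Nx[i];
    A[i] = gamma[c] * S[i];
    gv[i] = gamma[c] * Nx[i] + 1.0;
  }
  std::vector<double> dotAG(N, 0.0);
  for (size_t i = 0; i < NC; ++i) dotAG[i % N] += A[i] * G[i];
  std::vector<double> rel(NC);
  for (size_t i = 0; i < NC; ++i) {
    const int n = (int)(i % N);
    const double den = mn[n] + eps;
    const double gG = A[i] / den - dotAG[n] / (C * den * den);
    rel[i] = G[i] > 0 ? gG / G[i] : 0.0;
  }
  double* gxp = gx.begin();
  for (size_t s = 0; s < HW; ++s) {
    const double* xb = xp + NC * s;
    const double* gb = gyp + NC * s;
    double* ob = gxp + NC * s;
    for (size_t i = 0; i < NC; ++i) ob[i] = gb[i] * gv[i] + xb[i] * rel[i];
  }
  return List::create(_["gx"] = gx, _["gamma"] = ggamma, _["beta"] = gbeta);
}
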