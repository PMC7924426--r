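// Convolution and max-pool primitives for the compact CNN.
// Layout: activations are 4D arrays (H, W, C, N), column-major as in R.
// Conv weights are a (k*k*C) x F matrix with row index di + k*dj + k*k*c
// (di, dj 0-based kernel offsets; spatial offset = di - pad).  Stride 1,
// zero padding (k-1)/2 ("same").
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double *x, int H, int W, int C, int k, arma::mat &Xc) {
  const int pad = (k - 1) / 2;
  const R_xlen_t plane = (R_xlen_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double *xc = x + plane * c;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = di + k * dj + k * k * c;
        double *dst = Xc.colptr(col);
        const int oi = di - pad, oj = dj - pad;
        for (int j = 0; j < W; ++j) {
          const int sj = j + oj;
          double *drow = dst + (R_xlen_t)H * j;
          if (sj < 0 || sj >= W) {
            std::fill(drow, drow + H, 0.0);
            continue;
          }
          const double *srow = xc + (R_xlen_t)H * sj;
          for (int i = 0; i < H; ++i) {
            const int si = i + oi;
            drow[i] = (si < 0 || si >= H) ? 0.0 : srow[si];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".convFwCpp")]]
NumericVector conv_fw_cpp(NumericVector x, NumericMatrix w, NumericVector b,
                          int k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int F = w.ncol();
  arma::mat Wm(w.begin(), w.nrow(), F, false);
  arma::vec bv(b.begin(), F, false);
  NumericVector y((R_xlen_t)H * W * F * N);
  y.attr("dim") = IntegerVector::create(H, W, F, N);
  arma::mat Xc(H * W, k * k * C);
  const R_xlen_t in_img = (R_xlen_t)H * W * C, out_img = (R_xlen_t)H * W * F;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + in_img * n, H, W, C, k, Xc);
    arma::mat Y(y.begin() + out_img * n, H * W, F, false, true);
    Y = Xc * Wm;
    Y.each_row() += bv.t();
  }
  return y;
}

// [[Rcpp::export(name = ".convBwCpp")]]
List conv_bw_cpp(NumericVector x, NumericMatrix w, NumericVector dy, int k) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int F = w.ncol();
  const int pad = (k - 1) / 2;
  arma::mat Wm(w.begin(), w.nrow(), F, false);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xd;
  arma::mat dW(k * k * C, F, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  arma::mat Xc(H * W, k * k * C);
  const R_xlen_t in_img = (R_xlen_t)H * W * C, out_img = (R_xlen_t)H * W * F;
  const R_xlen_t plane = (R_xlen_t)H * W;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + in_img * n, H, W, C, k, Xc);
    arma::mat dY((double *)dy.begin() + out_img * n, H * W, F, false, true);
    dW += Xc.t() * dY;
    db += arma::sum(dY, 0).t();
    arma::mat dXc = dY * Wm.t();          // (H*W) x (k*k*C)
    // col2im scatter-add
    double *dximg = dx.begin() + in_img * n;
    for (int c = 0; c < C; ++c) {
      double *dxc = dximg + plane * c;
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di) {
          const int col = di + k * dj + k * k * c;
          const double *src = dXc.colptr(col);
          const int oi = di - pad, oj = dj - pad;
          for (int j = 0; j < W; ++j) {
            const int sj = j + oj;
            if (sj < 0 || sj >= W) continue;
            const double *srow = src + plane * 0 + (R_xlen_t)H * j;
            double *drow = dxc + (R_xlen_t)H * sj;
            for (int i = 0; i < H; ++i) {
              const int si = i + oi;
              if (si >= 0 && si < H) drow[si] += srow[i];
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = wrap(dW), _["db"] = wrap(db));
}

// 2x2 max pool, stride 2 (floor division on odd extents).
// [[Rcpp::export(name = ".maxpoolFwCpp")]]
List maxpool_fw_cpp(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector argm((R_xlen_t)Ho * Wo * C * N);  // 1-based linear idx into x
  argm.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double *xv = x.begin();
  double *yv = y.begin(), *av = argm.begin();
  R_xlen_t oi = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = ((R_xlen_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i, ++oi) {
          R_xlen_t i0 = base + (R_xlen_t)(2 * j) * H + 2 * i;
          R_xlen_t cand[4] = {i0, i0 + 1, i0 + H, i0 + H + 1};
          R_xlen_t best = cand[0];
          double bv = xv[cand[0]];
          for (int q = 1; q < 4; ++q)
            if (xv[cand[q]] > bv) { bv = xv[cand[q]]; best = cand[q]; }
          yv[oi] = bv;
          av[oi] = (double)(best + 1);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = argm);
}

// [[Rcpp::export(name = ".maxpoolBwCpp")]]
NumericVector maxpool_bw_cpp(NumericVector argm, NumericVector dy,
                             IntegerVector in_dim) {
  NumericVector dx((R_xlen_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  dx.attr("dim") = in_dim;
  const double *a = argm.begin(), *g = dy.begin();
  double *d = dx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) d[(R_xlen_t)a[i] - 1] += g[i];
  return dx;
}
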