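// Low-level convolution kernels for the CSR-Unet.
//
// Tensor layout everywhere: R arrays with dim (H, W, C, N), column-major,
// i.e. element (h, w, c, n) sits at h + H*(w + W*(c + C*n)).  Convolutions
// are stride-1, same-padding, odd kernels; implemented as im2col + GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Transposed im2col: row i = h + H*w (output pixel), column j = kh +
// KH*(kw + KW*c) -- matching the column-major flattening of a (KH, KW, C,
// Cout) weight array -- so y = col * Wm.  The inner copies run contiguously
// along h for both source and destination.
static inline void im2col_tr(const double *x, int H, int W, int C, int KH,
                             int KW, arma::mat &col) {
  const int padH = (KH - 1) / 2, padW = (KW - 1) / 2;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        double *cj = col.colptr(kh + KH * (kw + KW * c));
        const int off = kh - padH;
        const int hlo = std::max(0, -off);
        const int hhi = std::min(H, H - off);
        for (int w = 0; w < W; ++w) {
          const int sw = w + kw - padW;
          if (sw < 0 || sw >= W) continue;
          const double *src = xc + (size_t)H * sw + off;
          std::copy(src + hlo, src + hhi, cj + (size_t)H * w + hlo);
        }
      }
    }
  }
}

static inline void col2im_tr_add(const arma::mat &col, double *dx, int H,
                                 int W, int C, int KH, int KW) {
  const int padH = (KH - 1) / 2, padW = (KW - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double *xc = dx + (size_t)H * W * c;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        const double *cj = col.colptr(kh + KH * (kw + KW * c));
        const int off = kh - padH;
        const int hlo = std::max(0, -off);
        const int hhi = std::min(H, H - off);
        for (int w = 0; w < W; ++w) {
          const int sw = w + kw - padW;
          if (sw < 0 || sw >= W) continue;
          double *dst = xc + (size_t)H * sw + off;
          const double *src = cj + (size_t)H * w;
          for (int h = hlo; h < hhi; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector b, IntegerVector xdim,
                             IntegerVector wdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int KH = wdim[0], KW = wdim[1], Cout = wdim[3];
  NumericVector y((size_t)H * W * Cout * N);
  arma::mat Wm(const_cast<double *>(w.begin()), KH * KW * C, Cout, false);
  arma::rowvec bv(const_cast<double *>(b.begin()), Cout, false);
  arma::mat col(H * W, KH * KW * C);
  for (int n = 0; n < N; ++n) {
    im2col_tr(x.begin() + (size_t)H * W * C * n, H, W, C, KH, KW, col);
    arma::mat yn = col * Wm;           // (H*W) x Cout
    yn.each_row() += bv;
    std::copy(yn.begin(), yn.end(), y.begin() + (size_t)H * W * Cout * n);
  }
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    IntegerVector xdim, IntegerVector wdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int KH = wdim[0], KW = wdim[1], Cout = wdim[3];
  NumericVector dx((size_t)H * W * C * N);
  arma::mat Wm(const_cast<double *>(w.begin()), KH * KW * C, Cout, false);
  arma::mat dW(KH * KW * C, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat col(H * W, KH * KW * C);
  for (int n = 0; n < N; ++n) {
    im2col_tr(x.begin() + (size_t)H * W * C * n, H, W, C, KH, KW, col);
    arma::mat dyn(const_cast<double *>(dy.begin()) + (size_t)H * W * Cout * n,
                  H * W, Cout, false);
    dW += col.t() * dyn;
    db += arma::sum(dyn, 0);
    arma::mat dcol = dyn * Wm.t();     // (H*W) x (KH*KW*C)
    col2im_tr_add(dcol, dx.begin() + (size_t)H * W * C * n, H, W, C, KH, KW);
  }
  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = wdim;
  NumericVector dbr(db.begin(), db.end());
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dw"] = dWr, _["db"] = dbr);
}

// 2x2 max pooling, stride 2.  Returns pooled values and flat argmax indices
// (0-based into the input H*W plane of each (c, n) slab).
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xs = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double *ys = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      int *is = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          int best = 2 * h + H * (2 * w);
          double bv = xs[best];
          const int cand[3] = {2 * h + 1 + H * (2 * w), 2 * h + H * (2 * w + 1),
                               2 * h + 1 + H * (2 * w + 1)};
          for (int k = 0; k < 3; ++k)
            if (xs[cand[k]] > bv) { bv = xs[cand[k]]; best = cand[k]; }
          ys[h + Ho * w] = bv;
          is[h + Ho * w] = best;
        }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector idx,
                               IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector dx((size_t)H * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *ds = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      const int *is = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double *xs = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) xs[is[i]] += ds[i];
    }
  dx.attr("dim") = xdim;
  return dx;
}

// 2x2 transposed convolution, stride 2 (learned upsampling).
// w has dim (2, 2, Cin, Cout); output is (2H, 2W, Cout, N).
// [[Rcpp::export]]
NumericVector convt2_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             IntegerVector xdim, IntegerVector wdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Cout = wdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double *ys = y.begin() + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) ys[i] = b[co];
      for (int ci = 0; ci < C; ++ci) {
        const double *xs = x.begin() + (size_t)H * W * (ci + (size_t)C * n);
        const double *ws = w.begin() + 4 * (ci + (size_t)C * co);
        for (int wj = 0; wj < W; ++wj)
          for (int h = 0; h < H; ++h) {
            const double v = xs[h + (size_t)H * wj];
            double *yb = ys + 2 * h + (size_t)Ho * (2 * wj);
            yb[0] += v * ws[0];              // (a=0, b=0)
            yb[1] += v * ws[1];              // (a=1, b=0)
            yb[Ho] += v * ws[2];             // (a=0, b=1)
            yb[Ho + 1] += v * ws[3];         // (a=1, b=1)
          }
      }
    }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List convt2_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    IntegerVector xdim, IntegerVector wdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Cout = wdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((size_t)H * W * C * N);
  NumericVector dw((size_t)4 * C * Cout);
  NumericVector db(Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double *ds = dy.begin() + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) db[co] += ds[i];
      for (int ci = 0; ci < C; ++ci) {
        const double *xs = x.begin() + (size_t)H * W * (ci + (size_t)C * n);
        double *dxs = dx.begin() + (size_t)H * W * (ci + (size_t)C * n);
        const double *ws = w.begin() + 4 * (ci + (size_t)C * co);
        double *dws = dw.begin() + 4 * (ci + (size_t)C * co);
        for (int wj = 0; wj < W; ++wj)
          for (int h = 0; h < H; ++h) {
            const double v = xs[h + (size_t)H * wj];
            const double *dbk = ds + 2 * h + (size_t)Ho * (2 * wj);
            dws[0] += v * dbk[0];
            dws[1] += v * dbk[1];
            dws[2] += v * dbk[Ho];
            dws[3] += v * dbk[Ho + 1];
            dxs[h + (size_t)H * wj] += ws[0] * dbk[0] + ws[1] * dbk[1] +
                                       ws[2] * dbk[Ho] + ws[3] * dbk[Ho + 1];
          }
      }
    }
  dw.attr("dim") = wdim;
  dx.attr("dim") = xdim;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
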