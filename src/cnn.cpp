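// Compute kernels for the native CNN: 3x3 same-padding convolution via
// im2col + GEMM (forward and backward) and 2x2 max pooling. Batches are
// column-major R arrays of shape (h, w, channels, n).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// column layout of the im2col matrix: col = ch * 9 + (dc+1) * 3 + (dr+1)
static void im2col3(const double* x, int h, int w, int c, arma::mat& col) {
  const int hw = h * w;
  col.set_size(hw, 9 * c);
  for (int ch = 0; ch < c; ++ch) {
    const double* xc = x + ch * hw;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        double* dst = col.colptr(ch * 9 + (dc + 1) * 3 + (dr + 1));
        for (int j = 0; j < w; ++j) {
          int sj = j + dc;
          double* d = dst + j * h;
          if (sj < 0 || sj >= w) {
            std::fill(d, d + h, 0.0);
            continue;
          }
          const double* s = xc + sj * h;
          for (int i = 0; i < h; ++i) {
            int si = i + dr;
            d[i] = (si < 0 || si >= h) ? 0.0 : s[si];
          }
        }
      }
    }
  }
}

static void col2im3(const arma::mat& col, int h, int w, int c, double* gx) {
  const int hw = h * w;
  std::fill(gx, gx + (size_t)hw * c, 0.0);
  for (int ch = 0; ch < c; ++ch) {
    double* xc = gx + ch * hw;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const double* src = col.colptr(ch * 9 + (dc + 1) * 3 + (dr + 1));
        for (int j = 0; j < w; ++j) {
          int sj = j + dc;
          if (sj < 0 || sj >= w) continue;
          const double* s = src + j * h;
          double* d = xc + sj * h;
          for (int i = 0; i < h; ++i) {
            int si = i + dr;
            if (si >= 0 && si < h) d[si] += s[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3_forward")]]
NumericVector conv3_forward(const NumericVector& x, const arma::mat& W,
                            const arma::vec& b) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("x must be a 4-d array (h, w, c, n)");
  const int h = d[0], w = d[1], c = d[2], n = d[3];
  const int f = W.n_cols;
  if ((int)W.n_rows != 9 * c) stop("weight rows must equal 9 * channels");
  const int hw = h * w;
  NumericVector y((R_xlen_t)h * w * f * n);
  y.attr("dim") = IntegerVector::create(h, w, f, n);
  arma::mat col;
  for (int im = 0; im < n; ++im) {
    im2col3(REAL(x) + (size_t)im * hw * c, h, w, c, col);
    arma::mat out(REAL(y) + (size_t)im * hw * f, hw, f, false, true);
    out = col * W;
    out.each_row() += b.t();
  }
  return y;
}

// [[Rcpp::export(name = ".conv3_backward")]]
List conv3_backward(const NumericVector& x, const arma::mat& W,
                    const NumericVector& gy) {
  IntegerVector d = x.attr("dim");
  const int h = d[0], w = d[1], c = d[2], n = d[3];
  const int f = W.n_cols;
  const int hw = h * w;
  NumericVector gx((R_xlen_t)h * w * c * n);
  gx.attr("dim") = IntegerVector::create(h, w, c, n);
  arma::mat gW(9 * c, f, arma::fill::zeros);
  arma::vec gb(f, arma::fill::zeros);
  arma::mat col, gcol;
  for (int im = 0; im < n; ++im) {
    im2col3(REAL(x) + (size_t)im * hw * c, h, w, c, col);
    arma::mat g(const_cast<double*>(REAL(gy)) + (size_t)im * hw * f,
                hw, f, false, true);
    gW += col.t() * g;
    gb += arma::sum(g, 0).t();
    gcol = g * W.t();
    col2im3(gcol, h, w, c, REAL(gx) + (size_t)im * hw * c);
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  const int h = d[0], w = d[1], c = d[2], n = d[3];
  if (h % 2 || w % 2) stop("spatial dimensions must be even for 2x2 pooling");
  const int oh = h / 2, ow = w / 2;
  NumericVector y((R_xlen_t)oh * ow * c * n);
  y.attr("dim") = IntegerVector::create(oh, ow, c, n);
  IntegerVector idx((R_xlen_t)oh * ow * c * n);  // flat index into x
  idx.attr("dim") = IntegerVector::create(oh, ow, c, n);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  for (int im = 0; im < n; ++im)
    for (int ch = 0; ch < c; ++ch) {
      size_t xoff = ((size_t)im * c + ch) * h * w;
      size_t yoff = ((size_t)im * c + ch) * oh * ow;
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i) {
          size_t b00 = xoff + (size_t)(2 * j) * h + 2 * i;
          size_t cand[4] = {b00, b00 + 1, b00 + h, b00 + h + 1};
          size_t bi = cand[0];
          double bv = xp[bi];
          for (int q = 1; q < 4; ++q)
            if (xp[cand[q]] > bv) { bv = xp[cand[q]]; bi = cand[q]; }
          yp[yoff + (size_t)j * oh + i] = bv;
          ip[yoff + (size_t)j * oh + i] = (int)bi;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(const IntegerVector& idx,
                                const NumericVector& gy,
                                const IntegerVector& xdim) {
  NumericVector gx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  double* gp = REAL(gx);
  const double* gyp = REAL(gy);
  const int* ip = INTEGER(idx);
  const R_xlen_t m = gy.size();
  for (R_xlen_t q = 0; q < m; ++q) gp[ip[q]] += gyp[q];
  return gx;
}
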