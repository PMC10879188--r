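// Low-level image kernels shared by preprocessing, augmentation and the
// synthetic renderer. All filters use replicate (clamp-to-edge) padding so
// border behaviour is fully specified and testable.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 2-D correlation with an odd-sized kernel, replicate padding.
// Coefficients are applied directly (correlation, not flipped convolution).
// [[Rcpp::export(name = ".correlate2_replicate")]]
arma::mat correlate2_replicate(const arma::mat& img, const arma::mat& ker) {
  const int nr = img.n_rows, nc = img.n_cols;
  const int kr = ker.n_rows, kc = ker.n_cols;
  if (kr % 2 == 0 || kc % 2 == 0) stop("kernel dimensions must be odd");
  const int rr = kr / 2, rc = kc / 2;
  arma::mat out(nr, nc, arma::fill::zeros);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int dj = -rc; dj <= rc; ++dj) {
        int cj = clampi(j + dj, 0, nc - 1);
        for (int di = -rr; di <= rr; ++di) {
          int ci = clampi(i + di, 0, nr - 1);
          acc += img(ci, cj) * ker(di + rr, dj + rc);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Box mean of size s (possibly even), replicate padding. For even s the
// window is anchored at the top-left pixel of the center 2x2 block, i.e.
// offsets span [-(s-1)/2, s - 1 - (s-1)/2] in each axis (integer division).
// [[Rcpp::export(name = ".box_mean_replicate")]]
arma::mat box_mean_replicate(const arma::mat& img, int s) {
  if (s < 1) stop("box size must be >= 1");
  const int nr = img.n_rows, nc = img.n_cols;
  const int lo = (s - 1) / 2, hi = s - 1 - lo;
  const double w = 1.0 / (double)(s * s);
  arma::mat out(nr, nc, arma::fill::zeros);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int dj = -lo; dj <= hi; ++dj) {
        int cj = clampi(j + dj, 0, nc - 1);
        for (int di = -lo; di <= hi; ++di) {
          acc += img(clampi(i + di, 0, nr - 1), cj);
        }
      }
      out(i, j) = acc * w;
    }
  }
  return out;
}

// Inverse-map affine resampling: for each output pixel (r, c) (0-based), the
// source location is A %*% (c, r, 1)' in (x, y) = (col, row) coordinates.
// Out-of-range samples clamp to the nearest edge pixel ("nearest" fill).
// interp: 0 = nearest neighbour, 1 = bilinear.
// [[Rcpp::export(name = ".affine_sample")]]
arma::mat affine_sample(const arma::mat& img, int out_rows, int out_cols,
                        const arma::mat& A, int interp) {
  if (A.n_rows != 2 || A.n_cols != 3) stop("A must be 2x3");
  const int nr = img.n_rows, nc = img.n_cols;
  arma::mat out(out_rows, out_cols);
  for (int c = 0; c < out_cols; ++c) {
    for (int r = 0; r < out_rows; ++r) {
      double sx = A(0, 0) * c + A(0, 1) * r + A(0, 2);
      double sy = A(1, 0) * c + A(1, 1) * r + A(1, 2);
      if (interp == 0) {
        int ix = clampi((int)std::floor(sx + 0.5), 0, nc - 1);
        int iy = clampi((int)std::floor(sy + 0.5), 0, nr - 1);
        out(r, c) = img(iy, ix);
      } else {
        double fx = std::floor(sx), fy = std::floor(sy);
        double ax = sx - fx, ay = sy - fy;
        int x0 = clampi((int)fx, 0, nc - 1), x1 = clampi((int)fx + 1, 0, nc - 1);
        int y0 = clampi((int)fy, 0, nr - 1), y1 = clampi((int)fy + 1, 0, nr - 1);
        out(r, c) = (1 - ay) * ((1 - ax) * img(y0, x0) + ax * img(y0, x1)) +
                    ay * ((1 - ax) * img(y1, x0) + ax * img(y1, x1));
      }
    }
  }
  return out;
}

// Bilinear resize mapping pixel centers (align corners = FALSE convention).
// [[Rcpp::export(name = ".resize_bilinear")]]
arma::mat resize_bilinear(const arma::mat& img, int out_rows, int out_cols) {
  const double sr = (double)img.n_rows / out_rows;
  const double sc = (double)img.n_cols / out_cols;
  arma::mat A(2, 3);
  A(0, 0) = sc; A(0, 1) = 0;  A(0, 2) = 0.5 * sc - 0.5;
  A(1, 0) = 0;  A(1, 1) = sr; A(1, 2) = 0.5 * sr - 0.5;
  return affine_sample(img, out_rows, out_cols, A, 1);
}
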