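// Seeded RANSAC estimation of a 2-D geometric model (similarity, affine,
// homography) from point correspondences; returns the inlier count and mask.
// Homographies use the normalised 4-point DLT; inliers are judged by forward
// transfer error. Deterministic for a fixed seed (std::mt19937).
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// fit homography A -> B from point pairs (rows of pa, pb are x, y)
static bool fit_homography(const arma::mat& pa, const arma::mat& pb,
                           arma::mat& H) {
  const int n = pa.n_rows;
  if (n < 4) return false;
  // Hartley normalisation
  arma::rowvec ca = arma::mean(pa, 0), cb = arma::mean(pb, 0);
  double sa = 0, sb = 0;
  for (int i = 0; i < n; ++i) {
    sa += arma::norm(pa.row(i) - ca, 2);
    sb += arma::norm(pb.row(i) - cb, 2);
  }
  sa /= n; sb /= n;
  if (sa < 1e-10 || sb < 1e-10) return false;
  double fa = std::sqrt(2.0) / sa, fb = std::sqrt(2.0) / sb;
  arma::mat Ta = {{fa, 0, -fa * ca(0)}, {0, fa, -fa * ca(1)}, {0, 0, 1}};
  arma::mat Tb = {{fb, 0, -fb * cb(0)}, {0, fb, -fb * cb(1)}, {0, 0, 1}};

  arma::mat M(2 * n, 9, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double x = fa * (pa(i, 0) - ca(0)), y = fa * (pa(i, 1) - ca(1));
    double u = fb * (pb(i, 0) - cb(0)), v = fb * (pb(i, 1) - cb(1));
    M(2 * i, 0) = -x; M(2 * i, 1) = -y; M(2 * i, 2) = -1;
    M(2 * i, 6) = u * x; M(2 * i, 7) = u * y; M(2 * i, 8) = u;
    M(2 * i + 1, 3) = -x; M(2 * i + 1, 4) = -y; M(2 * i + 1, 5) = -1;
    M(2 * i + 1, 6) = v * x; M(2 * i + 1, 7) = v * y; M(2 * i + 1, 8) = v;
  }
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, M)) return false;
  arma::vec h = V.col(8);
  arma::mat Hn = arma::reshape(h, 3, 3).t();
  if (std::fabs(Hn(2, 2)) < 1e-12 && std::fabs(Hn(2, 0)) < 1e-12 &&
      std::fabs(Hn(2, 1)) < 1e-12)
    return false;
  H = arma::inv(Tb) * Hn * Ta;
  if (std::fabs(H(2, 2)) > 1e-12) H /= H(2, 2);
  return true;
}

// fit affine A -> B from >= 3 pairs (least squares)
static bool fit_affine(const arma::mat& pa, const arma::mat& pb,
                       arma::mat& H) {
  const int n = pa.n_rows;
  if (n < 3) return false;
  arma::mat X(n, 3, arma::fill::ones);
  X.cols(0, 1) = pa;
  arma::mat coef;
  if (!arma::solve(coef, X, pb)) return false;  // 3x2
  H = arma::eye(3, 3);
  H(0, 0) = coef(0, 0); H(0, 1) = coef(1, 0); H(0, 2) = coef(2, 0);
  H(1, 0) = coef(0, 1); H(1, 1) = coef(1, 1); H(1, 2) = coef(2, 1);
  return true;
}

// fit similarity (scale, rotation, translation) from >= 2 pairs
static bool fit_similarity(const arma::mat& pa, const arma::mat& pb,
                           arma::mat& H) {
  const int n = pa.n_rows;
  if (n < 2) return false;
  // params (a, b, tx, ty): u = a x - b y + tx, v = b x + a y + ty
  arma::mat X(2 * n, 4, arma::fill::zeros);
  arma::vec yv(2 * n);
  for (int i = 0; i < n; ++i) {
    X(2 * i, 0) = pa(i, 0); X(2 * i, 1) = -pa(i, 1); X(2 * i, 2) = 1;
    X(2 * i + 1, 0) = pa(i, 1); X(2 * i + 1, 1) = pa(i, 0); X(2 * i + 1, 3) = 1;
    yv(2 * i) = pb(i, 0);
    yv(2 * i + 1) = pb(i, 1);
  }
  arma::vec p;
  if (!arma::solve(p, X, yv)) return false;
  H = arma::eye(3, 3);
  H(0, 0) = p(0); H(0, 1) = -p(1); H(0, 2) = p(2);
  H(1, 0) = p(1); H(1, 1) = p(0); H(1, 2) = p(3);
  return true;
}

static int count_inliers(const arma::mat& pa, const arma::mat& pb,
                         const arma::mat& H, double thr2,
                         std::vector<int>* mask) {
  const int n = pa.n_rows;
  int cnt = 0;
  for (int i = 0; i < n; ++i) {
    double w = H(2, 0) * pa(i, 0) + H(2, 1) * pa(i, 1) + H(2, 2);
    if (std::fabs(w) < 1e-12) { if (mask) (*mask)[i] = 0; continue; }
    double u = (H(0, 0) * pa(i, 0) + H(0, 1) * pa(i, 1) + H(0, 2)) / w;
    double v = (H(1, 0) * pa(i, 0) + H(1, 1) * pa(i, 1) + H(1, 2)) / w;
    double du = u - pb(i, 0), dv = v - pb(i, 1);
    int in = (du * du + dv * dv <= thr2) ? 1 : 0;
    if (mask) (*mask)[i] = in;
    cnt += in;
  }
  return cnt;
}

static bool degenerate_sample(const arma::mat& p) {
  // any three (near-)collinear points among the sample
  const int n = p.n_rows;
  for (int a = 0; a < n - 2; ++a)
    for (int b = a + 1; b < n - 1; ++b)
      for (int c = b + 1; c < n; ++c) {
        double area = (p(b, 0) - p(a, 0)) * (p(c, 1) - p(a, 1)) -
                      (p(b, 1) - p(a, 1)) * (p(c, 0) - p(a, 0));
        if (std::fabs(area) < 1e-6) return true;
      }
  return false;
}

// [[Rcpp::export(name = ".ransac_geometric")]]
List ransac_geometric(const arma::mat& pa, const arma::mat& pb,
                      std::string model, double reproj_threshold,
                      double confidence, int max_iterations, int seed) {
  const int n = pa.n_rows;
  if ((int)pb.n_rows != n) stop("point sets must have equal size");
  int m;  // minimal sample size
  bool (*fit)(const arma::mat&, const arma::mat&, arma::mat&);
  if (model == "homography") { m = 4; fit = fit_homography; }
  else if (model == "affine") { m = 3; fit = fit_affine; }
  else if (model == "similarity") { m = 2; fit = fit_similarity; }
  else stop("unknown geometric model: %s", model.c_str());

  const double thr2 = reproj_threshold * reproj_threshold;
  if (n < m)
    return List::create(_["inliers"] = 0,
                        _["mask"] = IntegerVector(n, 0));

  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> unif(0, n - 1);

  int best = -1;
  std::vector<int> best_mask(n, 0), mask(n, 0);
  arma::mat best_H;
  long need = max_iterations;
  long it = 0;
  while (it < need && it < (long)max_iterations) {
    ++it;
    // sample m distinct indices
    int idx[4];
    int got = 0;
    while (got < m) {
      int cand = unif(rng);
      bool dup = false;
      for (int q = 0; q < got; ++q) if (idx[q] == cand) { dup = true; break; }
      if (!dup) idx[got++] = cand;
    }
    arma::mat sa(m, 2), sb(m, 2);
    for (int q = 0; q < m; ++q) {
      sa.row(q) = pa.row(idx[q]);
      sb.row(q) = pb.row(idx[q]);
    }
    if (m >= 3 && (degenerate_sample(sa) || degenerate_sample(sb))) continue;
    arma::mat H;
    if (!fit(sa, sb, H)) continue;
    int cnt = count_inliers(pa, pb, H, thr2, &mask);
    if (cnt > best) {
      best = cnt;
      best_mask = mask;
      best_H = H;
      // adaptive iteration bound
      double w = (double)cnt / n;
      double denom = std::log(std::max(1e-12, 1.0 - std::pow(w, m)));
      if (denom < 0) {
        double ni = std::log(std::max(1e-12, 1.0 - confidence)) / denom;
        need = (long)std::min((double)max_iterations,
                              std::ceil(std::max(1.0, ni)));
      }
    }
  }
  if (best < 0) best = 0;

  // refit on inliers and keep the recount if it improves
  if (best >= m) {
    arma::uvec in_idx(best);
    int q = 0;
    for (int i = 0; i < n; ++i) if (best_mask[i]) in_idx(q++) = i;
    arma::mat ia(best, 2), ib(best, 2);
    for (int i = 0; i < best; ++i) {
      ia.row(i) = pa.row(in_idx(i));
      ib.row(i) = pb.row(in_idx(i));
    }
    arma::mat H2;
    if (fit(ia, ib, H2)) {
      int cnt2 = count_inliers(pa, pb, H2, thr2, &mask);
      if (cnt2 > best) { best = cnt2; best_mask = mask; }
    }
  }
  return List::create(_["inliers"] = best,
                      _["mask"] = IntegerVector(best_mask.begin(),
                                                best_mask.end()));
}
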