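// KAZE-family feature extractor: Perona-Malik nonlinear diffusion scale
// space (octave pyramid with decimation), scale-normalised determinant-of-
// Hessian detection with 3x3x3 non-maximum suppression, and upright
// M-SURF-style 64-d real descriptors. Fully deterministic (no RNG).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// central differences, replicate borders
static void gradient(const arma::mat& L, arma::mat& Lx, arma::mat& Ly) {
  const int nr = L.n_rows, nc = L.n_cols;
  Lx.set_size(nr, nc);
  Ly.set_size(nr, nc);
  for (int j = 0; j < nc; ++j) {
    int jm = clampi(j - 1, 0, nc - 1), jp = clampi(j + 1, 0, nc - 1);
    for (int i = 0; i < nr; ++i) {
      int im = clampi(i - 1, 0, nr - 1), ip = clampi(i + 1, 0, nr - 1);
      Lx(i, j) = 0.5 * (L(i, jp) - L(i, jm));
      Ly(i, j) = 0.5 * (L(ip, j) - L(im, j));
    }
  }
}

// conductivity g(|grad L|^2 / k^2); type: 0 linear, 1 PM_G1, 2 PM_G2,
// 3 Weickert, 4 Charbonnier
static arma::mat conductivity(const arma::mat& Lx, const arma::mat& Ly,
                              double k, int type) {
  const double k2 = k * k;
  arma::mat g(Lx.n_rows, Lx.n_cols);
  for (arma::uword idx = 0; idx < g.n_elem; ++idx) {
    double m2 = Lx(idx) * Lx(idx) + Ly(idx) * Ly(idx);
    double x = m2 / k2;
    double v;
    switch (type) {
      case 1: v = std::exp(-x); break;
      case 2: v = 1.0 / (1.0 + x); break;
      case 3: v = (m2 <= 0) ? 1.0 : 1.0 - std::exp(-3.315 / (x * x * x * x));
              break;
      case 4: v = 1.0 / std::sqrt(1.0 + x); break;
      default: v = 1.0;
    }
    g(idx) = v;
  }
  return g;
}

// one explicit diffusion step: L += dt * div(g grad L), 4-neighbour scheme
static void diffuse_step(arma::mat& L, const arma::mat& g, double dt) {
  const int nr = L.n_rows, nc = L.n_cols;
  arma::mat Ln = L;
  for (int j = 0; j < nc; ++j) {
    int jm = clampi(j - 1, 0, nc - 1), jp = clampi(j + 1, 0, nc - 1);
    for (int i = 0; i < nr; ++i) {
      int im = clampi(i - 1, 0, nr - 1), ip = clampi(i + 1, 0, nr - 1);
      double c = L(i, j), gc = g(i, j);
      double flux =
        0.5 * (gc + g(i, jp)) * (L(i, jp) - c) +
        0.5 * (gc + g(i, jm)) * (L(i, jm) - c) +
        0.5 * (gc + g(ip, j)) * (L(ip, j) - c) +
        0.5 * (gc + g(im, j)) * (L(im, j) - c);
      Ln(i, j) = c + dt * flux;
    }
  }
  L = Ln;
}

// evolve L from diffusion time t0 to t1 (lagged-diffusivity explicit scheme)
static void evolve(arma::mat& L, double t0, double t1, double k, int type) {
  const double dt_max = 0.2;  // stability bound for the 4-neighbour scheme
  double t = t0;
  arma::mat Lx, Ly;
  while (t < t1 - 1e-12) {
    double dt = std::min(dt_max, t1 - t);
    gradient(L, Lx, Ly);
    arma::mat g = conductivity(Lx, Ly, k, type);
    diffuse_step(L, g, dt);
    t += dt;
  }
}

// contrast parameter: given percentile of gradient magnitudes (> 0)
static double contrast_k(const arma::mat& L, double prob) {
  arma::mat Lx, Ly;
  gradient(L, Lx, Ly);
  std::vector<double> mags;
  mags.reserve(L.n_elem);
  for (arma::uword i = 0; i < L.n_elem; ++i) {
    double m = std::sqrt(Lx(i) * Lx(i) + Ly(i) * Ly(i));
    if (m > 0) mags.push_back(m);
  }
  if (mags.empty()) return 0.03;
  std::sort(mags.begin(), mags.end());
  size_t idx = (size_t)std::floor(prob * (mags.size() - 1));
  double k = mags[idx];
  return k > 1e-8 ? k : 0.03;
}

static arma::mat decimate2(const arma::mat& L) {
  const int nr = (L.n_rows + 1) / 2, nc = (L.n_cols + 1) / 2;
  arma::mat out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = L(2 * i, 2 * j);
  return out;
}

struct Kp {
  double x, y, scale, response;
  int octave, layer;
  int gi, gj;  // grid coords within the octave
};

// upright M-SURF descriptor: 4x4 subregions x (sdx, sdy, s|dx|, s|dy|),
// 20s x 20s window sampled at spacing s, Gaussian weight sigma = 3.3 s
static void describe(const arma::mat& Lx, const arma::mat& Ly,
                     double gx, double gy, double s, double* out) {
  const int nr = Lx.n_rows, nc = Lx.n_cols;
  for (int q = 0; q < 64; ++q) out[q] = 0.0;
  const double wdenom = 2.0 * (3.3 * s) * (3.3 * s);
  for (int u = -10; u < 10; ++u) {
    int sub_c = (u + 10) / 5;  // 0..3
    double ox = (u + 0.5) * s;
    for (int v = -10; v < 10; ++v) {
      int sub_r = (v + 10) / 5;
      double oy = (v + 0.5) * s;
      int sx = clampi((int)std::floor(gx + ox + 0.5), 0, nc - 1);
      int sy = clampi((int)std::floor(gy + oy + 0.5), 0, nr - 1);
      double w = std::exp(-(ox * ox + oy * oy) / wdenom);
      double dx = w * Lx(sy, sx), dy = w * Ly(sy, sx);
      int base = 4 * (sub_r * 4 + sub_c);
      out[base + 0] += dx;
      out[base + 1] += dy;
      out[base + 2] += std::fabs(dx);
      out[base + 3] += std::fabs(dy);
    }
  }
  double nrm = 0.0;
  for (int q = 0; q < 64; ++q) nrm += out[q] * out[q];
  nrm = std::sqrt(nrm);
  if (nrm > 1e-12)
    for (int q = 0; q < 64; ++q) out[q] /= nrm;
}

// [[Rcpp::export(name = ".kaze_extract")]]
List kaze_extract(const arma::mat& img, int octaves, int layers,
                  int diffusivity, double threshold, int max_keypoints) {
  if (octaves < 1 || layers < 1) stop("octaves and layers must be >= 1");
  const double sigma0 = 1.6;
  arma::mat base = img / 255.0;

  // pre-smooth to sigma0 via linear diffusion (t = sigma^2 / 2)
  evolve(base, 0.0, 0.5 * sigma0 * sigma0, 1.0, 0);

  std::vector<Kp> kps;
  std::vector<std::vector<arma::mat>> oct_Lx, oct_Ly;  // per octave, per layer
  arma::mat cur = base;

  for (int o = 0; o < octaves; ++o) {
    if ((int)cur.n_rows < 16 || (int)cur.n_cols < 16) break;
    double k = contrast_k(cur, 0.7);
    std::vector<arma::mat> Ls(layers);
    std::vector<double> sig(layers);
    arma::mat L = cur;
    double t_prev = 0.5 * sigma0 * sigma0;
    for (int j = 0; j < layers; ++j) {
      sig[j] = sigma0 * std::pow(2.0, (double)j / layers);
      double t = 0.5 * sig[j] * sig[j];
      if (t > t_prev) evolve(L, t_prev, t, k, diffusivity);
      t_prev = std::max(t, t_prev);
      Ls[j] = L;
    }

    // determinant-of-Hessian responses, sigma^4-normalised (grid units)
    std::vector<arma::mat> R(layers);
    std::vector<arma::mat> Lxs(layers), Lys(layers);
    const int nr = L.n_rows, nc = L.n_cols;
    for (int j = 0; j < layers; ++j) {
      gradient(Ls[j], Lxs[j], Lys[j]);
      arma::mat Lxx, Lxy, Lyx, Lyy;
      gradient(Lxs[j], Lxx, Lxy);   // d/dx, d/dy of Lx -> (Lxx, Lxy)
      gradient(Lys[j], Lyx, Lyy);
      double s4 = std::pow(sig[j], 4.0);
      R[j] = s4 * (Lxx % Lyy - Lxy % Lyx);
    }

    // 3x3x3 non-maximum suppression on interior layers
    int j_lo = (layers >= 3) ? 1 : 0;
    int j_hi = (layers >= 3) ? layers - 2 : layers - 1;
    const double scale_mult = std::pow(2.0, o);
    for (int j = j_lo; j <= j_hi; ++j) {
      for (int cc = 2; cc < nc - 2; ++cc) {
        for (int rr2 = 2; rr2 < nr - 2; ++rr2) {
          double v = R[j](rr2, cc);
          if (v <= threshold) continue;
          bool is_max = true;
          for (int dj = -1; dj <= 1 && is_max; ++dj) {
            int lj = j + dj;
            if (lj < 0 || lj >= layers) continue;
            for (int dc = -1; dc <= 1 && is_max; ++dc)
              for (int dr = -1; dr <= 1; ++dr) {
                if (dj == 0 && dc == 0 && dr == 0) continue;
                if (R[lj](rr2 + dr, cc + dc) >= v) { is_max = false; break; }
              }
          }
          if (!is_max) continue;
          Kp kp;
          kp.x = cc * scale_mult;
          kp.y = rr2 * scale_mult;
          kp.scale = sig[j] * scale_mult;
          kp.response = v;
          kp.octave = o;
          kp.layer = j;
          kp.gi = rr2;
          kp.gj = cc;
          kps.push_back(kp);
        }
      }
    }
    oct_Lx.push_back(Lxs);
    oct_Ly.push_back(Lys);
    if (o + 1 < octaves) cur = decimate2(Ls[layers - 1]);
  }

  // keep strongest keypoints (stable order: response desc, then x, y)
  std::vector<size_t> ord(kps.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (kps[a].response != kps[b].response)
      return kps[a].response > kps[b].response;
    if (kps[a].x != kps[b].x) return kps[a].x < kps[b].x;
    return kps[a].y < kps[b].y;
  });
  size_t n = ord.size();
  if (max_keypoints > 0 && n > (size_t)max_keypoints) n = max_keypoints;

  NumericMatrix kmat(n, 4);
  NumericMatrix desc(n, 64);
  for (size_t i = 0; i < n; ++i) {
    const Kp& kp = kps[ord[i]];
    kmat(i, 0) = kp.x;
    kmat(i, 1) = kp.y;
    kmat(i, 2) = kp.scale;
    kmat(i, 3) = kp.response;
    double d[64];
    describe(oct_Lx[kp.octave][kp.layer], oct_Ly[kp.octave][kp.layer],
             kp.gj, kp.gi, kp.scale / std::pow(2.0, kp.octave), d);
    for (int q = 0; q < 64; ++q) desc(i, q) = d[q];
  }
  colnames(kmat) = CharacterVector::create("x", "y", "scale", "response");
  return List::create(_["keypoints"] = kmat, _["descriptors"] = desc);
}
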