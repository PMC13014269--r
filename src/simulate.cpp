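#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation on a uniform grid spanning [gmin, gmax].
static inline double interp_uniform(const NumericVector &y, double gmin,
                                    double inv_h, int n, double x) {
  double u = (x - gmin) * inv_h;
  if (u <= 0.0) return y[0];
  if (u >= n - 1) return y[n - 1];
  int i = (int)u;
  double f = u - i;
  return y[i] * (1.0 - f) + y[i + 1] * f;
}

// Fold a coordinate back into [lo, hi] (reflecting boundaries).
static inline double reflect(double r, double lo, double hi) {
  double w = hi - lo;
  while (r < lo || r > hi) {
    if (r < lo) r = 2.0 * lo - r;
    if (r > hi) r = 2.0 * hi - r;
    // pathological overshoot: fold modulo 2w
    if (r < lo - 2.0 * w || r > hi + 2.0 * w) {
      double q = (r - lo) / (2.0 * w);
      double z = (q - std::floor(q)) * 2.0 * w;
      r = lo + (z <= w ? z : 2.0 * w - z);
    }
  }
  return r;
}

// Overdamped Euler-Maruyama on a 1D landscape with position-dependent D.
// drift_grid holds -D(r) F'(r) + D'(r)  (Ito spurious-drift convention, F in kT),
// noise_grid holds sqrt(2 D(r) dt). Both tabulated on a uniform grid over
// [r_min, r_max]. Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
NumericVector bd_core(double r0, int n_steps, double dt, double r_min,
                      double r_max, int save_stride,
                      NumericVector drift_grid, NumericVector noise_grid,
                      double grid_min, double grid_h) {
  int ng = drift_grid.size();
  double inv_h = 1.0 / grid_h;
  int n_save = n_steps / save_stride;
  NumericVector out(n_save);
  double r = r0;
  RNGScope scope;
  int k = 0;
  for (int s = 1; s <= n_steps; ++s) {
    double drift = interp_uniform(drift_grid, grid_min, inv_h, ng, r);
    double noise = interp_uniform(noise_grid, grid_min, inv_h, ng, r);
    r = r + drift * dt + noise * norm_rand();
    r = reflect(r, r_min, r_max);
    if (s % save_stride == 0) out[k++] = r;
  }
  return out;
}

// Overdamped Rouse chain: n_beads beads, harmonic bonds with spring constant
// 3/b^2 (kT/nm^2) so that <bond^2> = b^2 at equilibrium; every bead diffuses
// with coefficient bead_D (nm^2/ns). coords0 is an n_beads x 3 matrix of the
// initial configuration. Returns the strided end-to-end distance series and,
// if save_coords, the strided bead coordinates (n_save x (3 n_beads)).
// [[Rcpp::export]]
List rouse_core(NumericMatrix coords0, int n_steps, double dt, double bead_D,
                double bond_scale, int save_stride, bool save_coords) {
  int nb = coords0.nrow();
  double kspr = 3.0 / (bond_scale * bond_scale); // kT / nm^2
  double amp = sqrt(2.0 * bead_D * dt);
  std::vector<double> x(nb), y(nb), z(nb), fx(nb), fy(nb), fz(nb);
  for (int i = 0; i < nb; ++i) {
    x[i] = coords0(i, 0);
    y[i] = coords0(i, 1);
    z[i] = coords0(i, 2);
  }
  int n_save = n_steps / save_stride;
  NumericVector ree(n_save);
  NumericMatrix coords(save_coords ? n_save : 1, save_coords ? 3 * nb : 1);
  RNGScope scope;
  int k = 0;
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < nb; ++i) {
      double gx = 0, gy = 0, gz = 0;
      if (i > 0) {
        gx += x[i - 1] - x[i];
        gy += y[i - 1] - y[i];
        gz += z[i - 1] - z[i];
      }
      if (i < nb - 1) {
        gx += x[i + 1] - x[i];
        gy += y[i + 1] - y[i];
        gz += z[i + 1] - z[i];
      }
      fx[i] = kspr * gx;
      fy[i] = kspr * gy;
      fz[i] = kspr * gz;
    }
    for (int i = 0; i < nb; ++i) {
      x[i] += bead_D * fx[i] * dt + amp * norm_rand();
      y[i] += bead_D * fy[i] * dt + amp * norm_rand();
      z[i] += bead_D * fz[i] * dt + amp * norm_rand();
    }
    if (s % save_stride == 0) {
      double dx = x[nb - 1] - x[0], dy = y[nb - 1] - y[0],
             dz = z[nb - 1] - z[0];
      ree[k] = sqrt(dx * dx + dy * dy + dz * dz);
      if (save_coords)
        for (int i = 0; i < nb; ++i) {
          coords(k, 3 * i) = x[i];
          coords(k, 3 * i + 1) = y[i];
          coords(k, 3 * i + 2) = z[i];
        }
      ++k;
    }
  }
  if (save_coords)
    return List::create(Named("ree") = ree, Named("coords") = coords);
  return List::create(Named("ree") = ree);
}
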