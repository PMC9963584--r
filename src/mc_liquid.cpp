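// Metropolis Monte-Carlo equilibration of a purely repulsive soft-sphere
// fluid (pair energy eps*(sigma/r)^12, truncated) in a cubic periodic box.
// Uses R's RNG so configurations are reproducible from set.seed().

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static inline double min_image(double d, double L) {
  return d - L * std::ceil(d / L - 0.5);
}

static double site_energy(const NumericMatrix& pos, int i, double xi, double yi,
                          double zi, double L, double sig, double eps,
                          double rc2) {
  const int n = pos.nrow();
  double e = 0.0;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    const double dx = min_image(pos(j, 0) - xi, L);
    const double dy = min_image(pos(j, 1) - yi, L);
    const double dz = min_image(pos(j, 2) - zi, L);
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) continue;
    const double sr2 = sig * sig / r2;
    const double sr6 = sr2 * sr2 * sr2;
    e += eps * sr6 * sr6;
  }
  return e;
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix mc_soft_sphere_cpp(NumericMatrix start, double box_length,
                                 double sigma, double epsilon, int sweeps,
                                 double max_disp) {
  NumericMatrix pos = clone(start);
  const int n = pos.nrow();
  const double L = box_length;
  double rc = 2.5 * sigma;
  if (rc > 0.5 * L) rc = 0.5 * L;
  const double rc2 = rc * rc;

  for (int s = 0; s < sweeps; ++s) {
    for (int i = 0; i < n; ++i) {
      const double x0 = pos(i, 0), y0 = pos(i, 1), z0 = pos(i, 2);
      const double x1 = x0 + max_disp * (2.0 * unif_rand() - 1.0);
      const double y1 = y0 + max_disp * (2.0 * unif_rand() - 1.0);
      const double z1 = z0 + max_disp * (2.0 * unif_rand() - 1.0);
      const double de = site_energy(pos, i, x1, y1, z1, L, sigma, epsilon, rc2) -
                        site_energy(pos, i, x0, y0, z0, L, sigma, epsilon, rc2);
      if (de <= 0.0 || unif_rand() < std::exp(-de)) {
        pos(i, 0) = x1 - L * std::floor(x1 / L);
        pos(i, 1) = y1 - L * std::floor(y1 / L);
        pos(i, 2) = z1 - L * std::floor(z1 / L);
      }
    }
    if (s % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return pos;
}
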