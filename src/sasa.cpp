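#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
// Test points are placed on a golden-spiral lattice on each atom's
// solvent-expanded sphere; a point is accessible when it lies outside
// every other atom's expanded sphere.
// [[Rcpp::export(name = ".sasa_shrake_rupley")]]
NumericVector sasa_shrake_rupley(NumericMatrix coords, NumericVector radii,
                                 int n_points = 960, double probe = 1.4) {
  const int n = coords.nrow();
  NumericVector area(n);
  if (n == 0) return area;

  // golden-spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double zk = 1.0 - 2.0 * (k + 0.5) / n_points;
    double rk = std::sqrt(std::max(0.0, 1.0 - zk * zk));
    double th = golden * k;
    px[k] = rk * std::cos(th);
    py[k] = rk * std::sin(th);
    pz[k] = zk;
  }

  std::vector<double> er(n);
  for (int i = 0; i < n; ++i) er[i] = radii[i] + probe;

  std::vector<int> nb;
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    const double ri = er[i];
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
             dz = coords(j, 2) - zi;
      double lim = ri + er[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double qx = xi + ri * px[k], qy = yi + ri * py[k], qz = zi + ri * pz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = qx - coords(j, 0), dy = qy - coords(j, 1),
               dz = qz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j]) {
          free_pt = false;
          break;
        }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * acc / n_points;
  }
  return area;
}
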