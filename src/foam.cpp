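#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// For every voxel centre, find the two nearest foam seed points under the
// multiplicatively weighted distance |p - s_i| / w_i.
// seeds: n x 3 matrix of physical coordinates (z, y, x) in um; weights are
// dimensionless (>= 1). With unequal weights the cell boundaries are
// spherical (Apollonius surfaces), giving curved, alveolus-like walls;
// equal weights recover the plane-faced Voronoi tessellation.
// Returns nearest / second-nearest seed index (1-based) and the weighted
// distance gap d2 - d1; multiplying the gap by the nearest seed's weight
// approximates the physical distance (um) between the two iso-surfaces, so
// `gap * w[nearest] <= wall_thickness` carves walls of roughly the
// requested physical thickness.
// [[Rcpp::export(name = ".foam_assign_cpp")]]
List foam_assign_cpp(IntegerVector dim, double spacing, NumericMatrix seeds,
                     NumericVector weights) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int ns = seeds.nrow();
  size_t n = (size_t)nz * ny * nx;
  IntegerVector i1(n), i2(n);
  NumericVector gap(n);
  std::vector<double> sz(ns), sy(ns), sx(ns), iw(ns);
  for (int s = 0; s < ns; s++) {
    sz[s] = seeds(s, 0);
    sy[s] = seeds(s, 1);
    sx[s] = seeds(s, 2);
    iw[s] = 1.0 / (weights[s] * weights[s]);
  }
  for (int x = 0; x < nx; x++) {
    double px = x * spacing;
    for (int y = 0; y < ny; y++) {
      double py = y * spacing;
      for (int z = 0; z < nz; z++) {
        double pz = z * spacing;
        double d1 = 1e30, d2 = 1e30;
        int b1 = -1, b2 = -1;
        for (int s = 0; s < ns; s++) {
          double dz = pz - sz[s], dy = py - sy[s], dx = px - sx[s];
          double d = (dz * dz + dy * dy + dx * dx) * iw[s];
          if (d < d1) {
            d2 = d1; b2 = b1;
            d1 = d; b1 = s;
          } else if (d < d2) {
            d2 = d; b2 = s;
          }
        }
        size_t i = z + (size_t)nz * (y + (size_t)ny * x);
        i1[i] = b1 + 1;
        i2[i] = b2 + 1;
        gap[i] = (b2 >= 0) ? (std::sqrt(d2) - std::sqrt(d1)) : 1e30;
      }
    }
  }
  i1.attr("dim") = dim;
  i2.attr("dim") = dim;
  gap.attr("dim") = dim;
  return List::create(_["nearest"] = i1, _["second"] = i2, _["gap"] = gap);
}
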