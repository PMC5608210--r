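#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exact squared Euclidean distance transform, separable lower-envelope
// algorithm (Felzenszwalb & Huttenlocher). Distances in voxel units.
static const double DT_INF = 1e20;

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared EDT of `phase` (distance of phase voxels to the nearest
// non-phase voxel centre; volume virtually padded with non-phase).
// dims: (nz, ny, nx), linear index z + nz*(y + ny*x).
static std::vector<double> sq_edt_padded(const LogicalVector &phase,
                                         int nz, int ny, int nx,
                                         bool pad_feature = true) {
  // pad by one voxel on every side; the pad ring is feature (distance 0)
  // unless pad_feature is false (then the volume border is ignored)
  int pz = nz + 2, py = ny + 2, px = nx + 2;
  std::vector<double> D((size_t)pz * py * px);
  for (int x = 0; x < px; x++)
    for (int y = 0; y < py; y++)
      for (int z = 0; z < pz; z++) {
        bool inside = (z > 0 && z <= nz && y > 0 && y <= ny && x > 0 && x <= nx);
        bool ph = inside ?
          (bool)phase[(z - 1) + (size_t)nz * ((y - 1) + (size_t)ny * (x - 1))] :
          !pad_feature;
        D[z + (size_t)pz * (y + (size_t)py * x)] = ph ? DT_INF : 0.0;
      }
  int nmax = std::max(pz, std::max(py, px));
  std::vector<double> f(nmax), d(nmax), zz(nmax + 1);
  std::vector<int> vv(nmax);
  // along z
  for (int x = 0; x < px; x++)
    for (int y = 0; y < py; y++) {
      size_t base = (size_t)pz * (y + (size_t)py * x);
      for (int z = 0; z < pz; z++) f[z] = D[z + base];
      dt1d(f, d, vv, zz, pz);
      for (int z = 0; z < pz; z++) D[z + base] = d[z];
    }
  // along y
  for (int x = 0; x < px; x++)
    for (int z = 0; z < pz; z++) {
      for (int y = 0; y < py; y++) f[y] = D[z + (size_t)pz * (y + (size_t)py * x)];
      dt1d(f, d, vv, zz, py);
      for (int y = 0; y < py; y++) D[z + (size_t)pz * (y + (size_t)py * x)] = d[y];
    }
  // along x
  for (int y = 0; y < py; y++)
    for (int z = 0; z < pz; z++) {
      for (int x = 0; x < px; x++) f[x] = D[z + (size_t)pz * (y + (size_t)py * x)];
      dt1d(f, d, vv, zz, px);
      for (int x = 0; x < px; x++) D[z + (size_t)pz * (y + (size_t)py * x)] = d[x];
    }
  // unpad
  std::vector<double> out((size_t)nz * ny * nx);
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++)
      for (int z = 0; z < nz; z++)
        out[z + (size_t)nz * (y + (size_t)ny * x)] =
          D[(z + 1) + (size_t)pz * ((y + 1) + (size_t)py * (x + 1))];
  return out;
}

// [[Rcpp::export(name = ".sq_edt_cpp")]]
NumericVector sq_edt_cpp(LogicalVector phase, IntegerVector dim,
                         bool pad_feature = true) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> D = sq_edt_padded(phase, nz, ny, nx, pad_feature);
  NumericVector out(D.begin(), D.end());
  out.attr("dim") = dim;
  return out;
}

// Local thickness by maximum inscribed spheres.
// Returns tau in voxel units (diameter); 0 on non-phase voxels.
// A sphere of radius r placed at a phase voxel centre x is admissible if no
// non-phase voxel centre lies within r: max radius r(x) = dist(x) - 1/2,
// so a single isolated phase voxel carries tau = 1 voxel.
// Redundant centres (spheres contained in a 26-neighbour's sphere) are
// removed first (distance ridge); removal is exact, so propagation from the
// ridge reproduces the brute-force maximisation voxel by voxel.
// [[Rcpp::export(name = ".local_thickness_cpp")]]
NumericVector local_thickness_cpp(LogicalVector phase, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  std::vector<double> D = sq_edt_padded(phase, nz, ny, nx);
  std::vector<double> r(n, 0.0);
  std::vector<size_t> phase_idx;
  phase_idx.reserve(n / 2);
  for (size_t i = 0; i < n; i++)
    if (phase[i]) {
      r[i] = std::sqrt(D[i]) - 0.5;
      phase_idx.push_back(i);
    }
  const double tol = 1e-9;
  // distance ridge: drop x if a nearby sphere contains its sphere.
  // Domination (r(y) >= r(x) + |x-y|) strictly increases r along chains, so
  // every removed centre is transitively covered by a kept one; checking a
  // 5x5x5 neighbourhood prunes more centres than 3x3x3 and remains exact.
  const int W = 2;
  std::vector<size_t> ridge;
  ridge.reserve(phase_idx.size());
  for (size_t ii = 0; ii < phase_idx.size(); ii++) {
    size_t i = phase_idx[ii];
    int x = (int)(i / ((size_t)nz * ny));
    int y = (int)((i / nz) % ny);
    int z = (int)(i % nz);
    bool dominated = false;
    for (int dx = -W; dx <= W && !dominated; dx++)
      for (int dy = -W; dy <= W && !dominated; dy++)
        for (int dz = -W; dz <= W && !dominated; dz++) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zzl = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zzl < 0 || zzl >= nz)
            continue;
          size_t j = zzl + (size_t)nz * (yy + (size_t)ny * xx);
          if (!phase[j]) continue;
          double dist = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
          if (r[j] - dist >= r[i] - tol) dominated = true;
        }
    if (!dominated) ridge.push_back(i);
  }
  // sphere propagation, largest first, with an exact redundancy skip:
  // cov[p] tracks max over processed spheres y of (r(y) - |p - y|), the
  // depth of p inside the deepest processed sphere. A candidate x is
  // contained in some processed sphere iff cov[x] >= r(x) (processing in
  // descending r makes the containment test one lookup) and then stamps
  // nothing new, so it is skipped; the result equals the brute-force
  // maximisation voxel by voxel.
  std::sort(ridge.begin(), ridge.end(),
            [&](size_t a, size_t b) { return r[a] > r[b]; });
  std::vector<double> tau(n, 0.0), cov(n, -1.0);
  std::vector<float> proc(n, 0.0f); // radius of the sphere processed at a voxel
  for (size_t ii = 0; ii < ridge.size(); ii++) {
    size_t i = ridge[ii];
    double ri = r[i];
    if (cov[i] >= ri - tol) continue; // sphere inside a processed sphere
    double diam = 2.0 * ri;
    int x = (int)(i / ((size_t)nz * ny));
    int y = (int)((i / nz) % ny);
    int z = (int)(i % nz);
    int rr = (int)std::floor(ri + tol);
    double r2 = ri * ri + 1e-7;
    // find a nearby processed sphere with radius >= ri: its voxels already
    // carry tau >= diam, so its z-column intervals can be skipped exactly
    int oz = 0, oy = 0, ox = 0;
    double re = -1.0;
    double bestd = 1e30;
    for (int dx = -W; dx <= W; dx++)
      for (int dy = -W; dy <= W; dy++)
        for (int dz = -W; dz <= W; dz++) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz2 = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz2 < 0 || zz2 >= nz)
            continue;
          size_t j = zz2 + (size_t)nz * (yy + (size_t)ny * xx);
          double pr = (double)proc[j];
          if (pr >= ri - tol) {
            double dd = dx * dx + dy * dy + dz * dz;
            if (dd < bestd) {
              bestd = dd;
              oz = dz; oy = dy; ox = dx;
              re = pr;
            }
          }
        }
    double re2 = (re > 0) ? re * re + 1e-7 : -1.0;
    proc[i] = (float)ri;
    for (int dx = -rr; dx <= rr; dx++) {
      int xx = x + dx;
      if (xx < 0 || xx >= nx) continue;
      for (int dy = -rr; dy <= rr; dy++) {
        int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        double d2xy = (double)dx * dx + (double)dy * dy;
        if (d2xy > r2) continue;
        size_t base = (size_t)nz * (yy + (size_t)ny * xx);
        int s = (int)std::floor(std::sqrt(r2 - d2xy));
        int zlo = std::max(z - s, 0), zhi = std::min(z + s, nz - 1);
        // excluded z-interval: inside the neighbouring processed sphere
        int elo = 1, ehi = 0;
        if (re2 > 0) {
          double e2xy = (double)(dx - ox) * (dx - ox) +
                        (double)(dy - oy) * (dy - oy);
          if (e2xy <= re2) {
            int t = (int)std::floor(std::sqrt(re2 - e2xy));
            elo = z + oz - t;
            ehi = z + oz + t;
          }
        }
        for (int seg = 0; seg < 2; seg++) {
          int a = (seg == 0) ? zlo : std::max(zlo, ehi + 1);
          int b = (seg == 0) ? ((elo <= ehi) ? std::min(zhi, elo - 1) : zhi)
                             : ((elo <= ehi) ? zhi : a - 1);
          for (int zzl = a; zzl <= b; zzl++) {
            size_t j = zzl + base;
            if (tau[j] < diam) tau[j] = diam;
            double dz = (double)(zzl - z);
            double depth = ri - std::sqrt(d2xy + dz * dz);
            if (cov[j] < depth) cov[j] = depth;
          }
          if (elo > ehi) break; // no exclusion: single segment
        }
      }
    }
  }
  NumericVector out(n);
  for (size_t i = 0; i < n; i++) out[i] = phase[i] ? tau[i] : 0.0;
  out.attr("dim") = dim;
  return out;
}
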