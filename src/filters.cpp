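#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable 3D Gaussian blur, sigma in voxels, replicate boundary.
// [[Rcpp::export(name = ".gaussian_blur3d_cpp")]]
NumericVector gaussian_blur3d_cpp(NumericVector vol, IntegerVector dim,
                                  double sigma) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  if (sigma <= 0) return clone(vol);
  int rad = (int)std::ceil(3.5 * sigma);
  std::vector<double> k(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; i++) {
    k[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + rad];
  }
  for (double &v : k) v /= s;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  // blur along z, then y, then x
  for (int pass = 0; pass < 3; pass++) {
    for (int x = 0; x < nx; x++)
      for (int y = 0; y < ny; y++)
        for (int z = 0; z < nz; z++) {
          double acc = 0;
          for (int o = -rad; o <= rad; o++) {
            int zz = z, yy = y, xx = x;
            if (pass == 0) zz = std::min(std::max(z + o, 0), nz - 1);
            else if (pass == 1) yy = std::min(std::max(y + o, 0), ny - 1);
            else xx = std::min(std::max(x + o, 0), nx - 1);
            acc += k[o + rad] * a[zz + (size_t)nz * (yy + (size_t)ny * xx)];
          }
          b[z + (size_t)nz * (y + (size_t)ny * x)] = acc;
        }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Resample `vol` under an affine voxel-space map: source voxel coordinate
// q = A %*% p + b for output voxel coordinate p (both 0-based, (z,y,x)).
// Linear interpolation unless `nearest`; `fill` outside the source lattice.
// [[Rcpp::export(name = ".resample_affine_cpp")]]
NumericVector resample_affine_cpp(NumericVector vol, IntegerVector dim,
                                  NumericMatrix A, NumericVector b,
                                  IntegerVector out_dim, bool nearest,
                                  double fill) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int oz = out_dim[0], oy = out_dim[1], ox = out_dim[2];
  NumericVector out((size_t)oz * oy * ox);
  for (int x = 0; x < ox; x++)
    for (int y = 0; y < oy; y++)
      for (int z = 0; z < oz; z++) {
        double qz = A(0, 0) * z + A(0, 1) * y + A(0, 2) * x + b[0];
        double qy = A(1, 0) * z + A(1, 1) * y + A(1, 2) * x + b[1];
        double qx = A(2, 0) * z + A(2, 1) * y + A(2, 2) * x + b[2];
        size_t oi = z + (size_t)oz * (y + (size_t)oy * x);
        if (nearest) {
          int iz = (int)std::lround(qz), iy = (int)std::lround(qy),
              ix = (int)std::lround(qx);
          if (iz < 0 || iz >= nz || iy < 0 || iy >= ny || ix < 0 || ix >= nx)
            out[oi] = fill;
          else
            out[oi] = vol[iz + (size_t)nz * (iy + (size_t)ny * ix)];
        } else {
          int z0 = (int)std::floor(qz), y0 = (int)std::floor(qy),
              x0 = (int)std::floor(qx);
          if (z0 < 0 || z0 + 1 >= nz + 1 || y0 < 0 || y0 + 1 >= ny + 1 ||
              x0 < 0 || x0 + 1 >= nx + 1 || qz < 0 || qy < 0 || qx < 0 ||
              qz > nz - 1 || qy > ny - 1 || qx > nx - 1) {
            out[oi] = fill;
            continue;
          }
          double fz = qz - z0, fy = qy - y0, fx = qx - x0;
          int z1 = std::min(z0 + 1, nz - 1), y1 = std::min(y0 + 1, ny - 1),
              x1 = std::min(x0 + 1, nx - 1);
          double acc = 0;
          for (int cz = 0; cz <= 1; cz++)
            for (int cy = 0; cy <= 1; cy++)
              for (int cx = 0; cx <= 1; cx++) {
                double w = (cz ? fz : 1 - fz) * (cy ? fy : 1 - fy) *
                           (cx ? fx : 1 - fx);
                int iz = cz ? z1 : z0, iy = cy ? y1 : y0, ix = cx ? x1 : x0;
                acc += w * vol[iz + (size_t)nz * (iy + (size_t)ny * ix)];
              }
          out[oi] = acc;
        }
      }
  out.attr("dim") = out_dim;
  return out;
}

// Line-profile ridge detection on one 1D profile.
// For every local maximum: walk to the flanking minima, compute the
// prominence above the higher flank, and the contiguous run of samples
// exceeding flank + min_margin. Accept when the run width lies in
// [min_width, max_width] and the prominence in [min_margin, max_margin];
// accepted run samples are flagged.
static void scan_profile(const std::vector<double> &v,
                         const std::vector<size_t> &idx, int min_width,
                         int max_width, double min_margin, double max_margin,
                         LogicalVector &mark) {
  int n = (int)v.size();
  if (n < 3) return;
  int i = 1;
  while (i < n - 1) {
    // ascend into a peak/plateau
    if (v[i] > v[i - 1] && v[i] >= v[i + 1]) {
      int pe = i;
      while (pe + 1 < n && v[pe + 1] == v[i]) pe++;
      if (pe + 1 < n && v[pe + 1] < v[i]) {
        // true local maximum spanning [i, pe]
        int jl = i;
        while (jl > 0 && v[jl - 1] <= v[jl]) jl--;
        int jr = pe;
        while (jr < n - 1 && v[jr + 1] <= v[jr]) jr++;
        double flank = std::max(v[jl], v[jr]);
        double prom = v[i] - flank;
        if (prom >= min_margin && prom <= max_margin) {
          double cut = flank + min_margin;
          int rl = i, rr = pe;
          while (rl > 0 && v[rl - 1] > cut) rl--;
          while (rr < n - 1 && v[rr + 1] > cut) rr++;
          int width = rr - rl + 1;
          if (width >= min_width && width <= max_width)
            for (int q = rl; q <= rr; q++) mark[idx[q]] = true;
        }
      }
      i = pe + 1;
    } else {
      i++;
    }
  }
}

// Ridge enhancement over all slices of a volume: line profiles along
// 0, 45, 90 and 135 degrees within each (y, x) slice.
// directions: logical length-4 vector for (0, 45, 90, 135).
// [[Rcpp::export(name = ".ridge_mark_cpp")]]
LogicalVector ridge_mark_cpp(NumericVector vol, IntegerVector dim,
                             int min_width, int max_width, double min_margin,
                             double max_margin, LogicalVector directions) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector mark((size_t)nz * ny * nx);
  std::vector<double> v;
  std::vector<size_t> idx;
  for (int z = 0; z < nz; z++) {
    // 0 degrees: along x
    if (directions[0])
      for (int y = 0; y < ny; y++) {
        v.clear(); idx.clear();
        for (int x = 0; x < nx; x++) {
          size_t i = z + (size_t)nz * (y + (size_t)ny * x);
          v.push_back(vol[i]); idx.push_back(i);
        }
        scan_profile(v, idx, min_width, max_width, min_margin, max_margin, mark);
      }
    // 90 degrees: along y
    if (directions[2])
      for (int x = 0; x < nx; x++) {
        v.clear(); idx.clear();
        for (int y = 0; y < ny; y++) {
          size_t i = z + (size_t)nz * (y + (size_t)ny * x);
          v.push_back(vol[i]); idx.push_back(i);
        }
        scan_profile(v, idx, min_width, max_width, min_margin, max_margin, mark);
      }
    // 45 degrees: step (+1, +1) in (y, x)
    if (directions[1])
      for (int s = -(ny - 1); s <= nx - 1; s++) {
        v.clear(); idx.clear();
        for (int y = std::max(0, -s); y < ny; y++) {
          int x = y + s;
          if (x < 0 || x >= nx) continue;
          size_t i = z + (size_t)nz * (y + (size_t)ny * x);
          v.push_back(vol[i]); idx.push_back(i);
        }
        scan_profile(v, idx, min_width, max_width, min_margin, max_margin, mark);
      }
    // 135 degrees: step (+1, -1) in (y, x)
    if (directions[3])
      for (int s = 0; s <= nx + ny - 2; s++) {
        v.clear(); idx.clear();
        for (int y = 0; y < ny; y++) {
          int x = s - y;
          if (x < 0 || x >= nx) continue;
          size_t i = z + (size_t)nz * (y + (size_t)ny * x);
          v.push_back(vol[i]); idx.push_back(i);
        }
        scan_profile(v, idx, min_width, max_width, min_margin, max_margin, mark);
      }
  }
  mark.attr("dim") = dim;
  return mark;
}
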