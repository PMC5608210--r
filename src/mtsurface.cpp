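#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Iso-surface of the air phase at level 1/2, by marching over the
// Freudenthal (6-tetrahedra) simplicial subdivision of the voxel lattice.
// The subdivision is translation invariant, so shared cube faces carry the
// same diagonal in adjacent cells and the resulting mesh is edge-manifold.
// Binary input puts every surface vertex at a lattice-edge midpoint.
// Triangles are wound so normals point from air toward tissue. Cells are
// formed between existing voxel centres only: air touching the volume
// border yields an open mesh there (no artificial caps).

struct Key64Hash {
  size_t operator()(const uint64_t &k) const { return std::hash<uint64_t>()(k); }
};

// [[Rcpp::export(name = ".extract_surface_cpp")]]
List extract_surface_cpp(LogicalVector air, IntegerVector dim, double spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  // Freudenthal tets: vertex order along monotone lattice paths 0 -> (1,1,1)
  static const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                  {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  std::unordered_map<uint64_t, int, Key64Hash> vmap;
  std::vector<double> vz, vy, vx;
  std::vector<int> tri;
  size_t N = (size_t)nz * ny * nx;
  auto lin = [&](int z, int y, int x) -> uint64_t {
    return (uint64_t)z + (uint64_t)nz * ((uint64_t)y + (uint64_t)ny * x);
  };
  // tet corner offsets (z,y,x per corner) for the 6 permutations
  int tets[6][4][3];
  for (int p = 0; p < 6; p++) {
    int c[3] = {0, 0, 0};
    for (int k = 0; k < 3; k++) {
      tets[p][k][0] = c[0]; tets[p][k][1] = c[1]; tets[p][k][2] = c[2];
      c[perms[p][k]] = 1;
    }
    tets[p][3][0] = 1; tets[p][3][1] = 1; tets[p][3][2] = 1;
  }
  auto vertex_at = [&](uint64_t a, uint64_t b) -> int {
    uint64_t lo = std::min(a, b), hi = std::max(a, b);
    uint64_t key = lo * (uint64_t)N + hi;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    int id = (int)vz.size();
    // midpoint of the lattice edge, in voxel coordinates
    double az = (double)(a % nz), ay = (double)((a / nz) % ny),
           ax = (double)(a / ((uint64_t)nz * ny));
    double bz = (double)(b % nz), by = (double)((b / nz) % ny),
           bx = (double)(b / ((uint64_t)nz * ny));
    vz.push_back(0.5 * (az + bz));
    vy.push_back(0.5 * (ay + by));
    vx.push_back(0.5 * (ax + bx));
    vmap[key] = id;
    return id;
  };
  auto emit = [&](int a, int b, int c, const double refd[3]) {
    // orient so the triangle normal has positive dot with refd (air->tissue)
    double e1z = vz[b] - vz[a], e1y = vy[b] - vy[a], e1x = vx[b] - vx[a];
    double e2z = vz[c] - vz[a], e2y = vy[c] - vy[a], e2x = vx[c] - vx[a];
    double nzc = e1y * e2x - e1x * e2y;
    double nyc = e1x * e2z - e1z * e2x;
    double nxc = e1z * e2y - e1y * e2z;
    // note: cross in (z,y,x) component order equals the (x,y,z) formula
    // with components permuted consistently; only the sign of the dot
    // product with refd (same component order) matters here
    double d = nzc * refd[0] + nyc * refd[1] + nxc * refd[2];
    if (d >= 0) {
      tri.push_back(a + 1); tri.push_back(b + 1); tri.push_back(c + 1);
    } else {
      tri.push_back(a + 1); tri.push_back(c + 1); tri.push_back(b + 1);
    }
  };
  for (int x = 0; x < nx - 1; x++)
    for (int y = 0; y < ny - 1; y++)
      for (int z = 0; z < nz - 1; z++) {
        // skip uniform cells fast
        bool any_air = false, any_tis = false;
        for (int dz = 0; dz <= 1; dz++)
          for (int dy = 0; dy <= 1; dy++)
            for (int dx = 0; dx <= 1; dx++) {
              if (air[lin(z + dz, y + dy, x + dx)]) any_air = true;
              else any_tis = true;
            }
        if (!any_air || !any_tis) continue;
        for (int p = 0; p < 6; p++) {
          uint64_t id[4];
          bool a[4];
          double cz[4], cy[4], cx[4];
          int nair = 0;
          for (int k = 0; k < 4; k++) {
            int tz = z + tets[p][k][0], ty = y + tets[p][k][1],
                tx = x + tets[p][k][2];
            id[k] = lin(tz, ty, tx);
            cz[k] = tz; cy[k] = ty; cx[k] = tx;
            a[k] = air[id[k]];
            if (a[k]) nair++;
          }
          if (nair == 0 || nair == 4) continue;
          // reference direction: centroid(tissue) - centroid(air)
          double refd[3] = {0, 0, 0};
          double ca[3] = {0, 0, 0}, ct[3] = {0, 0, 0};
          int na = 0, nt = 0;
          for (int k = 0; k < 4; k++) {
            if (a[k]) { ca[0] += cz[k]; ca[1] += cy[k]; ca[2] += cx[k]; na++; }
            else { ct[0] += cz[k]; ct[1] += cy[k]; ct[2] += cx[k]; nt++; }
          }
          for (int q = 0; q < 3; q++) refd[q] = ct[q] / nt - ca[q] / na;
          if (nair == 1 || nair == 3) {
            int lone = -1;
            for (int k = 0; k < 4; k++)
              if (a[k] == (nair == 1)) lone = k;
            int oth[3], m = 0;
            for (int k = 0; k < 4; k++)
              if (k != lone) oth[m++] = k;
            int u = vertex_at(id[lone], id[oth[0]]);
            int v = vertex_at(id[lone], id[oth[1]]);
            int w = vertex_at(id[lone], id[oth[2]]);
            emit(u, v, w, refd);
          } else {
            // two air, two tissue: quad across the four mixed edges
            int ai[2], ti[2], m1 = 0, m2 = 0;
            for (int k = 0; k < 4; k++) {
              if (a[k]) ai[m1++] = k;
              else ti[m2++] = k;
            }
            int q1 = vertex_at(id[ai[0]], id[ti[0]]);
            int q2 = vertex_at(id[ai[0]], id[ti[1]]);
            int q3 = vertex_at(id[ai[1]], id[ti[1]]);
            int q4 = vertex_at(id[ai[1]], id[ti[0]]);
            emit(q1, q2, q3, refd);
            emit(q1, q3, q4, refd);
          }
        }
      }
  int nv = (int)vz.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; i++) {
    V(i, 0) = vz[i] * spacing;
    V(i, 1) = vy[i] * spacing;
    V(i, 2) = vx[i] * spacing;
  }
  int nt = (int)tri.size() / 3;
  IntegerMatrix T(nt, 3);
  for (int i = 0; i < nt; i++) {
    T(i, 0) = tri[3 * i];
    T(i, 1) = tri[3 * i + 1];
    T(i, 2) = tri[3 * i + 2];
  }
  return List::create(_["vertices"] = V, _["triangles"] = T);
}
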