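#include <Rcpp.h>
#include <vector>
#include <queue>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Normal-cycle curvature tensor with geodesic neighbourhoods.
//
// For each vertex v, all mesh edges inside the geodesic ball B(v, R)
// (Dijkstra over the edge graph with Euclidean weights) contribute
// beta(e) * len(e within B) * ebar ebar^T, where beta is the signed
// dihedral angle across e (positive for edges convex toward the vertex
// normal side). The accumulated tensor is divided by the barycentric area
// of the ball and restricted to the tangent plane of v; its eigenvalues
// are the principal curvature estimates (reported sorted, kappa1 <= kappa2).
// Vertices whose ball touches a mesh boundary are flagged excluded.
//
// Vertices are (z, y, x) in um; cross products use the same component
// order as the surface extractor so that the orientation convention
// (normals from air toward tissue) carries through.

static inline void cross3(const double a[3], const double b[3], double out[3]) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double a[3], const double b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// [[Rcpp::export(name = ".curvature_cpp")]]
List curvature_cpp(NumericMatrix V, IntegerMatrix T, NumericMatrix VN,
                   double radius, int stride = 1) {
  int nv = V.nrow(), nt = T.nrow();
  // face normals (unnormalised = 2*area vector) and areas
  std::vector<double> fn(3 * (size_t)nt), farea(nt);
  std::vector<double> varea(nv, 0.0);
  for (int f = 0; f < nt; f++) {
    int a = T(f, 0) - 1, b = T(f, 1) - 1, c = T(f, 2) - 1;
    double e1[3] = {V(b, 0) - V(a, 0), V(b, 1) - V(a, 1), V(b, 2) - V(a, 2)};
    double e2[3] = {V(c, 0) - V(a, 0), V(c, 1) - V(a, 1), V(c, 2) - V(a, 2)};
    double n[3];
    cross3(e1, e2, n);
    double l = std::sqrt(dot3(n, n));
    farea[f] = 0.5 * l;
    for (int q = 0; q < 3; q++) fn[3 * (size_t)f + q] = (l > 0) ? n[q] / l : 0.0;
    double a3 = farea[f] / 3.0;
    varea[a] += a3; varea[b] += a3; varea[c] += a3;
  }
  // edge table: key = lo * nv + hi
  struct Edge { int i, j, f1, f2; };
  std::unordered_map<uint64_t, int> emap;
  std::vector<Edge> edges;
  edges.reserve(3 * (size_t)nt / 2);
  for (int f = 0; f < nt; f++)
    for (int k = 0; k < 3; k++) {
      int i = T(f, k) - 1, j = T(f, (k + 1) % 3) - 1;
      uint64_t key = (uint64_t)std::min(i, j) * nv + std::max(i, j);
      auto it = emap.find(key);
      if (it == emap.end()) {
        emap[key] = (int)edges.size();
        edges.push_back({std::min(i, j), std::max(i, j), f, -1});
      } else if (edges[it->second].f2 < 0) {
        edges[it->second].f2 = f;
      }
    }
  int ne = (int)edges.size();
  std::vector<double> elen(ne), beta(ne), edir(3 * (size_t)ne);
  std::vector<bool> vboundary(nv, false);
  for (int e = 0; e < ne; e++) {
    int i = edges[e].i, j = edges[e].j;
    double d[3] = {V(j, 0) - V(i, 0), V(j, 1) - V(i, 1), V(j, 2) - V(i, 2)};
    double l = std::sqrt(dot3(d, d));
    elen[e] = l;
    for (int q = 0; q < 3; q++) edir[3 * (size_t)e + q] = (l > 0) ? d[q] / l : 0.0;
    if (edges[e].f2 < 0) {
      vboundary[i] = vboundary[j] = true;
      beta[e] = 0.0;
      continue;
    }
    const double *n1 = &fn[3 * (size_t)edges[e].f1];
    const double *n2 = &fn[3 * (size_t)edges[e].f2];
    double cx[3];
    cross3(n1, n2, cx);
    double sgn = dot3(cx, &edir[3 * (size_t)e]);
    // determine whether f1 traverses the edge as i -> j; if not, flip sign
    int f = edges[e].f1;
    bool fwd = false;
    for (int k = 0; k < 3; k++)
      if (T(f, k) - 1 == i && T(f, (k + 1) % 3) - 1 == j) fwd = true;
    if (!fwd) sgn = -sgn;
    double ang = std::atan2(std::fabs(sgn), dot3(n1, n2));
    beta[e] = (sgn >= 0) ? ang : -ang;
  }
  // vertex -> incident edges adjacency (CSR)
  std::vector<int> deg(nv, 0);
  for (int e = 0; e < ne; e++) { deg[edges[e].i]++; deg[edges[e].j]++; }
  std::vector<int> off(nv + 1, 0);
  for (int v = 0; v < nv; v++) off[v + 1] = off[v] + deg[v];
  std::vector<int> adj(off[nv]);
  std::vector<int> fill(nv, 0);
  for (int e = 0; e < ne; e++) {
    adj[off[edges[e].i] + fill[edges[e].i]++] = e;
    adj[off[edges[e].j] + fill[edges[e].j]++] = e;
  }
  NumericVector k1(nv), k2(nv);
  LogicalVector excluded(nv);
  std::vector<double> dist(nv, -1.0);
  std::vector<int> touched, ball, seen;
  std::vector<char> eflag(ne, 0);
  touched.reserve(1024);
  ball.reserve(1024);
  seen.reserve(4096);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int v = 0; v < nv; v++) {
    if (stride > 1 && (v % stride)) { // vertex not sampled
      k1[v] = k2[v] = 0.0;
      excluded[v] = true;
      continue;
    }
    // Dijkstra ball
    touched.clear();
    ball.clear();
    seen.clear();
    dist[v] = 0.0;
    touched.push_back(v);
    pq.push(QE(0.0, v));
    bool bnd = vboundary[v];
    while (!pq.empty()) {
      QE top = pq.top();
      pq.pop();
      int u = top.second;
      if (top.first > dist[u] + 1e-12) continue;
      ball.push_back(u);
      if (vboundary[u]) bnd = true;
      for (int p = off[u]; p < off[u + 1]; p++) {
        int e = adj[p];
        int w = edges[e].i == u ? edges[e].j : edges[e].i;
        double nd = dist[u] + elen[e];
        if (nd <= radius && (dist[w] < 0 || nd < dist[w] - 1e-12)) {
          if (dist[w] < 0) touched.push_back(w);
          dist[w] = nd;
          pq.push(QE(nd, w));
        }
      }
    }
    // accumulate tensor over edges with at least one endpoint in the ball
    double Tm[6] = {0, 0, 0, 0, 0, 0}; // zz, zy, zx, yy, yx, xx
    double area = 0.0;
    for (size_t bi = 0; bi < ball.size(); bi++) area += varea[ball[bi]];
    for (size_t bi = 0; bi < ball.size(); bi++) {
      int u = ball[bi];
      for (int p = off[u]; p < off[u + 1]; p++) {
        int e = adj[p];
        if (eflag[e]) continue;
        eflag[e] = 1;
        seen.push_back(e);
        int i = edges[e].i, j = edges[e].j;
        double di = dist[i] >= 0 ? dist[i] : 1e30;
        double dj = dist[j] >= 0 ? dist[j] : 1e30;
        double dmin = std::min(di, dj);
        if (dmin > radius) continue;
        double frac;
        if (std::max(di, dj) <= radius) frac = 1.0;
        else frac = std::min(1.0, std::max(0.0, (radius - dmin) / elen[e]));
        double w = beta[e] * elen[e] * frac;
        const double *d = &edir[3 * (size_t)e];
        Tm[0] += w * d[0] * d[0];
        Tm[1] += w * d[0] * d[1];
        Tm[2] += w * d[0] * d[2];
        Tm[3] += w * d[1] * d[1];
        Tm[4] += w * d[1] * d[2];
        Tm[5] += w * d[2] * d[2];
      }
    }
    for (size_t si = 0; si < seen.size(); si++) eflag[seen[si]] = 0;
    for (size_t ti = 0; ti < touched.size(); ti++) dist[touched[ti]] = -1.0;
    excluded[v] = bnd;
    if (area <= 0 || ball.size() < 2) {
      k1[v] = k2[v] = 0.0;
      excluded[v] = true;
      continue;
    }
    for (int q = 0; q < 6; q++) Tm[q] /= area;
    // tangent basis perpendicular to the vertex normal
    double n[3] = {VN(v, 0), VN(v, 1), VN(v, 2)};
    double t1[3];
    double ref[3] = {1, 0, 0};
    if (std::fabs(n[0]) > 0.9) { ref[0] = 0; ref[1] = 1; }
    cross3(n, ref, t1);
    double l1 = std::sqrt(dot3(t1, t1));
    for (int q = 0; q < 3; q++) t1[q] /= (l1 > 0 ? l1 : 1);
    double t2[3];
    cross3(n, t1, t2);
    auto quad = [&](const double a[3], const double b[3]) {
      double Ta0 = Tm[0] * a[0] + Tm[1] * a[1] + Tm[2] * a[2];
      double Ta1 = Tm[1] * a[0] + Tm[3] * a[1] + Tm[4] * a[2];
      double Ta2 = Tm[2] * a[0] + Tm[4] * a[1] + Tm[5] * a[2];
      return Ta0 * b[0] + Ta1 * b[1] + Ta2 * b[2];
    };
    double m11 = quad(t1, t1), m12 = quad(t1, t2), m22 = quad(t2, t2);
    double tr = m11 + m22;
    double det = m11 * m22 - m12 * m12;
    double disc = std::sqrt(std::max(0.0, tr * tr / 4.0 - det));
    double la = tr / 2.0 + disc, lb = tr / 2.0 - disc;
    k1[v] = std::min(la, lb);
    k2[v] = std::max(la, lb);
  }
  return List::create(_["kappa1"] = k1, _["kappa2"] = k2,
                      _["excluded"] = excluded);
}

// Signed volume enclosed by a closed mesh (divergence theorem).
// [[Rcpp::export(name = ".mesh_volume_cpp")]]
double mesh_volume_cpp(NumericMatrix V, IntegerMatrix T) {
  double vol = 0.0;
  for (int f = 0; f < T.nrow(); f++) {
    int a = T(f, 0) - 1, b = T(f, 1) - 1, c = T(f, 2) - 1;
    double va[3] = {V(a, 0), V(a, 1), V(a, 2)};
    double vb[3] = {V(b, 0), V(b, 1), V(b, 2)};
    double vc[3] = {V(c, 0), V(c, 1), V(c, 2)};
    double cx[3];
    cross3(vb, vc, cx);
    vol += dot3(va, cx) / 6.0;
  }
  return std::fabs(vol);
}
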