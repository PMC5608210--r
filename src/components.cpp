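#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling on a boolean volume.
// connectivity: 6 (faces) or 26 (faces+edges+corners). Labels start at 1,
// assigned in scan order; 0 marks background.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  IntegerVector lab(n);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    next++;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      size_t i = stack.back();
      stack.pop_back();
      int x = (int)(i / ((size_t)nz * ny));
      int y = (int)((i / nz) % ny);
      int z = (int)(i % nz);
      for (int dx = -1; dx <= 1; dx++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dz = -1; dz <= 1; dz++) {
            int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (ad == 0) continue;
            if (connectivity == 6 && ad != 1) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            size_t j = zz + (size_t)nz * (yy + (size_t)ny * xx);
            if (mask[j] && !lab[j]) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Count tissue neighbours in the 26-neighbourhood of every voxel.
// [[Rcpp::export(name = ".neighbor_count_cpp")]]
IntegerVector neighbor_count_cpp(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  IntegerVector cnt(n);
  for (size_t i = 0; i < n; i++) {
    if (!mask[i]) continue;
    int x = (int)(i / ((size_t)nz * ny));
    int y = (int)((i / nz) % ny);
    int z = (int)(i % nz);
    int c = 0;
    for (int dx = -1; dx <= 1; dx++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dz = -1; dz <= 1; dz++) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          if (mask[zz + (size_t)nz * (yy + (size_t)ny * xx)]) c++;
        }
    cnt[i] = c;
  }
  cnt.attr("dim") = dim;
  return cnt;
}
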