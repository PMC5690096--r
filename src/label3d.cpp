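#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D connected-component labeling of a logical mask by breadth-first flood
// fill. connectivity is 6 (faces) or 26 (faces+edges+corners). Returns an
// integer array of the same shape with 0 for background and 1..n_components
// for foreground, labels ordered by first-encountered voxel (column-major).
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dim, int connectivity = 26) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");

  std::vector<int> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back(dx);
        off.push_back(dy);
        off.push_back(dz);
      }

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      int rem = (int)(cur - (R_xlen_t)z * nx * ny);
      int y = rem / nx, x = rem % nx;
      for (size_t j = 0; j < off.size(); j += 3) {
        int xx = x + off[j], yy = y + off[j + 1], zz = z + off[j + 2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t nb = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[nb] && lab[nb] == 0) {
          lab[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  lab.attr("n_components") = next;
  return lab;
}
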