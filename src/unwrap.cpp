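#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Quality-guided region-growing phase unwrapping on a 3-D grid (6-connected).
// Each connected component of the mask is grown independently from its
// highest-quality voxel; a neighbour is unwrapped by adding the multiple of
// 2*pi that brings it closest to the already-unwrapped voxel it was reached
// from. Returns the unwrapped phase plus the component index per voxel.
// The result is defined up to one additive 2*pi*k constant per component.

struct QItem {
  double q;
  R_xlen_t idx;
  R_xlen_t from;
};
struct QLess {
  bool operator()(const QItem& a, const QItem& b) const { return a.q < b.q; }
};

// [[Rcpp::export(name = ".unwrap_qg")]]
List unwrap_qg(NumericVector wrapped, LogicalVector mask, NumericVector quality,
               IntegerVector dim) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (wrapped.size() != n || mask.size() != n || quality.size() != n)
    stop("input lengths do not match dim");
  const double TWO_PI = 2.0 * M_PI;

  NumericVector out(n, NA_REAL);
  IntegerVector comp(n, 0);
  std::vector<char> done(n, 0);
  const int dxs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};

  int ncomp = 0;
  for (R_xlen_t seed0 = 0; seed0 < n; ++seed0) {
    if (!mask[seed0] || done[seed0]) continue;
    // find the best-quality voxel of this not-yet-visited component by a
    // cheap flood fill, then grow from it
    std::vector<R_xlen_t> members;
    {
      std::vector<R_xlen_t> stack(1, seed0);
      ++ncomp;
      comp[seed0] = ncomp;
      while (!stack.empty()) {
        R_xlen_t cur = stack.back();
        stack.pop_back();
        members.push_back(cur);
        int z = (int)(cur / ((R_xlen_t)nx * ny));
        int rem = (int)(cur - (R_xlen_t)z * nx * ny);
        int y = rem / nx, x = rem % nx;
        for (int j = 0; j < 6; ++j) {
          int xx = x + dxs[j], yy = y + dys[j], zz = z + dzs[j];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          R_xlen_t nb = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
          if (mask[nb] && comp[nb] == 0) {
            comp[nb] = ncomp;
            stack.push_back(nb);
          }
        }
      }
    }
    R_xlen_t seed = members[0];
    for (R_xlen_t m : members)
      if (quality[m] > quality[seed]) seed = m;

    std::priority_queue<QItem, std::vector<QItem>, QLess> pq;
    out[seed] = wrapped[seed];
    done[seed] = 1;
    pq.push(QItem{quality[seed], seed, seed});
    while (!pq.empty()) {
      QItem it = pq.top();
      pq.pop();
      R_xlen_t cur = it.idx;
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      int rem = (int)(cur - (R_xlen_t)z * nx * ny);
      int y = rem / nx, x = rem % nx;
      for (int j = 0; j < 6; ++j) {
        int xx = x + dxs[j], yy = y + dys[j], zz = z + dzs[j];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t nb = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (!mask[nb] || done[nb]) continue;
        double ref = out[cur];
        double w = wrapped[nb];
        out[nb] = w - TWO_PI * std::round((w - ref) / TWO_PI);
        done[nb] = 1;
        pq.push(QItem{quality[nb], nb, cur});
      }
    }
  }
  out.attr("dim") = dim;
  comp.attr("dim") = dim;
  return List::create(_["unwrapped"] = out, _["component"] = comp,
                      _["n_components"] = ncomp);
}
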