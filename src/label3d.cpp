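#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D connected-component labeling with 26-connectivity.
//
// mask: logical vector in column-major (x fastest) order; dim = c(nx, ny, nz).
// Returns integer labels (0 = background) plus per-component voxel counts and
// 0-based coordinate sums (for centroid computation in R).
//
// Iterative flood fill with an explicit stack; label ids are assigned in
// raster-scan order of each component's first voxel, so labeling is
// deterministic for a given mask.
// [[Rcpp::export]]
List label_components_3d(LogicalVector mask, IntegerVector dim) {
  if (dim.size() != 3) stop("dim must have length 3");
  const R_xlen_t nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");

  IntegerVector labels(n, 0);
  std::vector<double> cnt, sx, sy, sz;
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    cnt.push_back(0.0); sx.push_back(0.0); sy.push_back(0.0); sz.push_back(0.0);
    stack.clear();
    stack.push_back(start);
    labels[start] = next_label;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      R_xlen_t x = v % nx;
      R_xlen_t y = (v / nx) % ny;
      R_xlen_t z = v / (nx * ny);
      cnt[next_label - 1] += 1.0;
      sx[next_label - 1] += (double)x;
      sy[next_label - 1] += (double)y;
      sz[next_label - 1] += (double)z;
      for (int dz = -1; dz <= 1; ++dz) {
        R_xlen_t zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          R_xlen_t yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            R_xlen_t xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            R_xlen_t w = xx + nx * (yy + ny * zz);
            if (mask[w] && labels[w] == 0) {
              labels[w] = next_label;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }

  return List::create(
    _["labels"] = labels,
    _["n_components"] = next_label,
    _["voxel_count"] = NumericVector(cnt.begin(), cnt.end()),
    _["sum_x"] = NumericVector(sx.begin(), sx.end()),
    _["sum_y"] = NumericVector(sy.begin(), sy.end()),
    _["sum_z"] = NumericVector(sz.begin(), sz.end()));
}
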