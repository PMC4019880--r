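#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling over a binary mask stored in R's
// column-major order (dim = ny, nx, nz; linear index = y + ny*(x + nx*z)).
// Labels are assigned in raster-scan order of each component's first voxel
// (i.e. ascending linear index), which makes the labeling deterministic.
// connectivity: 6 (faces), 18 (faces+edges) or 26 (full neighborhood).

// [[Rcpp::export(name = ".cc3d_label")]]
IntegerVector cc3d_label(LogicalVector mask, IntegerVector dims,
                         int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (mask.size() != n) stop("mask size does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offset table
  std::vector<int> dy, dx, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cx = -1; cx <= 1; ++cx)
      for (int cy = -1; cy <= 1; ++cy) {
        if (cy == 0 && cx == 0 && cz == 0) continue;
        int manhattan = std::abs(cy) + std::abs(cx) + std::abs(cz);
        if (connectivity == 6 && manhattan > 1) continue;
        if (connectivity == 18 && manhattan > 2) continue;
        dy.push_back(cy); dx.push_back(cx); dz.push_back(cz);
      }
  const int nn = (int)dy.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || mask[i] == NA_LOGICAL || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int y = (int)(v % ny);
      int x = (int)((v / ny) % nx);
      int z = (int)(v / ((R_xlen_t)ny * nx));
      for (int k = 0; k < nn; ++k) {
        int yy = y + dy[k], xx = x + dx[k], zz = z + dz[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = yy + (R_xlen_t)ny * (xx + (R_xlen_t)nx * zz);
        if (mask[w] && mask[w] != NA_LOGICAL && labels[w] == 0) {
          labels[w] = next_label;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}
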