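#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Binary dilation/erosion with an arbitrary structuring element given as a
// matrix of integer voxel offsets (m x 3). The volume is zero-padded: voxels
// outside the grid count as background.
// [[Rcpp::export]]
IntegerVector morph_cpp(IntegerVector grid, IntegerVector dims, IntegerMatrix offsets,
                        bool dilate) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int m = offsets.nrow();
  IntegerVector out(grid.size());
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        bool hit = dilate ? false : true;
        for (int t = 0; t < m; t++) {
          int ii = i + offsets(t, 0), jj = j + offsets(t, 1), kk = k + offsets(t, 2);
          int v = 0;
          if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
            v = grid[((size_t)kk * ny + jj) * nx + ii];
          if (dilate) { if (v) { hit = true; break; } }
          else        { if (!v) { hit = false; break; } }
        }
        out[((size_t)k * ny + j) * nx + i] = hit ? 1 : 0;
      }
  return out;
}

// Majority (median) filter of a binary volume over a footprint of offsets;
// zero-padded boundary. Output voxel is 1 iff foreground strictly outnumbers
// background within the footprint.
// [[Rcpp::export]]
IntegerVector median_cpp(IntegerVector grid, IntegerVector dims, IntegerMatrix offsets) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int m = offsets.nrow();
  IntegerVector out(grid.size());
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        int cnt = 0;
        for (int t = 0; t < m; t++) {
          int ii = i + offsets(t, 0), jj = j + offsets(t, 1), kk = k + offsets(t, 2);
          if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
            cnt += grid[((size_t)kk * ny + jj) * nx + ii];
        }
        out[((size_t)k * ny + j) * nx + i] = (2 * cnt > m) ? 1 : 0;
      }
  return out;
}

// 26-connected component labelling; labels assigned in raster-scan discovery
// order starting at 1, background 0.
// [[Rcpp::export]]
IntegerVector components_cpp(IntegerVector grid, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; s++) {
    if (!grid[s] || lab[s]) continue;
    next++;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      size_t c = stack.back(); stack.pop_back();
      int i = c % nx, j = (c / nx) % ny, k = c / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
            size_t t = ((size_t)kk * ny + jj) * nx + ii;
            if (grid[t] && !lab[t]) { lab[t] = next; stack.push_back(t); }
          }
    }
  }
  return lab;
}
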