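#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Iso-surface of a scalar grid via tetrahedral decomposition of each cell
// (the marching-tetrahedra variant of marching cubes: 6 tetrahedra per cube
// sharing the main diagonal, iso-crossing vertices linearly interpolated on
// cell edges, so the result is watertight by construction on any grid).
// Vertices are returned in index space (node (i,j,k) at coordinate (i,j,k));
// triangle winding is made globally outward by orienting each facet away
// from the inside corners of its tetrahedron.

static const int TET[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
};

// [[Rcpp::export]]
List march_tets_cpp(NumericVector grid, IntegerVector dims, double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nnode = (size_t)nx * ny * nz;
  MTState st;
  double cpos[8][3];
  double cval[8];
  uint64_t cid[8];

  for (int k = 0; k + 1 < nz; k++)
    for (int j = 0; j + 1 < ny; j++)
      for (int i = 0; i + 1 < nx; i++) {
        for (int c = 0; c < 8; c++) {
          int ii = i + (c & 1), jj = j + ((c >> 1) & 1), kk = k + ((c >> 2) & 1);
          cpos[c][0] = ii; cpos[c][1] = jj; cpos[c][2] = kk;
          cid[c] = ((uint64_t)kk * ny + jj) * nx + ii;
          cval[c] = grid[cid[c]];
        }
        for (int t = 0; t < 6; t++) {
          const int *tv = TET[t];
          int inside[4], nin = 0;
          for (int a = 0; a < 4; a++) {
            inside[a] = cval[tv[a]] > iso;
            nin += inside[a];
          }
          if (nin == 0 || nin == 4) continue;

          // edge-interpolated vertex, deduplicated on global node pairs
          auto edge_pt = [&](int a, int b) -> int {
            uint64_t ia = cid[tv[a]], ib = cid[tv[b]];
            uint64_t key = ia < ib ? ia * nnode + ib : ib * nnode + ia;
            auto it = st.edge_vertex.find(key);
            if (it != st.edge_vertex.end()) return it->second;
            double va = cval[tv[a]], vb = cval[tv[b]];
            double u = (iso - va) / (vb - va);
            int id = (int)st.vx.size();
            st.vx.push_back(cpos[tv[a]][0] + u * (cpos[tv[b]][0] - cpos[tv[a]][0]));
            st.vy.push_back(cpos[tv[a]][1] + u * (cpos[tv[b]][1] - cpos[tv[a]][1]));
            st.vz.push_back(cpos[tv[a]][2] + u * (cpos[tv[b]][2] - cpos[tv[a]][2]));
            st.edge_vertex[key] = id;
            return id;
          };

          // centroid of inside corners minus centroid of outside corners
          double din[3] = {0, 0, 0}, dout[3] = {0, 0, 0};
          int cin = 0, cout = 0;
          for (int a = 0; a < 4; a++) {
            double *acc = inside[a] ? din : dout;
            for (int d = 0; d < 3; d++) acc[d] += cpos[tv[a]][d];
            if (inside[a]) cin++; else cout++;
          }
          for (int d = 0; d < 3; d++) { din[d] /= cin; dout[d] /= cout; }

          auto emit = [&](int p0, int p1, int p2) {
            double ax = st.vx[p1] - st.vx[p0], ay = st.vy[p1] - st.vy[p0], az = st.vz[p1] - st.vz[p0];
            double bx = st.vx[p2] - st.vx[p0], by = st.vy[p2] - st.vy[p0], bz = st.vz[p2] - st.vz[p0];
            double nxv = ay * bz - az * by, nyv = az * bx - ax * bz, nzv = ax * by - ay * bx;
            double ox = dout[0] - din[0], oy = dout[1] - din[1], oz = dout[2] - din[2];
            if (nxv * ox + nyv * oy + nzv * oz < 0) std::swap(p1, p2);
            st.tri.push_back(p0); st.tri.push_back(p1); st.tri.push_back(p2);
          };

          if (nin == 1 || nin == 3) {
            int apex = -1;
            for (int a = 0; a < 4; a++)
              if ((nin == 1 && inside[a]) || (nin == 3 && !inside[a])) apex = a;
            int others[3], o = 0;
            for (int a = 0; a < 4; a++) if (a != apex) others[o++] = a;
            emit(edge_pt(apex, others[0]), edge_pt(apex, others[1]), edge_pt(apex, others[2]));
          } else {  // nin == 2: quad split into two triangles
            int ins[2], outs[2], ni = 0, no = 0;
            for (int a = 0; a < 4; a++) (inside[a] ? ins[ni++] : outs[no++]) = a;
            int q0 = edge_pt(ins[0], outs[0]);
            int q1 = edge_pt(ins[0], outs[1]);
            int q2 = edge_pt(ins[1], outs[1]);
            int q3 = edge_pt(ins[1], outs[0]);
            emit(q0, q1, q2);
            emit(q0, q2, q3);
          }
        }
      }

  int nv = st.vx.size(), nf = st.tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; v++) { V(v, 0) = st.vx[v]; V(v, 1) = st.vy[v]; V(v, 2) = st.vz[v]; }
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; f++)
    for (int d = 0; d < 3; d++) F(f, d) = st.tri[3 * f + d] + 1;
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Uniform (umbrella) Laplacian smoothing: each iteration moves every vertex
// toward the mean of its face-connected neighbours by the relaxation factor.
// [[Rcpp::export]]
NumericMatrix smooth_mesh_cpp(NumericMatrix V, IntegerMatrix F, int iters, double relax) {
  int nv = V.nrow(), nf = F.nrow();
  std::vector<double> cur(3 * nv), acc(3 * nv);
  std::vector<int> deg(nv);
  for (int v = 0; v < nv; v++)
    for (int d = 0; d < 3; d++) cur[3 * v + d] = V(v, d);
  for (int it = 0; it < iters; it++) {
    std::fill(acc.begin(), acc.end(), 0.0);
    std::fill(deg.begin(), deg.end(), 0);
    for (int f = 0; f < nf; f++) {
      int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
      const int e[3][2] = { {a, b}, {b, c}, {c, a} };
      for (int s = 0; s < 3; s++) {
        int u = e[s][0], w = e[s][1];
        for (int d = 0; d < 3; d++) {
          acc[3 * u + d] += cur[3 * w + d];
          acc[3 * w + d] += cur[3 * u + d];
        }
        deg[u]++; deg[w]++;
      }
    }
    for (int v = 0; v < nv; v++) {
      if (!deg[v]) continue;
      for (int d = 0; d < 3; d++) {
        double mean = acc[3 * v + d] / deg[v];
        cur[3 * v + d] += relax * (mean - cur[3 * v + d]);
      }
    }
  }
  NumericMatrix out(nv, 3);
  for (int v = 0; v < nv; v++)
    for (int d = 0; d < 3; d++) out(v, d) = cur[3 * v + d];
  return out;
}

// Parity-fill voxelization of a closed mesh: for every (x,y) voxel column a
// vertical ray collects triangle crossings; voxel centres between successive
// crossing pairs are labelled foreground. Ray origins carry a small fixed
// sub-voxel jitter so rays avoid triangle edges/vertices. Returns the label
// vector plus the number of columns with unpaired (odd) crossings.
// [[Rcpp::export]]
List voxelize_cpp(NumericMatrix V, IntegerMatrix F, NumericVector origin,
                  NumericVector spacing, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nf = F.nrow();
  double jx = 3.7e-4 * spacing[0], jy = 6.1e-4 * spacing[1];
  std::vector< std::vector<double> > cross((size_t)nx * ny);

  for (int f = 0; f < nf; f++) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    double x0 = V(a, 0), y0 = V(a, 1), z0 = V(a, 2);
    double x1 = V(b, 0), y1 = V(b, 1), z1 = V(b, 2);
    double x2 = V(c, 0), y2 = V(c, 1), z2 = V(c, 2);
    double xmin = std::min({x0, x1, x2}), xmax = std::max({x0, x1, x2});
    double ymin = std::min({y0, y1, y2}), ymax = std::max({y0, y1, y2});
    int i0 = std::max(0, (int)std::ceil((xmin - origin[0] - jx) / spacing[0]));
    int i1 = std::min(nx - 1, (int)std::floor((xmax - origin[0] - jx) / spacing[0]));
    int j0 = std::max(0, (int)std::ceil((ymin - origin[1] - jy) / spacing[1]));
    int j1 = std::min(ny - 1, (int)std::floor((ymax - origin[1] - jy) / spacing[1]));
    double det = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (std::abs(det) < 1e-300) continue;  // degenerate xy projection
    for (int j = j0; j <= j1; j++) {
      double py = origin[1] + j * spacing[1] + jy;
      for (int i = i0; i <= i1; i++) {
        double px = origin[0] + i * spacing[0] + jx;
        double u = ((px - x0) * (y2 - y0) - (py - y0) * (x2 - x0)) / det;
        double w = ((x1 - x0) * (py - y0) - (y1 - y0) * (px - x0)) / det;
        if (u < 0 || w < 0 || u + w > 1) continue;
        cross[(size_t)j * nx + i].push_back(z0 + u * (z1 - z0) + w * (z2 - z0));
      }
    }
  }

  IntegerVector out((size_t)nx * ny * nz);
  int odd = 0;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      std::vector<double> &zs = cross[(size_t)j * nx + i];
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      if (zs.size() % 2) { odd++; continue; }
      for (size_t s = 0; s + 1 < zs.size(); s += 2) {
        int k0 = std::max(0, (int)std::ceil((zs[s] - origin[2]) / spacing[2]));
        int k1 = std::min(nz - 1, (int)std::floor((zs[s + 1] - origin[2]) / spacing[2]));
        for (int k = k0; k <= k1; k++)
          out[((size_t)k * ny + j) * nx + i] = 1;
      }
    }
  return List::create(_["grid"] = out, _["odd_columns"] = odd);
}
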