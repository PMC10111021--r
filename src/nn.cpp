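#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Uniform-grid spatial hash over a fixed point set. Cells are cubes of side
// h chosen so the average occupancy is ~2 points; queries expand Chebyshev
// rings until the ring lower bound exceeds the best distance found.
struct PointGrid {
  const double *px, *py, *pz;
  int n;
  double lo[3], h;
  int dim[3];
  std::vector< std::vector<int> > cells;

  PointGrid(const NumericMatrix &P) {
    n = P.nrow();
    px = &P(0, 0); py = &P(0, 1); pz = &P(0, 2);
    double hi[3];
    for (int d = 0; d < 3; d++) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
    for (int i = 0; i < n; i++) {
      const double c[3] = { px[i], py[i], pz[i] };
      for (int d = 0; d < 3; d++) {
        if (c[d] < lo[d]) lo[d] = c[d];
        if (c[d] > hi[d]) hi[d] = c[d];
      }
    }
    double vol = 1.0;
    for (int d = 0; d < 3; d++) vol *= std::max(hi[d] - lo[d], 1e-9);
    h = std::cbrt(2.0 * vol / std::max(n, 1));
    if (!(h > 0) || !R_FINITE(h)) h = 1.0;
    size_t ncell = 1;
    for (int d = 0; d < 3; d++) {
      dim[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / h) + 1);
      if (dim[d] > 256) dim[d] = 256;
      ncell *= dim[d];
    }
    h = 0.0;
    for (int d = 0; d < 3; d++)
      h = std::max(h, (hi[d] - lo[d]) / dim[d] + 1e-12);
    cells.resize(ncell);
    for (int i = 0; i < n; i++) cells[cell_of(px[i], py[i], pz[i])].push_back(i);
  }

  inline int clampi(int v, int m) const { return v < 0 ? 0 : (v >= m ? m - 1 : v); }
  inline size_t idx3(int i, int j, int k) const {
    return ((size_t)k * dim[1] + j) * dim[0] + i;
  }
  inline size_t cell_of(double x, double y, double z) const {
    int i = clampi((int)std::floor((x - lo[0]) / h), dim[0]);
    int j = clampi((int)std::floor((y - lo[1]) / h), dim[1]);
    int k = clampi((int)std::floor((z - lo[2]) / h), dim[2]);
    return idx3(i, j, k);
  }

  // nearest point to (x,y,z) among those with keep[i] true (keep may be NULL)
  int nearest(double x, double y, double z, double &best2,
              const std::vector<char> *keep = NULL) const {
    int ci = clampi((int)std::floor((x - lo[0]) / h), dim[0]);
    int cj = clampi((int)std::floor((y - lo[1]) / h), dim[1]);
    int ck = clampi((int)std::floor((z - lo[2]) / h), dim[2]);
    best2 = std::numeric_limits<double>::infinity();
    int best = -1;
    int rmax = dim[0] + dim[1] + dim[2];
    for (int r = 0; r <= rmax; r++) {
      if (best >= 0) {
        double bound = (double)(r - 1) * h;   // min distance to ring r cells
        if (bound > 0 && bound * bound > best2) break;
      }
      bool any = false;
      int i0 = ci - r, i1 = ci + r, j0 = cj - r, j1 = cj + r, k0 = ck - r, k1 = ck + r;
      for (int k = k0; k <= k1; k++) {
        if (k < 0 || k >= dim[2]) continue;
        for (int j = j0; j <= j1; j++) {
          if (j < 0 || j >= dim[1]) continue;
          for (int i = i0; i <= i1; i++) {
            if (i < 0 || i >= dim[0]) continue;
            // only the surface of the ring
            if (r > 0 && std::abs(i - ci) != r && std::abs(j - cj) != r &&
                std::abs(k - ck) != r) continue;
            any = true;
            const std::vector<int> &cl = cells[idx3(i, j, k)];
            for (size_t t = 0; t < cl.size(); t++) {
              int p = cl[t];
              if (keep && !(*keep)[p]) continue;
              double dx = px[p] - x, dy = py[p] - y, dz = pz[p] - z;
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best2) { best2 = d2; best = p; }
            }
          }
        }
      }
      if (!any && best >= 0) break;
    }
    return best;
  }
};

// [[Rcpp::export]]
List nn_cpp(NumericMatrix query, NumericMatrix target) {
  PointGrid g(target);
  int nq = query.nrow();
  IntegerVector idx(nq);
  NumericVector d2(nq);
  for (int i = 0; i < nq; i++) {
    double b2;
    int j = g.nearest(query(i, 0), query(i, 1), query(i, 2), b2);
    idx[i] = j + 1;
    d2[i] = b2;
  }
  return List::create(_["idx"] = idx, _["dist2"] = d2);
}

// Farthest-point sampling: returns 1-based indices of m samples.
// [[Rcpp::export]]
IntegerVector fps_cpp(NumericMatrix P, int m, int start) {
  int n = P.nrow();
  std::vector<double> mind(n, std::numeric_limits<double>::infinity());
  IntegerVector out(m);
  int cur = start - 1;
  for (int s = 0; s < m; s++) {
    out[s] = cur + 1;
    double cx = P(cur, 0), cy = P(cur, 1), cz = P(cur, 2);
    int nxt = -1;
    double best = -1.0;
    for (int i = 0; i < n; i++) {
      double dx = P(i, 0) - cx, dy = P(i, 1) - cy, dz = P(i, 2) - cz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < mind[i]) mind[i] = d2;
      if (mind[i] > best) { best = mind[i]; nxt = i; }
    }
    cur = nxt;
  }
  return out;
}

struct Cand {
  double d2; int i; int j;
  bool operator<(const Cand &o) const { return d2 > o.d2; }  // min-heap
};

// k nearest target indices for one query point: expanding ring scan over
// the grid, collecting candidates until the ring lower bound exceeds the
// current kth-best distance; results sorted ascending by distance
static void knn_of(const PointGrid &g, const NumericMatrix &P, int qi, int k,
                   std::vector<int> &idx, std::vector<double> &d2) {
  double x = P(qi, 0), y = P(qi, 1), z = P(qi, 2);
  int ci = g.clampi((int)std::floor((x - g.lo[0]) / g.h), g.dim[0]);
  int cj = g.clampi((int)std::floor((y - g.lo[1]) / g.h), g.dim[1]);
  int ck = g.clampi((int)std::floor((z - g.lo[2]) / g.h), g.dim[2]);
  std::vector< std::pair<double, int> > found;
  int rmax = g.dim[0] + g.dim[1] + g.dim[2];
  for (int r = 0; r <= rmax; r++) {
    if ((int)found.size() >= k) {
      std::nth_element(found.begin(), found.begin() + (k - 1), found.end());
      double kth = found[k - 1].first;
      double bound = (double)(r - 1) * g.h;
      if (bound > 0 && bound * bound > kth) break;
    }
    bool any = false;
    for (int kk = ck - r; kk <= ck + r; kk++) {
      if (kk < 0 || kk >= g.dim[2]) continue;
      for (int jj = cj - r; jj <= cj + r; jj++) {
        if (jj < 0 || jj >= g.dim[1]) continue;
        for (int ii = ci - r; ii <= ci + r; ii++) {
          if (ii < 0 || ii >= g.dim[0]) continue;
          if (r > 0 && std::abs(ii - ci) != r && std::abs(jj - cj) != r &&
              std::abs(kk - ck) != r) continue;
          any = true;
          const std::vector<int> &cl = g.cells[g.idx3(ii, jj, kk)];
          for (size_t t = 0; t < cl.size(); t++) {
            int p = cl[t];
            double dx = g.px[p] - x, dy = g.py[p] - y, dz = g.pz[p] - z;
            found.push_back(std::make_pair(dx * dx + dy * dy + dz * dz, p));
          }
        }
      }
    }
    if (!any && (int)found.size() >= std::min(k, g.n)) break;
  }
  int kk = std::min((size_t)k, found.size());
  std::partial_sort(found.begin(), found.begin() + kk, found.end());
  idx.resize(kk); d2.resize(kk);
  for (int t = 0; t < kk; t++) { idx[t] = found[t].second; d2[t] = found[t].first; }
}

// Near-optimal one-to-one assignment by forward auction with epsilon
// scaling. Costs are squared distances, optionally augmented with a
// surface-normal mismatch term w^2 * ||n_i - n_j||^2 (which keeps
// epicardial points from matching endocardial ones), restricted to per-row
// candidate lists (k nearest targets by position, expanded on demand).
// Returns perm (0-based).
static std::vector<int> auction_assign(const NumericMatrix &tmpl,
                                       const NumericMatrix &cloud,
                                       const NumericMatrix &tn,
                                       const NumericMatrix &cn,
                                       double w) {
  int n = tmpl.nrow();
  bool use_n = w > 0 && tn.nrow() == n && cn.nrow() == n;
  double w2 = w * w;
  PointGrid gc(cloud);
  int k0 = std::min(16, n);
  std::vector< std::vector<int> > cand(n);
  std::vector< std::vector<double> > cost(n);
  auto pair_cost = [&](int i, int j, double d2) {
    if (!use_n) return d2;
    double dx = tn(i, 0) - cn(j, 0), dy = tn(i, 1) - cn(j, 1), dz = tn(i, 2) - cn(j, 2);
    return d2 + w2 * (dx * dx + dy * dy + dz * dz);
  };
  double cmax = 0;
  {
    std::vector<int> idx; std::vector<double> d2;
    for (int i = 0; i < n; i++) {
      knn_of(gc, tmpl, i, k0, idx, d2);
      cand[i] = idx;
      cost[i].resize(idx.size());
      for (size_t t = 0; t < idx.size(); t++)
        cost[i][t] = pair_cost(i, idx[t], d2[t]);
      if (!cost[i].empty()) cmax = std::max(cmax, cost[i].back());
    }
  }
  if (cmax <= 0) cmax = 1.0;
  std::vector<double> price(n, 0.0);
  std::vector<int> owner(n, -1), assign(n, -1);
  std::vector<int> expand_level(n, 0);

  // epsilon floor set at the sampling-jitter scale: cost differences below
  // ~5% of the typical best-candidate cost only reshuffle ties among
  // equally good matches, while a finer floor triggers price wars
  double cmed = 0;
  {
    std::vector<double> best(n);
    for (int i = 0; i < n; i++)
      best[i] = cost[i].empty() ? 0.0 : *std::min_element(cost[i].begin(), cost[i].end());
    std::nth_element(best.begin(), best.begin() + n / 2, best.end());
    cmed = best[n / 2];
  }
  double eps = cmax / 4.0;
  const double eps_min = cmax * 1e-6 + cmed * 0.05 + 1e-12;
  // bid budget per scaling round: a degenerate near-tie price war is cut
  // short and the handful of still-free rows is completed greedily
  const long bid_budget = 150L * n;
  for (;;) {
    std::fill(owner.begin(), owner.end(), -1);
    std::fill(assign.begin(), assign.end(), -1);
    long bids = 0;
    std::vector<int> free_rows(n);
    for (int i = 0; i < n; i++) free_rows[i] = i;
    while (!free_rows.empty()) {
      if (++bids > bid_budget) break;
      int i = free_rows.back(); free_rows.pop_back();
      // best and second-best value among candidates
      int bj = -1; double bv = -1e300, sv = -1e300;
      for (size_t t = 0; t < cand[i].size(); t++) {
        double v = -cost[i][t] - price[cand[i][t]];
        if (v > bv) { sv = bv; bv = v; bj = cand[i][t]; }
        else if (v > sv) sv = v;
      }
      if ((bj < 0 || (cand[i].size() < (size_t)n &&
                      bv < -cmax * 4 * (expand_level[i] + 1))) &&
          expand_level[i] < 3) {
        // candidate list too tight for the current prices: widen and retry
        expand_level[i]++;
        int nk = std::min((int)(k0 << (2 * expand_level[i])), n);
        std::vector<int> idx; std::vector<double> d2;
        knn_of(gc, tmpl, i, nk, idx, d2);
        cand[i] = idx;
        cost[i].resize(idx.size());
        for (size_t t = 0; t < idx.size(); t++)
          cost[i][t] = pair_cost(i, idx[t], d2[t]);
        free_rows.push_back(i);
        continue;
      }
      if (bj < 0) continue;  // exhausted list; row completed greedily later
      if (sv <= -1e299) sv = bv - cmax;  // single candidate
      double bid = price[bj] + (bv - sv) + eps;
      price[bj] = bid;
      if (owner[bj] >= 0) { assign[owner[bj]] = -1; free_rows.push_back(owner[bj]); }
      owner[bj] = i;
      assign[i] = bj;
    }
    if (eps <= eps_min) break;
    eps /= 5.0;
  }
  return assign;
}

// One-to-one assignment of cloud points to template rows.
// method 0: mutual nearest neighbours locked first, remaining rows matched
//           by global lazy-greedy ascending distance;
// method 1: pure global greedy over all rows (no mutual-NN pre-lock);
// method 2: near-optimal linear assignment (auction, squared distances).
// Returns perm, 1-based: perm[i] = cloud row assigned to template row i.
// [[Rcpp::export]]
IntegerVector match_points_cpp(NumericMatrix tmpl, NumericMatrix cloud, int method,
                               NumericMatrix tmpl_normals,
                               NumericMatrix cloud_normals,
                               double normal_weight) {
  int n = tmpl.nrow();
  if (cloud.nrow() != n) stop("point counts differ");
  IntegerVector perm(n, NA_INTEGER);
  std::vector<char> tfree(n, 1), cfree(n, 1);
  if (method == 2) {
    std::vector<int> a = auction_assign(tmpl, cloud, tmpl_normals,
                                        cloud_normals, normal_weight);
    for (int i = 0; i < n; i++)
      if (a[i] >= 0) { perm[i] = a[i] + 1; tfree[i] = 0; cfree[a[i]] = 0; }
    // any rows left unassigned by a truncated auction fall through to the
    // lazy-greedy completion below
  }
  PointGrid gc(cloud), gt(tmpl);

  if (method == 0) {
    double b2;
    std::vector<int> t2c(n), c2t(n);
    for (int i = 0; i < n; i++)
      t2c[i] = gc.nearest(tmpl(i, 0), tmpl(i, 1), tmpl(i, 2), b2);
    for (int j = 0; j < n; j++)
      c2t[j] = gt.nearest(cloud(j, 0), cloud(j, 1), cloud(j, 2), b2);
    for (int i = 0; i < n; i++) {
      int j = t2c[i];
      if (c2t[j] == i && cfree[j]) { perm[i] = j + 1; tfree[i] = 0; cfree[j] = 0; }
    }
  }

  // lazy-greedy on the remaining rows
  std::priority_queue<Cand> pq;
  for (int i = 0; i < n; i++) {
    if (!tfree[i]) continue;
    double b2;
    int j = gc.nearest(tmpl(i, 0), tmpl(i, 1), tmpl(i, 2), b2, &cfree);
    if (j >= 0) pq.push(Cand{b2, i, j});
  }
  while (!pq.empty()) {
    Cand c = pq.top(); pq.pop();
    if (!tfree[c.i]) continue;
    if (cfree[c.j]) {
      perm[c.i] = c.j + 1; tfree[c.i] = 0; cfree[c.j] = 0;
    } else {
      double b2;
      int j = gc.nearest(tmpl(c.i, 0), tmpl(c.i, 1), tmpl(c.i, 2), b2, &cfree);
      if (j >= 0) pq.push(Cand{b2, c.i, j});
    }
  }
  return perm;
}
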