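// Uniform-grid spatial queries for point clouds: k-nearest-neighbour
// statistics/indices and eps-radius connected components.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct PointGrid {
  double x0[3];
  double cell;
  int n[3];
  std::vector<int> start;   // CSR offsets, length ncell+1
  std::vector<int> idx;     // point ids ordered by cell
  const NumericMatrix &P;

  explicit PointGrid(const NumericMatrix &pts, double cell_size) : P(pts) {
    const int np = pts.nrow();
    double hi[3];
    for (int d = 0; d < 3; ++d) { x0[d] = R_PosInf; hi[d] = R_NegInf; }
    for (int i = 0; i < np; ++i)
      for (int d = 0; d < 3; ++d) {
        x0[d] = std::min(x0[d], pts(i, d));
        hi[d] = std::max(hi[d], pts(i, d));
      }
    cell = cell_size;
    long ncell = 1;
    for (int d = 0; d < 3; ++d) {
      n[d] = std::max(1, std::min(512, (int)std::floor((hi[d] - x0[d]) / cell) + 1));
      ncell *= n[d];
    }
    start.assign(ncell + 1, 0);
    std::vector<int> ci(np);
    for (int i = 0; i < np; ++i) { ci[i] = cell_of(pts(i,0), pts(i,1), pts(i,2)); start[ci[i] + 1]++; }
    for (long c = 0; c < ncell; ++c) start[c + 1] += start[c];
    idx.resize(np);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int i = 0; i < np; ++i) idx[fill[ci[i]]++] = i;
  }

  int coord(double v, int d) const {
    int c = (int)std::floor((v - x0[d]) / cell);
    return std::max(0, std::min(n[d] - 1, c));
  }
  int cell_of(double x, double y, double z) const {
    return (coord(z,2) * n[1] + coord(y,1)) * n[0] + coord(x,0);
  }
  template <class F> void visit_cell(int cx, int cy, int cz, F f) const {
    if (cx < 0 || cy < 0 || cz < 0 || cx >= n[0] || cy >= n[1] || cz >= n[2]) return;
    long c = ((long)cz * n[1] + cy) * n[0] + cx;
    for (int k = start[c]; k < start[c + 1]; ++k) f(idx[k]);
  }
};

inline double sqdist(const NumericMatrix &P, int i, int j) {
  double s = 0;
  for (int d = 0; d < 3; ++d) { double v = P(i,d) - P(j,d); s += v * v; }
  return s;
}

double heuristic_cell(const NumericMatrix &P, int k) {
  // aim for ~k points per cell so ring searches terminate quickly
  const int np = P.nrow();
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < np; ++i)
    for (int d = 0; d < 3; ++d) { lo[d] = std::min(lo[d], P(i,d)); hi[d] = std::max(hi[d], P(i,d)); }
  double ext = 0;
  for (int d = 0; d < 3; ++d) ext = std::max(ext, hi[d] - lo[d]);
  if (ext <= 0) ext = 1.0;
  double h = ext / std::max(1.0, std::cbrt((double)np / std::max(1, k)));
  return std::max(h, ext * 1e-6);
}

// k nearest neighbours of point i (excluding i); returns squared distances
// (heap) and optionally ids
void knn_point(const PointGrid &g, const NumericMatrix &P, int i, int k,
               std::priority_queue<std::pair<double,int> > &heap) {
  const int cx = g.coord(P(i,0),0), cy = g.coord(P(i,1),1), cz = g.coord(P(i,2),2);
  int max_ring = std::max(std::max(g.n[0], g.n[1]), g.n[2]);
  for (int ring = 0; ring <= max_ring; ++ring) {
    if ((int)heap.size() >= k) {
      double worst = std::sqrt(heap.top().first);
      // all points in rings beyond this one are at least (ring-1)*cell away
      if ((ring - 1) * g.cell > worst) break;
    }
    for (int dz = -ring; dz <= ring; ++dz)
      for (int dy = -ring; dy <= ring; ++dy)
        for (int dx = -ring; dx <= ring; ++dx) {
          if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != ring) continue;
          g.visit_cell(cx + dx, cy + dy, cz + dz, [&](int j) {
            if (j == i) return;
            double d2 = sqdist(P, i, j);
            if ((int)heap.size() < k) heap.push(std::make_pair(d2, j));
            else if (d2 < heap.top().first) { heap.pop(); heap.push(std::make_pair(d2, j)); }
          });
        }
  }
}

struct DSU {
  std::vector<int> p;
  explicit DSU(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[a] = b; }
};

} // namespace

// [[Rcpp::export(name = ".cpp_knn_mean_dist")]]
NumericVector cpp_knn_mean_dist(NumericMatrix P, int k) {
  const int np = P.nrow();
  if (k >= np) stop("too few points");
  PointGrid g(P, heuristic_cell(P, k));
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    std::priority_queue<std::pair<double,int> > heap;
    knn_point(g, P, i, k, heap);
    double s = 0; int m = heap.size();
    while (!heap.empty()) { s += std::sqrt(heap.top().first); heap.pop(); }
    out[i] = s / m;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_knn_indices")]]
IntegerMatrix cpp_knn_indices(NumericMatrix P, int k) {
  const int np = P.nrow();
  if (k >= np) stop("too few points");
  PointGrid g(P, heuristic_cell(P, k));
  IntegerMatrix out(np, k);
  for (int i = 0; i < np; ++i) {
    std::priority_queue<std::pair<double,int> > heap;
    knn_point(g, P, i, k, heap);
    int m = heap.size();
    for (int c = m - 1; c >= 0; --c) { out(i, c) = heap.top().second + 1; heap.pop(); }
    for (int c = m; c < k; ++c) out(i, c) = NA_INTEGER;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_radius_components")]]
IntegerVector cpp_radius_components(NumericMatrix P, double eps) {
  const int np = P.nrow();
  if (np == 0) return IntegerVector(0);
  PointGrid g(P, std::max(eps, 1e-9));
  DSU dsu(np);
  const double e2 = eps * eps;
  for (int i = 0; i < np; ++i) {
    const int cx = g.coord(P(i,0),0), cy = g.coord(P(i,1),1), cz = g.coord(P(i,2),2);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          g.visit_cell(cx + dx, cy + dy, cz + dz, [&](int j) {
            if (j > i && sqdist(P, i, j) <= e2) dsu.unite(i, j);
          });
  }
  IntegerVector comp(np);
  std::vector<int> relabel(np, 0);
  int next = 0;
  for (int i = 0; i < np; ++i) {
    int r = dsu.find(i);
    if (!relabel[r]) relabel[r] = ++next;
    comp[i] = relabel[r];
  }
  return comp;
}
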