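#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// 8-connected component labeling of a binary mask.
// Labels are assigned in row-major scan order of each component's first pixel,
// so the labeling is deterministic.
// [[Rcpp::export(name = ".cc_label8")]]
IntegerMatrix cc_label8(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) != 0 && lab(r, c) == 0) {
        ++next;
        stack.clear();
        stack.push_back(r + c * nr);
        lab(r, c) = next;
        while (!stack.empty()) {
          int idx = stack.back(); stack.pop_back();
          int rr = idx % nr, cc = idx / nr;
          for (int k = 0; k < 8; ++k) {
            int r2 = rr + DR8[k], c2 = cc + DC8[k];
            if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc &&
                mask(r2, c2) != 0 && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

struct QNode {
  double dist;
  int label;
  int idx;
};
struct QNodeCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.dist != b.dist) return a.dist > b.dist;
    if (a.label != b.label) return a.label > b.label;
    return a.idx > b.idx;
  }
};

// Multi-source geodesic (within-foreground) Dijkstra assignment.
// seeds: integer matrix with seed labels (> 0) at seed pixels, 0 elsewhere.
// fg: binary foreground mask; seed pixels are treated as foreground.
// Steps to 4-neighbours cost 1, diagonal steps cost sqrt(2).
// Ties in geodesic distance are broken toward the smaller seed label.
// [[Rcpp::export(name = ".geodesic_assign")]]
IntegerMatrix geodesic_assign(const IntegerMatrix& seeds, const IntegerMatrix& fg) {
  const int nr = seeds.nrow(), nc = seeds.ncol();
  const double SQ2 = std::sqrt(2.0);
  std::vector<double> dist((size_t)nr * nc, R_PosInf);
  std::vector<int> lab((size_t)nr * nc, 0);
  std::vector<char> done((size_t)nr * nc, 0);
  std::priority_queue<QNode, std::vector<QNode>, QNodeCmp> pq;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0) {
        int idx = r + c * nr;
        dist[idx] = 0.0;
        lab[idx] = seeds(r, c);
        pq.push(QNode{0.0, seeds(r, c), idx});
      }
  while (!pq.empty()) {
    QNode nd = pq.top(); pq.pop();
    if (done[nd.idx]) continue;
    done[nd.idx] = 1;
    lab[nd.idx] = nd.label;
    int rr = nd.idx % nr, cc = nd.idx / nr;
    for (int k = 0; k < 8; ++k) {
      int r2 = rr + DR8[k], c2 = cc + DC8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int idx2 = r2 + c2 * nr;
      if (done[idx2]) continue;
      if (fg(r2, c2) == 0 && seeds(r2, c2) == 0) continue;
      double w = (DR8[k] != 0 && DC8[k] != 0) ? SQ2 : 1.0;
      double d2 = nd.dist + w;
      if (d2 < dist[idx2] || (d2 == dist[idx2] && nd.label < lab[idx2])) {
        dist[idx2] = d2;
        lab[idx2] = nd.label;
        pq.push(QNode{d2, nd.label, idx2});
      }
    }
  }
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = done[r + c * nr] ? lab[r + c * nr] : 0;
  return out;
}

// Outer-boundary walk length of a single connected object, diagonal steps
// weighted sqrt(2) (Moore-neighbour contour tracing with Jacob's stopping
// criterion). Objects whose contour has fewer than 3 pixels fall back to the
// exposed pixel-edge (crack) length. Returns length in pixel units.
// [[Rcpp::export(name = ".boundary_walk_length")]]
double boundary_walk_length(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  // start pixel: smallest column, then smallest row (row-major within column scan)
  int sr = -1, sc = -1;
  for (int c = 0; c < nc && sr < 0; ++c)
    for (int r = 0; r < nr; ++r)
      if (mask(r, c) != 0) { sr = r; sc = c; break; }
  if (sr < 0) return 0.0;

  // clockwise Moore neighbourhood starting from W when image rows grow down
  static const int MR[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  static const int MC[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const double SQ2 = std::sqrt(2.0);

  auto inside = [&](int r, int c) {
    return r >= 0 && r < nr && c >= 0 && c < nc && mask(r, c) != 0;
  };

  // crack length fallback for degenerate objects
  auto crack = [&]() {
    double tot = 0.0;
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r)
        if (mask(r, c) != 0) {
          if (!inside(r - 1, c)) tot += 1.0;
          if (!inside(r + 1, c)) tot += 1.0;
          if (!inside(r, c - 1)) tot += 1.0;
          if (!inside(r, c + 1)) tot += 1.0;
        }
    return tot;
  };

  // Walk states are (pixel, scan-start direction); the walk is a deterministic
  // map on states, so the outer contour is recovered by stopping at the first
  // repeated state. The scan starts at W of the minimum pixel, which is
  // guaranteed background, so the initial state lies on the contour cycle.
  // at_len[state] = accumulated length when the state was first reached;
  // the contour length is the length of the state cycle.
  std::vector<double> at_len((size_t)nr * nc * 8, -1.0);
  int cr = sr, cc = sc;
  int dir = 0;
  at_len[((size_t)(cr + cc * nr)) * 8 + dir] = 0.0;
  double len = 0.0;
  int steps = 0;
  const int maxsteps = 8 * nr * nc + 8;
  double cyc = -1.0;
  while (steps < maxsteps) {
    int found = -1;
    for (int k = 0; k < 8; ++k) {
      int d = (dir + k) % 8;
      if (inside(cr + MR[d], cc + MC[d])) { found = d; break; }
    }
    if (found < 0) return crack();  // isolated pixel
    len += (MR[found] != 0 && MC[found] != 0) ? SQ2 : 1.0;
    cr += MR[found]; cc += MC[found];
    // next scan starts just past the backtrack direction, clockwise
    dir = (found + 5) % 8;
    ++steps;
    size_t st = ((size_t)(cr + cc * nr)) * 8 + dir;
    if (at_len[st] >= 0.0) { cyc = len - at_len[st]; break; }
    at_len[st] = len;
  }
  if (steps < 3) return crack();
  return cyc >= 0.0 ? cyc : len;
}
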