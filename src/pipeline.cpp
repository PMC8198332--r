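#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 8-neighbour offsets (row, col)
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Connected-component labelling of a binary image with 8-connectivity.
// Labels are assigned in column-major scan order (R's native order), so the
// result is deterministic for a given mask.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int ni = ci + DR[k], nj = cj + DC[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}

static inline int nb(const LogicalMatrix& m, int i, int j) {
  if (i < 0 || i >= m.nrow() || j < 0 || j >= m.ncol()) return 0;
  return m(i, j) ? 1 : 0;
}

// Zhang-Suen thinning. Runs to convergence, so the output is a fixed point:
// thinning a skeleton returns it unchanged.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img = clone(mask);
  std::vector<int> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img(i, j)) continue;
          // neighbours clockwise from north: p2..p9
          int p2 = nb(img, i - 1, j),     p3 = nb(img, i - 1, j + 1);
          int p4 = nb(img, i, j + 1),     p5 = nb(img, i + 1, j + 1);
          int p6 = nb(img, i + 1, j),     p7 = nb(img, i + 1, j - 1);
          int p8 = nb(img, i, j - 1),     p9 = nb(img, i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(i + j * nr);
        }
      }
      for (size_t k = 0; k < kill.size(); ++k)
        img[kill[k]] = FALSE;
      if (!kill.empty()) changed = true;
    }
  }
  return img;
}

struct PqEntry {
  double dist;
  int label;
  int idx;
};
struct PqCompare {
  bool operator()(const PqEntry& a, const PqEntry& b) const {
    if (a.dist != b.dist) return a.dist > b.dist;
    return a.label > b.label; // lower label wins ties
  }
};

// Seeded region growing bounded by barriers and a geodesic expansion cap.
// Seeds keep their labels; growth proceeds through `allowed` pixels only,
// accumulating chamfer distance (1 orthogonal, sqrt(2) diagonal) from the
// seed boundary, and stops at barriers, the image edge, or `max_dist`.
// A diagonal step is blocked when both orthogonal intermediate pixels are
// barriers, so growth cannot slip through a diagonally connected barrier
// curve. Contested pixels go to the nearer seed, then to the lower label.
// Afterwards, `absorbable` barrier pixels adjacent to a claimed region are
// absorbed into the nearest region for `absorb` passes (thin boundary walls
// such as a basal lamina skeleton belong to the follicle they delimit).
// [[Rcpp::export]]
IntegerMatrix cpp_propagate(const IntegerMatrix& seeds,
                            const LogicalMatrix& allowed,
                            const LogicalMatrix& absorbable,
                            double max_dist,
                            int absorb = 2) {
  const int nr = seeds.nrow(), nc = seeds.ncol();
  const double SQRT2 = std::sqrt(2.0);
  IntegerMatrix out = clone(seeds);
  std::vector<double> dist((size_t)nr * nc, R_PosInf);
  std::vector<char> done((size_t)nr * nc, 0);
  std::priority_queue<PqEntry, std::vector<PqEntry>, PqCompare> pq;

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (seeds(i, j) > 0) {
        size_t idx = (size_t)i + (size_t)j * nr;
        dist[idx] = 0.0;
        pq.push(PqEntry{0.0, seeds(i, j), (int)idx});
      }

  while (!pq.empty()) {
    PqEntry e = pq.top(); pq.pop();
    if (done[e.idx]) continue;
    done[e.idx] = 1;
    out[e.idx] = e.label;
    int ci = e.idx % nr, cj = e.idx / nr;
    for (int k = 0; k < 8; ++k) {
      int ni = ci + DR[k], nj = cj + DC[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      size_t nidx = (size_t)ni + (size_t)nj * nr;
      if (done[nidx] || seeds(ni, nj) > 0) continue;
      if (!allowed(ni, nj)) continue;
      bool diag = (DR[k] != 0 && DC[k] != 0);
      if (diag) {
        bool pass1 = allowed(ci + DR[k], cj) || seeds(ci + DR[k], cj) > 0;
        bool pass2 = allowed(ci, cj + DC[k]) || seeds(ci, cj + DC[k]) > 0;
        if (!pass1 && !pass2) continue;
      }
      double w = diag ? SQRT2 : 1.0;
      double nd = e.dist + w;
      if (nd > max_dist + 1e-9) continue;
      if (nd < dist[nidx] + 1e-9) {
        dist[nidx] = std::min(dist[nidx], nd);
        pq.push(PqEntry{nd, e.label, (int)nidx});
      }
    }
  }

  // absorb thin barrier walls adjacent to claimed regions
  for (int pass = 0; pass < absorb; ++pass) {
    std::vector<std::pair<size_t, int> > grab;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        size_t idx = (size_t)i + (size_t)j * nr;
        if (out[idx] != 0 || allowed(i, j) || !absorbable(i, j)) continue;
        double best = R_PosInf;
        int bestlab = 0;
        for (int k = 0; k < 8; ++k) {
          int ni = i + DR[k], nj = j + DC[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          size_t nidx = (size_t)ni + (size_t)nj * nr;
          if (out[nidx] == 0) continue;
          double d = dist[nidx];
          bool take = bestlab == 0 || d < best - 1e-9 ||
                      (d < best + 1e-9 && out[nidx] < bestlab);
          if (take) { best = d; bestlab = out[nidx]; }
        }
        if (bestlab > 0) grab.push_back(std::make_pair(idx, bestlab));
      }
    }
    if (grab.empty()) break;
    for (size_t k = 0; k < grab.size(); ++k) {
      out[grab[k].first] = grab[k].second;
      dist[grab[k].first] = 0.0; // treat absorbed wall as part of the region
    }
  }
  return out;
}
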