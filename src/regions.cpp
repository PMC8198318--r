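#include <Rcpp.h>
#include <queue>
#include <climits>
using namespace Rcpp;

// Connected-component labelling of a binary mask by breadth-first search.
// Labels are assigned in order of the first pixel encountered scanning rows
// within columns is NOT used: the scan runs row-major (row 1 col 1, row 1
// col 2, ...) so labelling is reproducible across platforms.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 0, 0, 1};
  static const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<int> q;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push(r + c * nr);
      while (!q.empty()) {
        const int p = q.front(); q.pop();
        const int pr = p % nr, pc = p / nr;
        for (int k = 0; k < nd; ++k) {
          const int r2 = pr + dr[k], c2 = pc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            q.push(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Seeded flood-fill partition of a foreground mask: each foreground pixel is
// assigned to the seed with the smallest geodesic (within-mask) distance,
// measured in 8-neighbour hops of unit cost. Equidistant pixels go to the
// seed with the lowest index (seeds are passed already ordered by id).
// Pixels unreachable from every seed keep label 0. Seed coordinates are
// 0-based and must lie on the mask (the R wrapper snaps/validates).
// [[Rcpp::export(name = ".flood_fill_label")]]
IntegerMatrix flood_fill_label(LogicalMatrix mask, IntegerVector seed_row,
                               IntegerVector seed_col) {
  const int nr = mask.nrow(), nc = mask.ncol(), ns = seed_row.size();
  IntegerMatrix lab(nr, nc);
  std::vector<int> best(nr * nc, INT_MAX), dist(nr * nc);
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int s = 0; s < ns; ++s) {
    std::fill(dist.begin(), dist.end(), INT_MAX);
    std::queue<int> q;
    const int p0 = seed_row[s] + seed_col[s] * nr;
    dist[p0] = 0;
    q.push(p0);
    while (!q.empty()) {
      const int p = q.front(); q.pop();
      const int pr = p % nr, pc = p / nr, d = dist[p];
      for (int k = 0; k < 8; ++k) {
        const int r2 = pr + dr8[k], c2 = pc + dc8[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (!mask(r2, c2)) continue;
        const int p2 = r2 + c2 * nr;
        if (dist[p2] > d + 1) {
          dist[p2] = d + 1;
          q.push(p2);
        }
      }
    }
    // strict '<' keeps the earlier (lower id) seed on ties
    for (int p = 0; p < nr * nc; ++p) {
      if (dist[p] < best[p]) {
        best[p] = dist[p];
        lab[p] = s + 1;
      }
    }
  }
  return lab;
}
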