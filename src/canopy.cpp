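#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Variable-window local-maximum candidates.
// A cell is a candidate iff its height is >= min_height and no cell inside
// the square window of half-width hw(i,j) cells is strictly higher.  Equal
// -height plateaus are resolved on the R side.
// [[Rcpp::export]]
LogicalMatrix local_max_candidates(NumericMatrix h, IntegerMatrix hw,
                                   double min_height) {
  int nr = h.nrow(), nc = h.ncol();
  LogicalMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double v = h(i, j);
      if (NumericMatrix::is_na(v) || v < min_height) {
        out(i, j) = false;
        continue;
      }
      int w = hw(i, j);
      bool ok = true;
      int alo = std::max(0, i - w), ahi = std::min(nr - 1, i + w);
      int blo = std::max(0, j - w), bhi = std::min(nc - 1, j + w);
      for (int a = alo; ok && a <= ahi; ++a) {
        for (int b = blo; b <= bhi; ++b) {
          double u = h(a, b);
          if (!NumericMatrix::is_na(u) && u > v) {
            ok = false;
            break;
          }
        }
      }
      out(i, j) = ok;
    }
  }
  return out;
}

struct FloodNode {
  double h;
  long order;
  int idx;
};

struct FloodCompare {
  // priority queue pops the highest cell; FIFO on exact ties
  bool operator()(const FloodNode &a, const FloodNode &b) const {
    if (a.h != b.h) return a.h < b.h;
    return a.order > b.order;
  }
};

// Marker-controlled watershed by priority flooding (Meyer's algorithm) on
// the height surface, 4-neighbor connectivity.  seeds holds marker labels
// (> 0) at marker cells and 0 elsewhere; cells below min_height stay 0.
// [[Rcpp::export]]
IntegerMatrix watershed_flood(NumericMatrix h, IntegerMatrix seeds,
                              double min_height) {
  int nr = h.nrow(), nc = h.ncol(), n = nr * nc;
  IntegerMatrix labels(nr, nc);
  std::priority_queue<FloodNode, std::vector<FloodNode>, FloodCompare> pq;
  long order = 0;
  for (int k = 0; k < n; ++k) {
    if (seeds[k] > 0) {
      labels[k] = seeds[k];
      pq.push({h[k], order++, k});
    }
  }
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    FloodNode cur = pq.top();
    pq.pop();
    int i = cur.idx % nr, j = cur.idx / nr;
    for (int d = 0; d < 4; ++d) {
      int a = i + di[d], b = j + dj[d];
      if (a < 0 || a >= nr || b < 0 || b >= nc) continue;
      int k = a + b * nr;
      if (labels[k] != 0) continue;
      double u = h[k];
      if (NumericMatrix::is_na(u) || u < min_height) continue;
      labels[k] = labels[cur.idx];
      pq.push({u, order++, k});
    }
  }
  return labels;
}
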