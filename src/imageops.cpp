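#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 8-neighbour offsets
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r0 + c0 * nr);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int r = idx % nr, c = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int rr = r + DR[k], cc = c + DC[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Local maxima over a (2h+1)x(2h+1) window. Plateaus are broken by keeping
// only the lexicographically smallest (row, col) pixel of each plateau that
// is maximal in its window.
// [[Rcpp::export]]
LogicalMatrix cpp_local_maxima(NumericMatrix x, int h) {
  int nr = x.nrow(), nc = x.ncol();
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = x(r, c);
      bool ismax = true;
      for (int cc = std::max(0, c - h); cc <= std::min(nc - 1, c + h) && ismax; ++cc) {
        for (int rr = std::max(0, r - h); rr <= std::min(nr - 1, r + h); ++rr) {
          if (rr == r && cc == c) continue;
          double w = x(rr, cc);
          if (w > v) { ismax = false; break; }
          // plateau tie-break: earlier pixel in column-major (col, then row) wins
          if (w == v && (cc < c || (cc == c && rr < r))) { ismax = false; break; }
        }
      }
      out(r, c) = ismax;
    }
  }
  return out;
}

struct QNode {
  double prio;
  long order;
  int idx;
};
struct QCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;  // lowest relief first
    return a.order > b.order;                      // FIFO among ties
  }
};

// Seeded (marker-controlled) watershed by priority flood.
// relief:  the landscape (basins grow uphill from markers);
// markers: 0 = unlabeled, >0 seed labels, -1 = background marker;
// mask:    flooding is confined to mask == TRUE; pixels outside keep label 0
//          unless they carry a background marker (which still floods inward).
// Returns integer labels; background basin pixels are 0 in the output.
// [[Rcpp::export]]
IntegerMatrix cpp_marker_watershed(NumericMatrix relief, IntegerMatrix markers,
                                   LogicalMatrix mask) {
  int nr = relief.nrow(), nc = relief.ncol();
  if (markers.nrow() != nr || markers.ncol() != nc || mask.nrow() != nr ||
      mask.ncol() != nc)
    stop("relief, markers and mask must share one shape");
  IntegerMatrix lab(nr, nc);
  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  long order = 0;
  const int BG = -1;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (markers(r, c) != 0) {
        lab(r, c) = markers(r, c);
        pq.push({relief(r, c), order++, r + c * nr});
      }
  while (!pq.empty()) {
    QNode nd = pq.top();
    pq.pop();
    int r = nd.idx % nr, c = nd.idx / nr;
    int l = lab(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (lab(rr, cc) != 0) continue;
      if (!mask(rr, cc)) continue;
      lab(rr, cc) = l;
      pq.push({relief(rr, cc), order++, rr + cc * nr});
    }
  }
  // background basin reported as 0
  for (int i = 0; i < nr * nc; ++i)
    if (lab[i] == BG) lab[i] = 0;
  return lab;
}
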