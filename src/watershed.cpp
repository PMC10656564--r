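#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Priority-flood marker-controlled watershed on a canopy height model.
// Flooding runs downhill from the marker cells (i.e. watershed of the
// inverted surface with minima imposed at the markers). Cells below the
// height threshold are background (label 0). Ties in height are broken by
// insertion order, which favors earlier (lower-id) markers, giving a
// deterministic equidistant split between equal touching crowns.
//
// chm: numeric matrix (row-major from R as column-major; we use linear idx)
// marker_idx: 1-based linear indices of marker cells
// mask: logical matrix, true where the cell belongs to canopy
// [[Rcpp::export(name = ".watershed_flood")]]
IntegerMatrix watershed_flood(NumericMatrix chm, IntegerVector marker_idx,
                              LogicalMatrix mask) {
  int nr = chm.nrow(), nc = chm.ncol();
  IntegerMatrix lab(nr, nc);

  struct Node {
    double h;
    long order;
    int idx;
    int label;
  };
  struct Cmp {
    bool operator()(const Node& a, const Node& b) const {
      if (a.h != b.h) return a.h < b.h;     // max-heap on height
      return a.order > b.order;             // FIFO on ties
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;
  long order = 0;

  for (int k = 0; k < marker_idx.size(); ++k) {
    int idx = marker_idx[k] - 1;
    if (idx < 0 || idx >= nr * nc) stop("marker index out of range");
    if (!mask[idx]) continue;  // caller warns about dropped markers
    if (lab[idx] != 0) continue;
    lab[idx] = k + 1;
    pq.push({chm[idx], order++, idx, k + 1});
  }

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    int r = nd.idx % nr, c = nd.idx / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = cc * nr + rr;
      if (!mask[j] || lab[j] != 0) continue;
      lab[j] = nd.label;
      pq.push({chm[j], order++, j, nd.label});
    }
  }
  return lab;
}
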