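#include <Rcpp.h>
#include <queue>
#include <vector>
#include <tuple>

using namespace Rcpp;

// Neighbour offsets. Order is fixed so that all algorithms are deterministic.
static const int DR8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DC8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DR4[4] = {-1, 1, 0, 0};
static const int DC4[4] = {0, 0, -1, 1};

// Connected-component labelling of a binary mask.
// Labels are assigned 1..n in row-major raster-scan discovery order
// (origin top-left), independently of the column-major storage of R matrices.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int nn = (connectivity == 8) ? 8 : 4;
  const int *dr = (connectivity == 8) ? DR8 : DR4;
  const int *dc = (connectivity == 8) ? DC8 : DC4;
  std::vector<int> stack;
  int cur = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) && lab(r, c) == 0) {
        ++cur;
        lab(r, c) = cur;
        stack.clear();
        stack.push_back(r + c * nr);
        while (!stack.empty()) {
          const int p = stack.back();
          stack.pop_back();
          const int pr = p % nr, pc = p / nr;
          for (int k = 0; k < nn; ++k) {
            const int qr = pr + dr[k], qc = pc + dc[k];
            if (qr >= 0 && qr < nr && qc >= 0 && qc < nc &&
                mask(qr, qc) && lab(qr, qc) == 0) {
              lab(qr, qc) = cur;
              stack.push_back(qr + qc * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

struct WsNode {
  double priority;   // pixel intensity: larger floods first
  long long order;   // FIFO tie-break for equal priorities (deterministic)
  int pixel;         // column-major linear index
};

struct WsCompare {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.priority != b.priority) return a.priority < b.priority; // max-heap
    return a.order > b.order;                                     // FIFO ties
  }
};

// Marker-controlled watershed: grows the seed regions over `mask`,
// admitting pixels in order of decreasing `priority` (to flood basins of an
// inverted image, pass the image itself as priority). A popped pixel is
// assigned to the lowest-numbered labelled neighbour, so label ties are
// resolved reproducibly. Masked pixels unreachable from any seed stay 0.
// [[Rcpp::export]]
IntegerMatrix cpp_marker_watershed(NumericMatrix priority, IntegerMatrix seeds,
                                   LogicalMatrix mask, int connectivity) {
  const int nr = priority.nrow(), nc = priority.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc ||
      mask.nrow() != nr || mask.ncol() != nc)
    stop("priority, seeds and mask must share dimensions");
  IntegerMatrix lab(nr, nc);
  std::vector<char> queued((size_t)nr * nc, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCompare> pq;
  const int nn = (connectivity == 8) ? 8 : 4;
  const int *dr = (connectivity == 8) ? DR8 : DR4;
  const int *dc = (connectivity == 8) ? DC8 : DC4;
  long long order = 0;

  // Seeds keep their own labels; enqueue their unlabelled masked neighbours.
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0) lab(r, c) = seeds(r, c);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) > 0) {
        for (int k = 0; k < nn; ++k) {
          const int qr = r + dr[k], qc = c + dc[k];
          if (qr >= 0 && qr < nr && qc >= 0 && qc < nc &&
              mask(qr, qc) && lab(qr, qc) == 0) {
            const size_t q = (size_t)qr + (size_t)qc * nr;
            if (!queued[q]) {
              queued[q] = 1;
              pq.push(WsNode{priority(qr, qc), order++, (int)q});
            }
          }
        }
      }
    }
  }

  while (!pq.empty()) {
    const WsNode nd = pq.top();
    pq.pop();
    const int pr = nd.pixel % nr, pc = nd.pixel / nr;
    if (lab(pr, pc) != 0) continue;
    int best = 0;
    for (int k = 0; k < nn; ++k) {
      const int qr = pr + dr[k], qc = pc + dc[k];
      if (qr >= 0 && qr < nr && qc >= 0 && qc < nc) {
        const int l = lab(qr, qc);
        if (l > 0 && (best == 0 || l < best)) best = l;
      }
    }
    if (best == 0) continue; // isolated queue remnant; cannot happen in practice
    lab(pr, pc) = best;
    for (int k = 0; k < nn; ++k) {
      const int qr = pr + dr[k], qc = pc + dc[k];
      if (qr >= 0 && qr < nr && qc >= 0 && qc < nc &&
          mask(qr, qc) && lab(qr, qc) == 0) {
        const size_t q = (size_t)qr + (size_t)qc * nr;
        if (!queued[q]) {
          queued[q] = 1;
          pq.push(WsNode{priority(qr, qc), order++, (int)q});
        }
      }
    }
  }
  return lab;
}
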