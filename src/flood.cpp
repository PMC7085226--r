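#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Priority-flood marker watershed on a relief, 4-connectivity.
// Ties on relief value are resolved by push order (FIFO), so results are
// fully deterministic for a given relief and seed list.
namespace {

struct QNode {
  double value;
  std::uint64_t order;
  int idx;
};

struct QNodeCmp {
  bool operator()(const QNode &a, const QNode &b) const {
    if (a.value != b.value) return a.value > b.value;
    return a.order > b.order; // earlier push wins among equal relief
  }
};

} // namespace

// [[Rcpp::export(name = ".watershed_flood")]]
IntegerMatrix watershed_flood(NumericMatrix relief,
                              IntegerVector seed_rows,
                              IntegerVector seed_cols) {
  const int nr = relief.nrow(), nc = relief.ncol();
  const int k = seed_rows.size();
  if (k == 0) stop("at least one seed is required");
  IntegerMatrix labels(nr, nc);

  std::priority_queue<QNode, std::vector<QNode>, QNodeCmp> pq;
  std::uint64_t order = 0;

  for (int s = 0; s < k; ++s) {
    int r = seed_rows[s] - 1, c = seed_cols[s] - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("seed %d lies outside the image", s + 1);
    int idx = c * nr + r;
    if (labels[idx] != 0)
      stop("seeds %d and %d coincide", labels[idx], s + 1);
    labels[idx] = s + 1;
    pq.push({relief[idx], order++, idx});
  }

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  while (!pq.empty()) {
    QNode top = pq.top();
    pq.pop();
    const int idx = top.idx;
    const int r = idx % nr, c = idx / nr;
    const int lab = labels[idx];
    for (int d = 0; d < 4; ++d) {
      const int rr = r + dr[d], cc = c + dc[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int nidx = cc * nr + rr;
      if (labels[nidx] == 0) {
        labels[nidx] = lab;
        pq.push({relief[nidx], order++, nidx});
      }
    }
  }
  return labels;
}

// Grayscale morphological reconstruction by dilation (Vincent's hybrid
// algorithm): raster scan, anti-raster scan, then FIFO queue propagation.
// marker <= mask is required; the result is the largest image <= mask whose
// regional maxima are limited by marker.
// [[Rcpp::export(name = ".reconstruct_dilation")]]
NumericMatrix reconstruct_dilation(NumericMatrix marker, NumericMatrix mask) {
  const int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask must have identical dimensions");
  NumericMatrix J = clone(marker);
  for (int i = 0; i < nr * nc; ++i)
    if (J[i] > mask[i]) stop("marker must be <= mask everywhere");

  auto at = [&](int r, int c) -> double & { return J[c * nr + r]; };
  auto maskat = [&](int r, int c) -> double { return mask[c * nr + r]; };

  // forward raster: N and W neighbours
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double v = at(r, c);
      if (r > 0 && at(r - 1, c) > v) v = at(r - 1, c);
      if (c > 0 && at(r, c - 1) > v) v = at(r, c - 1);
      at(r, c) = std::min(v, maskat(r, c));
    }

  std::queue<int> fifo;
  // backward raster: S and E neighbours; queue boundary pixels
  for (int c = nc - 1; c >= 0; --c)
    for (int r = nr - 1; r >= 0; --r) {
      double v = at(r, c);
      if (r < nr - 1 && at(r + 1, c) > v) v = at(r + 1, c);
      if (c < nc - 1 && at(r, c + 1) > v) v = at(r, c + 1);
      at(r, c) = std::min(v, maskat(r, c));
      const double jv = at(r, c);
      bool push = false;
      if (r < nr - 1 && at(r + 1, c) < jv && at(r + 1, c) < maskat(r + 1, c))
        push = true;
      if (!push && c < nc - 1 && at(r, c + 1) < jv &&
          at(r, c + 1) < maskat(r, c + 1))
        push = true;
      if (push) fifo.push(c * nr + r);
    }

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!fifo.empty()) {
    const int idx = fifo.front();
    fifo.pop();
    const int r = idx % nr, c = idx / nr;
    const double jv = at(r, c);
    for (int d = 0; d < 4; ++d) {
      const int rr = r + dr[d], cc = c + dc[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (at(rr, cc) < jv && at(rr, cc) < maskat(rr, cc)) {
        at(rr, cc) = std::min(jv, maskat(rr, cc));
        fifo.push(cc * nr + rr);
      }
    }
  }
  return J;
}
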