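#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>
using namespace Rcpp;

struct QItem {
  double relief;
  uint64_t order;   // insertion counter: FIFO among equal reliefs
  int64_t idx;
  int label;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.relief != b.relief) return a.relief > b.relief;  // min-heap
    return a.order > b.order;
  }
};

// Marker-based priority-flood watershed. Markers: 0 = unlabeled, >0 = seed
// label. Voxels are flooded from a minimum-relief priority queue seeded at
// the markers (pushed in ascending linear-index order); each voxel takes the
// label of the neighbour that claimed it first; ties broken by insertion
// order. Connectivity 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export]]
IntegerVector watershed_cpp(NumericVector relief, IntegerVector dim,
                            IntegerVector markers, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int64_t n = (int64_t)nx * ny * nz;
  IntegerVector labels(n);
  std::vector<char> claimed((size_t)n, 0);

  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  uint64_t counter = 0;
  for (int64_t i = 0; i < n; ++i) {
    if (markers[i] > 0) {
      pq.push(QItem{relief[i], counter++, i, markers[i]});
      claimed[i] = 1;
    }
  }
  if (pq.empty()) stop("no marker voxels");

  // neighbour offsets
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }

  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    labels[it.idx] = it.label;
    int x = (int)(it.idx % nx);
    int y = (int)((it.idx / nx) % ny);
    int z = (int)(it.idx / ((int64_t)nx * ny));
    for (size_t m = 0; m < dxs.size(); ++m) {
      int xx = x + dxs[m], yy = y + dys[m], zz = z + dzs[m];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      int64_t j = (int64_t)xx + nx * ((int64_t)yy + (int64_t)ny * zz);
      if (claimed[j]) continue;
      claimed[j] = 1;
      pq.push(QItem{relief[j], counter++, j, it.label});
    }
  }
  return labels;
}
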