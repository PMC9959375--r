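#include "common.h"
#include <queue>
#include <vector>

using namespace Rcpp;

namespace {
struct QItem {
  double elev;
  unsigned long order;
  R_xlen_t idx;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.elev != b.elev) return a.elev > b.elev;
    return a.order > b.order; // FIFO tie-break -> deterministic
  }
};
}

// marker-controlled watershed by priority flooding, restricted to mask,
// 26-connected; markers > 0 are seeds, output label per voxel
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector elev, IntegerVector markers,
                            LogicalVector mask) {
  Dim3 d = get_dim3(elev);
  IntegerVector lab(elev.size());
  lab.attr("dim") = elev.attr("dim");
  std::priority_queue<QItem, std::vector<QItem>, QCmp> q;
  unsigned long ord = 0;
  for (R_xlen_t i = 0; i < d.n(); ++i) {
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      q.push({elev[i], ord++, i});
    }
  }
  while (!q.empty()) {
    QItem it = q.top(); q.pop();
    R_xlen_t c = it.idx;
    int cz = (int)(c % d.nz);
    int cy = (int)((c / d.nz) % d.ny);
    int cx = (int)(c / ((R_xlen_t)d.nz * d.ny));
    int cl = lab[c];
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dx && !dy && !dz) continue;
          int zz = cz + dz, yy = cy + dy, xx = cx + dx;
          if (!d.inside(zz, yy, xx)) continue;
          R_xlen_t j = d.idx(zz, yy, xx);
          if (!mask[j] || lab[j]) continue;
          lab[j] = cl;
          q.push({elev[j], ord++, j});
        }
  }
  return lab;
}
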