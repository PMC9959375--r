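#include "common.h"
#include <vector>

using namespace Rcpp;

// 26-connected component labelling of a boolean volume; labels 1..K in scan order
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask) {
  Dim3 d = get_dim3(mask);
  IntegerVector lab(mask.size());
  lab.attr("dim") = mask.attr("dim");
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        R_xlen_t i = d.idx(z, y, x);
        if (!mask[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t c = stack.back(); stack.pop_back();
          int cz = (int)(c % d.nz);
          int cy = (int)((c / d.nz) % d.ny);
          int cx = (int)(c / ((R_xlen_t)d.nz * d.ny));
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dz = -1; dz <= 1; ++dz) {
                if (!dx && !dy && !dz) continue;
                int zz = cz + dz, yy = cy + dy, xx = cx + dx;
                if (!d.inside(zz, yy, xx)) continue;
                R_xlen_t j = d.idx(zz, yy, xx);
                if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
              }
        }
      }
  return lab;
}
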