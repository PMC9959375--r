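#include "common.h"
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// trilinear resampling: output voxel i maps to input coordinate i * f per
// axis (voxel-centre aligned at the origin), clamped to the input grid
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector vol, int nz2, int ny2, int nx2,
                             double fz, double fy, double fx) {
  Dim3 d = get_dim3(vol);
  NumericVector out((R_xlen_t)nz2 * ny2 * nx2);
  out.attr("dim") = IntegerVector::create(nz2, ny2, nx2);
  Dim3 d2; d2.nz = nz2; d2.ny = ny2; d2.nx = nx2;
  for (int x = 0; x < nx2; ++x) {
    double gx = std::min(std::max(x * fx, 0.0), (double)(d.nx - 1));
    int x0 = (int)gx, x1 = std::min(x0 + 1, d.nx - 1);
    double tx = gx - x0;
    for (int y = 0; y < ny2; ++y) {
      double gy = std::min(std::max(y * fy, 0.0), (double)(d.ny - 1));
      int y0 = (int)gy, y1 = std::min(y0 + 1, d.ny - 1);
      double ty = gy - y0;
      for (int z = 0; z < nz2; ++z) {
        double gz = std::min(std::max(z * fz, 0.0), (double)(d.nz - 1));
        int z0 = (int)gz, z1 = std::min(z0 + 1, d.nz - 1);
        double tz = gz - z0;
        double c00 = vol[d.idx(z0, y0, x0)] * (1 - tz) + vol[d.idx(z1, y0, x0)] * tz;
        double c10 = vol[d.idx(z0, y1, x0)] * (1 - tz) + vol[d.idx(z1, y1, x0)] * tz;
        double c01 = vol[d.idx(z0, y0, x1)] * (1 - tz) + vol[d.idx(z1, y0, x1)] * tz;
        double c11 = vol[d.idx(z0, y1, x1)] * (1 - tz) + vol[d.idx(z1, y1, x1)] * tz;
        double c0 = c00 * (1 - ty) + c10 * ty;
        double c1 = c01 * (1 - ty) + c11 * ty;
        out[d2.idx(z, y, x)] = c0 * (1 - tx) + c1 * tx;
      }
    }
  }
  return out;
}
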