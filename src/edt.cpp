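#include "common.h"
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Felzenszwalb & Huttenlocher 1-D squared distance transform on a sampled
// line with physical sample spacing `step`.
static void dt1d(std::vector<double> &f, std::vector<double> &out,
                 std::vector<int> &v, std::vector<double> &zb, int n, double step) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  zb[0] = -INF;
  zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qq = q * step;
    double s;
    while (true) {
      double vp = v[k] * step;
      s = ((f[q] + qq * qq) - (f[v[k]] + vp * vp)) / (2 * qq - 2 * vp);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = q * step;
    while (zb[k + 1] < qq) ++k;
    double vp = v[k] * step;
    out[q] = (qq - vp) * (qq - vp) + f[v[k]];
  }
}

// anisotropic Euclidean distance (um) from each foreground voxel to the
// nearest background voxel centre
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, double dz, double dy, double dx) {
  Dim3 d = get_dim3(mask);
  // large finite init keeps the parabola intersections well-defined when a
  // whole scan line is foreground
  double ez = d.nz * dz, ey = d.ny * dy, ex = d.nx * dx;
  const double BIG = ez * ez + ey * ey + ex * ex + 1.0;
  std::vector<double> D(d.n());
  for (R_xlen_t i = 0; i < d.n(); ++i) D[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(d.nz, std::max(d.ny, d.nx));
  std::vector<double> f(nmax), o(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // z axis
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y) {
      for (int z = 0; z < d.nz; ++z) f[z] = D[d.idx(z, y, x)];
      dt1d(f, o, v, zb, d.nz, dz);
      for (int z = 0; z < d.nz; ++z) D[d.idx(z, y, x)] = o[z];
    }
  // y axis
  for (int x = 0; x < d.nx; ++x)
    for (int z = 0; z < d.nz; ++z) {
      for (int y = 0; y < d.ny; ++y) f[y] = D[d.idx(z, y, x)];
      dt1d(f, o, v, zb, d.ny, dy);
      for (int y = 0; y < d.ny; ++y) D[d.idx(z, y, x)] = o[y];
    }
  // x axis
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y) {
      for (int x = 0; x < d.nx; ++x) f[x] = D[d.idx(z, y, x)];
      dt1d(f, o, v, zb, d.nx, dx);
      for (int x = 0; x < d.nx; ++x) D[d.idx(z, y, x)] = o[x];
    }

  NumericVector out(d.n());
  out.attr("dim") = mask.attr("dim");
  for (R_xlen_t i = 0; i < d.n(); ++i) out[i] = std::sqrt(D[i]);
  return out;
}
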