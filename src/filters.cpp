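#include "common.h"
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// reflect index into [0, n-1]
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, int r) {
  Dim3 d = get_dim3(vol);
  NumericVector out(vol.size());
  out.attr("dim") = vol.attr("dim");
  int w = 2 * r + 1;
  std::vector<double> buf(w * w * w);
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        int k = 0;
        for (int dx = -r; dx <= r; ++dx) {
          int xx = reflect(x + dx, d.nx);
          for (int dy = -r; dy <= r; ++dy) {
            int yy = reflect(y + dy, d.ny);
            for (int dz = -r; dz <= r; ++dz) {
              int zz = reflect(z + dz, d.nz);
              buf[k++] = vol[d.idx(zz, yy, xx)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
        out[d.idx(z, y, x)] = buf[k / 2];
      }
  return out;
}

static void gauss_axis(std::vector<double> &v, std::vector<double> &tmp,
                       const Dim3 &d, int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto &kk : k) kk /= s;
  int n[3] = {d.nz, d.ny, d.nx};
  int na = n[axis];
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        double acc = 0;
        int c[3] = {z, y, x};
        for (int i = -r; i <= r; ++i) {
          int cc[3] = {z, y, x};
          cc[axis] = reflect(c[axis] + i, na);
          acc += k[i + r] * v[d.idx(cc[0], cc[1], cc[2])];
        }
        tmp[d.idx(z, y, x)] = acc;
      }
  v.swap(tmp);
}

// separable Gaussian, sigmas in voxels per axis (z, y, x)
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, double sz, double sy, double sx) {
  Dim3 d = get_dim3(vol);
  std::vector<double> v(vol.begin(), vol.end()), tmp(v.size());
  gauss_axis(v, tmp, d, 0, sz);
  gauss_axis(v, tmp, d, 1, sy);
  gauss_axis(v, tmp, d, 2, sx);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = vol.attr("dim");
  return out;
}

// second-difference Laplacian with per-axis physical spacing (units 1/um^2)
// [[Rcpp::export]]
NumericVector cpp_laplacian3d(NumericVector vol, double dz, double dy, double dx) {
  Dim3 d = get_dim3(vol);
  NumericVector out(vol.size());
  out.attr("dim") = vol.attr("dim");
  double wz = 1.0 / (dz * dz), wy = 1.0 / (dy * dy), wx = 1.0 / (dx * dx);
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        double c = vol[d.idx(z, y, x)];
        double az = vol[d.idx(reflect(z - 1, d.nz), y, x)] +
                    vol[d.idx(reflect(z + 1, d.nz), y, x)] - 2 * c;
        double ay = vol[d.idx(z, reflect(y - 1, d.ny), x)] +
                    vol[d.idx(z, reflect(y + 1, d.ny), x)] - 2 * c;
        double ax = vol[d.idx(z, y, reflect(x - 1, d.nx))] +
                    vol[d.idx(z, y, reflect(x + 1, d.nx))] - 2 * c;
        out[d.idx(z, y, x)] = az * wz + ay * wy + ax * wx;
      }
  return out;
}

// local maxima over the 26-neighbourhood (>= all neighbours, > min_val)
// returns 0-based (z,y,x) rows
// [[Rcpp::export]]
IntegerMatrix cpp_local_maxima(NumericVector vol, double min_val) {
  Dim3 d = get_dim3(vol);
  std::vector<int> zs, ys, xs;
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        double c = vol[d.idx(z, y, x)];
        if (!(c > min_val)) continue;
        bool mx = true;
        for (int dx = -1; dx <= 1 && mx; ++dx)
          for (int dy = -1; dy <= 1 && mx; ++dy)
            for (int dz = -1; dz <= 1 && mx; ++dz) {
              if (!dx && !dy && !dz) continue;
              int zz = z + dz, yy = y + dy, xx = x + dx;
              if (!d.inside(zz, yy, xx)) continue;
              if (vol[d.idx(zz, yy, xx)] > c) mx = false;
            }
        if (mx) { zs.push_back(z); ys.push_back(y); xs.push_back(x); }
      }
  IntegerMatrix out(zs.size(), 3);
  for (size_t i = 0; i < zs.size(); ++i) {
    out(i, 0) = zs[i]; out(i, 1) = ys[i]; out(i, 2) = xs[i];
  }
  return out;
}
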