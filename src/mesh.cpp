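#include "common.h"
#include <vector>
#include <cmath>

using namespace Rcpp;

// Isosurface area by marching tetrahedra on the Kuhn (6-tetrahedra)
// decomposition of each grid cube.  Each cube is split along its main
// diagonal into 6 tetrahedra (one per permutation of the axis steps);
// within a tetrahedron the level set of the trilinear field is planar,
// giving 0, 1 or 2 triangles per tetrahedron with vertices linearly
// interpolated on crossing edges.  The decomposition is conforming across
// faces, so the surface is watertight for interior structures.
//
// Returns a matrix with one row per triangle: (area_um2, cz, cy, cx) where
// (cz, cy, cx) is the triangle centroid in physical um (voxel centre i at i*d).

namespace {
struct P3 { double z, y, x; };

inline P3 lerp(const P3 &a, const P3 &b, double va, double vb, double level) {
  double t = (level - va) / (vb - va);
  return {a.z + t * (b.z - a.z), a.y + t * (b.y - a.y), a.x + t * (b.x - a.x)};
}

inline double tri_area(const P3 &a, const P3 &b, const P3 &c) {
  double uz = b.z - a.z, uy = b.y - a.y, ux = b.x - a.x;
  double vz = c.z - a.z, vy = c.y - a.y, vx = c.x - a.x;
  double cz = uy * vx - ux * vy;
  double cy = ux * vz - uz * vx;
  double cx = uz * vy - uy * vz;
  return 0.5 * std::sqrt(cz * cz + cy * cy + cx * cx);
}
}

// [[Rcpp::export]]
NumericMatrix cpp_mtetra_area(NumericVector vol, double level,
                              double dz, double dy, double dx) {
  Dim3 d = get_dim3(vol);
  std::vector<double> areas;
  std::vector<double> cz_, cy_, cx_;

  // the 6 permutations of axis order (z=0, y=1, x=2)
  const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  const double sp[3] = {dz, dy, dx};

  P3 pos[4];
  double val[4];

  auto emit = [&](const P3 &a, const P3 &b, const P3 &c) {
    double ar = tri_area(a, b, c);
    if (ar <= 0) return;
    areas.push_back(ar);
    cz_.push_back((a.z + b.z + c.z) / 3.0);
    cy_.push_back((a.y + b.y + c.y) / 3.0);
    cx_.push_back((a.x + b.x + c.x) / 3.0);
  };

  for (int x = 0; x + 1 < d.nx; ++x)
    for (int y = 0; y + 1 < d.ny; ++y)
      for (int z = 0; z + 1 < d.nz; ++z) {
        // fast reject on the cube
        double v8[8];
        bool anyAbove = false, anyBelow = false;
        for (int k = 0; k < 8; ++k) {
          int bz = k & 1, by = (k >> 1) & 1, bx = (k >> 2) & 1;
          v8[k] = vol[d.idx(z + bz, y + by, x + bx)];
          if (v8[k] > level) anyAbove = true; else anyBelow = true;
        }
        if (!anyAbove || !anyBelow) continue;

        for (int p = 0; p < 6; ++p) {
          int c[3] = {z, y, x}; // walk from cube origin to opposite corner
          for (int t = 0; t < 4; ++t) {
            int bz = c[0] - z, by = c[1] - y, bx = c[2] - x;
            val[t] = v8[bz | (by << 1) | (bx << 2)];
            pos[t] = {c[0] * sp[0], c[1] * sp[1], c[2] * sp[2]};
            if (t < 3) c[perms[p][t]] += 1;
          }
          bool ab[4];
          int na = 0;
          for (int t = 0; t < 4; ++t) { ab[t] = val[t] > level; if (ab[t]) ++na; }
          if (na == 0 || na == 4) continue;
          if (na == 1 || na == 3) {
            bool target = (na == 1);
            int i = 0;
            while (ab[i] != target) ++i;
            int o[3], k = 0;
            for (int t = 0; t < 4; ++t) if (t != i) o[k++] = t;
            emit(lerp(pos[i], pos[o[0]], val[i], val[o[0]], level),
                 lerp(pos[i], pos[o[1]], val[i], val[o[1]], level),
                 lerp(pos[i], pos[o[2]], val[i], val[o[2]], level));
          } else {
            int hi[2], lo[2], a = 0, b = 0;
            for (int t = 0; t < 4; ++t) (ab[t] ? hi[a++] : lo[b++]) = t;
            // quad cycle: (hi0,lo0) (hi0,lo1) (hi1,lo1) (hi1,lo0)
            P3 q0 = lerp(pos[hi[0]], pos[lo[0]], val[hi[0]], val[lo[0]], level);
            P3 q1 = lerp(pos[hi[0]], pos[lo[1]], val[hi[0]], val[lo[1]], level);
            P3 q2 = lerp(pos[hi[1]], pos[lo[1]], val[hi[1]], val[lo[1]], level);
            P3 q3 = lerp(pos[hi[1]], pos[lo[0]], val[hi[1]], val[lo[0]], level);
            emit(q0, q1, q2);
            emit(q0, q2, q3);
          }
        }
      }

  NumericMatrix out(areas.size(), 4);
  for (size_t i = 0; i < areas.size(); ++i) {
    out(i, 0) = areas[i];
    out(i, 1) = cz_[i];
    out(i, 2) = cy_[i];
    out(i, 3) = cx_[i];
  }
  colnames(out) = CharacterVector::create("area", "cz", "cy", "cx");
  return out;
}
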