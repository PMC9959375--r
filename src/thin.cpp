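#include "common.h"
#include <vector>

using namespace Rcpp;

// 3-D curve skeletonization by sequential directional thinning.
// A foreground voxel is deleted only if it is a simple point (deletion
// preserves topology) and not a curve endpoint.  Simplicity is decided by
// the local characterization: exactly one 26-connected foreground component
// in the 26-neighbourhood, and exactly one 6-connected background component
// in the 18-neighbourhood that is 6-adjacent to the centre.  Deleting a
// simple point never changes connectivity, holes or cavities, so the
// sequential schedule preserves topology by construction; the six
// directional sub-iterations keep erosion balanced so the residue is close
// to the medial axis.

namespace {

// offsets of the 3x3x3 block, index o = (dz+1) + 3*(dy+1) + 9*(dx+1); centre = 13
inline int off_index(int dz, int dy, int dx) {
  return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
}

struct Neigh {
  bool fg[27]; // foreground flags, centre at 13
};

inline void fill_neigh(const int *mask, const Dim3 &d, int z, int y, int x, Neigh &nb) {
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz, yy = y + dy, xx = x + dx;
        bool v = d.inside(zz, yy, xx) ? mask[d.idx(zz, yy, xx)] != 0 : false;
        nb.fg[off_index(dz, dy, dx)] = v;
      }
}

inline void decode(int o, int &dz, int &dy, int &dx) {
  dz = o % 3 - 1;
  dy = (o / 3) % 3 - 1;
  dx = o / 9 - 1;
}

// number of foreground 26-neighbours (centre excluded)
inline int n26_count(const Neigh &nb) {
  int c = 0;
  for (int o = 0; o < 27; ++o)
    if (o != 13 && nb.fg[o]) ++c;
  return c;
}

// number of 26-connected components of foreground within the 26-neighbourhood
int fg_components26(const Neigh &nb) {
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb.fg[s] || seen[s]) continue;
    ++comps;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int o = stack[--top];
      int oz, oy, ox;
      decode(o, oz, oy, ox);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int nz2 = oz + dz, ny2 = oy + dy, nx2 = ox + dx;
            if (nz2 < -1 || nz2 > 1 || ny2 < -1 || ny2 > 1 || nx2 < -1 || nx2 > 1)
              continue;
            int o2 = off_index(nz2, ny2, nx2);
            if (o2 == 13 || o2 == o || seen[o2] || !nb.fg[o2]) continue;
            seen[o2] = true;
            stack[top++] = o2;
          }
    }
  }
  return comps;
}

// number of 6-connected background components within the 18-neighbourhood
// that contain at least one face neighbour of the centre
int bg_components6(const Neigh &nb) {
  bool in18[27];
  for (int o = 0; o < 27; ++o) {
    int dz, dy, dx;
    decode(o, dz, dy, dx);
    int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
    in18[o] = (o != 13) && (m <= 2); // exclude 8 corners and centre
  }
  bool seen[27] = {false};
  int comps = 0;
  int stack[27];
  const int face[6] = {off_index(-1, 0, 0), off_index(1, 0, 0),
                       off_index(0, -1, 0), off_index(0, 1, 0),
                       off_index(0, 0, -1), off_index(0, 0, 1)};
  for (int fi = 0; fi < 6; ++fi) {
    int s = face[fi];
    if (nb.fg[s] || seen[s]) continue; // background face neighbour, unseen
    ++comps;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int o = stack[--top];
      int oz, oy, ox;
      decode(o, oz, oy, ox);
      const int d6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int k = 0; k < 6; ++k) {
        int nz2 = oz + d6[k][0], ny2 = oy + d6[k][1], nx2 = ox + d6[k][2];
        if (nz2 < -1 || nz2 > 1 || ny2 < -1 || ny2 > 1 || nx2 < -1 || nx2 > 1)
          continue;
        int o2 = off_index(nz2, ny2, nx2);
        if (!in18[o2] || seen[o2] || nb.fg[o2]) continue;
        seen[o2] = true;
        stack[top++] = o2;
      }
    }
  }
  return comps;
}

inline bool is_simple(const Neigh &nb) {
  return fg_components26(nb) == 1 && bg_components6(nb) == 1;
}

} // namespace

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask_in) {
  Dim3 d = get_dim3(mask_in);
  std::vector<int> mask(d.n());
  for (R_xlen_t i = 0; i < d.n(); ++i) mask[i] = mask_in[i] ? 1 : 0;

  // 6 directions (dz, dy, dx): U, D, N, S, E, W
  const int dirs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  Neigh nb;
  std::vector<R_xlen_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int di = 0; di < 6; ++di) {
      cand.clear();
      for (int x = 0; x < d.nx; ++x)
        for (int y = 0; y < d.ny; ++y)
          for (int z = 0; z < d.nz; ++z) {
            R_xlen_t i = d.idx(z, y, x);
            if (!mask[i]) continue;
            int zz = z + dirs[di][0], yy = y + dirs[di][1], xx = x + dirs[di][2];
            bool border = !d.inside(zz, yy, xx) || !mask[d.idx(zz, yy, xx)];
            if (!border) continue;
            fill_neigh(mask.data(), d, z, y, x, nb);
            int nc = n26_count(nb);
            if (nc <= 1) continue; // endpoint or isolated: keep
            if (is_simple(nb)) cand.push_back(i);
          }
      // sequential re-check so earlier deletions invalidate later candidates
      for (R_xlen_t i : cand) {
        int z = (int)(i % d.nz);
        int y = (int)((i / d.nz) % d.ny);
        int x = (int)(i / ((R_xlen_t)d.nz * d.ny));
        fill_neigh(mask.data(), d, z, y, x, nb);
        int nc = n26_count(nb);
        if (nc <= 1) continue;
        if (is_simple(nb)) {
          mask[i] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(d.n());
  out.attr("dim") = mask_in.attr("dim");
  for (R_xlen_t i = 0; i < d.n(); ++i) out[i] = mask[i] != 0;
  return out;
}
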