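#ifndef VILLOMORPH_COMMON_H
#define VILLOMORPH_COMMON_H

#include <Rcpp.h>

// Volumes are 3-D arrays dim = (nz, ny, nx), z fastest (R column-major).
// idx = z + nz * (y + ny * x)

struct Dim3 {
  int nz, ny, nx;
  R_xlen_t n() const { return (R_xlen_t)nz * ny * nx; }
  R_xlen_t idx(int z, int y, int x) const {
    return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
  }
  bool inside(int z, int y, int x) const {
    return z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx;
  }
};

inline Dim3 get_dim3(const Rcpp::RObject &a) {
  Rcpp::IntegerVector d = a.attr("dim");
  if (d.size() != 3) Rcpp::stop("expected a 3-D array");
  Dim3 dd;
  dd.nz = d[0]; dd.ny = d[1]; dd.nx = d[2];
  return dd;
}

#endif
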