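#include <Rcpp.h>
using namespace Rcpp;

// Trilinear gather/scatter on 3D arrays at fractional 0-based voxel indices.
// Gather and scatter share weights so the pair is an exact adjoint, which the
// model-based reconstruction relies on. Out-of-volume coordinates contribute 0.

// [[Rcpp::export]]
NumericVector trilinear_gather_cpp(NumericVector vol, IntegerVector dim,
                                   NumericMatrix idx) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = idx.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (R_xlen_t p = 0; p < n; ++p) {
    const double x = idx(p, 0), y = idx(p, 1), z = idx(p, 2);
    const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    double acc = 0.0;
    for (int dz = 0; dz <= 1; ++dz) {
      const int zz = z0 + dz;
      if (zz < 0 || zz >= nz) continue;
      const double wz = dz ? fz : 1.0 - fz;
      for (int dy = 0; dy <= 1; ++dy) {
        const int yy = y0 + dy;
        if (yy < 0 || yy >= ny) continue;
        const double wy = dy ? fy : 1.0 - fy;
        for (int dx = 0; dx <= 1; ++dx) {
          const int xx = x0 + dx;
          if (xx < 0 || xx >= nx) continue;
          const double wx = dx ? fx : 1.0 - fx;
          acc += wx * wy * wz *
                 v[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
        }
      }
    }
    out[p] = acc;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector trilinear_scatter_cpp(NumericVector vals, IntegerVector dim,
                                    NumericMatrix idx) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = idx.nrow();
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *v = REAL(out);
  for (R_xlen_t p = 0; p < n; ++p) {
    const double x = idx(p, 0), y = idx(p, 1), z = idx(p, 2);
    const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    const double val = vals[p];
    for (int dz = 0; dz <= 1; ++dz) {
      const int zz = z0 + dz;
      if (zz < 0 || zz >= nz) continue;
      const double wz = dz ? fz : 1.0 - fz;
      for (int dy = 0; dy <= 1; ++dy) {
        const int yy = y0 + dy;
        if (yy < 0 || yy >= ny) continue;
        const double wy = dy ? fy : 1.0 - fy;
        for (int dx = 0; dx <= 1; ++dx) {
          const int xx = x0 + dx;
          if (xx < 0 || xx >= nx) continue;
          const double wx = dx ? fx : 1.0 - fx;
          v[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] +=
              wx * wy * wz * val;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector nearest_gather_cpp(NumericVector vol, IntegerVector dim,
                                 NumericMatrix idx) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = idx.nrow();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (R_xlen_t p = 0; p < n; ++p) {
    const int xx = (int)std::floor(idx(p, 0) + 0.5);
    const int yy = (int)std::floor(idx(p, 1) + 0.5);
    const int zz = (int)std::floor(idx(p, 2) + 0.5);
    out[p] = (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                 ? 0.0
                 : v[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
  }
  return out;
}
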