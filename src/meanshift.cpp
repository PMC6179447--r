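// Hot loop of the mean-shift stage: for each query position, accumulate the
// Gaussian-kernel-weighted sums over the grid points within 3*sigma.
// Only grid points with positive stored density contribute.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".meanShiftSumsC")]]
List meanShiftSumsC(NumericVector values, IntegerVector dims,
                    NumericVector origin, NumericVector voxel,
                    NumericMatrix X, double sigma) {
  const int n = X.nrow();
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const double cut2 = 9.0 * sigma * sigma;
  const double inv2 = 1.5 / (sigma * sigma);

  NumericVector sw(n), sx(n), sy(n), sz(n);

  for (int i = 0; i < n; ++i) {
    const double x = X(i, 0), y = X(i, 1), z = X(i, 2);
    const double tx = (x - origin[0]) / voxel[0];
    const double ty = (y - origin[1]) / voxel[1];
    const double tz = (z - origin[2]) / voxel[2];
    const int hx = (int)std::ceil(3.0 * sigma / voxel[0]) + 1;
    const int hy = (int)std::ceil(3.0 * sigma / voxel[1]) + 1;
    const int hz = (int)std::ceil(3.0 * sigma / voxel[2]) + 1;
    const int bx = (int)std::lround(tx), by = (int)std::lround(ty),
              bz = (int)std::lround(tz);
    const int x0 = std::max(0, bx - hx), x1 = std::min(d1 - 1, bx + hx);
    const int y0 = std::max(0, by - hy), y1 = std::min(d2 - 1, by + hy);
    const int z0 = std::max(0, bz - hz), z1 = std::min(d3 - 1, bz + hz);

    double Sw = 0, Sx = 0, Sy = 0, Sz = 0;
    for (int kz = z0; kz <= z1; ++kz) {
      const double pz = origin[2] + kz * voxel[2];
      const double dz2 = (pz - z) * (pz - z);
      if (dz2 > cut2) continue;
      for (int ky = y0; ky <= y1; ++ky) {
        const double py = origin[1] + ky * voxel[1];
        const double dyz2 = dz2 + (py - y) * (py - y);
        if (dyz2 > cut2) continue;
        const R_xlen_t base = (R_xlen_t)d1 * (ky + (R_xlen_t)d2 * kz);
        for (int kx = x0; kx <= x1; ++kx) {
          const double rho = values[base + kx];
          if (rho <= 0) continue;
          const double px = origin[0] + kx * voxel[0];
          const double dd = dyz2 + (px - x) * (px - x);
          if (dd > cut2) continue;
          const double w = rho * std::exp(-inv2 * dd);
          Sw += w;
          Sx += w * px;
          Sy += w * py;
          Sz += w * pz;
        }
      }
    }
    sw[i] = Sw; sx[i] = Sx; sy[i] = Sy; sz[i] = Sz;
  }
  return List::create(_["sw"] = sw, _["sx"] = sx, _["sy"] = sy,
                      _["sz"] = sz);
}
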