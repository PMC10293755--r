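#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Explicit forward-Euler step of the heat equation on a regular voxel grid:
//   dT/dt = alpha * laplacian(T) + heat_rate (K/s, while the source is on)
// with either insulated (zero-flux, reflected neighbour) or fixed-ambient
// faces, and an optional convective loss -h/(rho_c * voxel) * (T - ambient)
// on the top face (z = 0). The insulated stencil is conservative: the sum of
// T over the grid changes only through source and convection terms.
//
// Grid layout matches an R array dim = c(nx, ny, nz): x fastest, z slowest;
// z = 0 is the top (heated, observed) surface.

// [[Rcpp::export]]
List fd_heat_solve_cpp(NumericVector T0, double alpha, double voxel,
                       double dt, int n_steps, NumericVector heat_rate,
                       int source_steps, double h_top, double ambient,
                       double rho_c, int snap_every, bool fixed_ambient) {
  IntegerVector dims = T0.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  std::vector<double> cur(T0.begin(), T0.end()), nxt(N);
  const double r = alpha * dt / (voxel * voxel);
  const double conv = h_top * dt / (rho_c * voxel);

  const int n_snaps = n_steps / snap_every + 1;
  NumericVector snaps(N * (R_xlen_t)n_snaps);
  NumericVector times(n_snaps);
  std::copy(cur.begin(), cur.end(), snaps.begin());
  times[0] = 0.0;
  int isnap = 1;

  for (int step = 1; step <= n_steps; ++step) {
    const bool src_on = step <= source_steps;
    for (int iz = 0; iz < nz; ++iz) {
      for (int iy = 0; iy < ny; ++iy) {
        const R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        for (int ix = 0; ix < nx; ++ix) {
          const R_xlen_t idx = base + ix;
          const double t = cur[idx];
          double lap;
          if (fixed_ambient) {
            const double xm = ix > 0      ? cur[idx - 1]  : ambient;
            const double xp = ix < nx - 1 ? cur[idx + 1]  : ambient;
            const double ym = iy > 0      ? cur[idx - nx] : ambient;
            const double yp = iy < ny - 1 ? cur[idx + nx] : ambient;
            const double zm = iz > 0      ? cur[idx - (R_xlen_t)nx * ny] : ambient;
            const double zp = iz < nz - 1 ? cur[idx + (R_xlen_t)nx * ny] : ambient;
            lap = xm + xp + ym + yp + zm + zp - 6.0 * t;
          } else {
            const double xm = ix > 0      ? cur[idx - 1]  : t;
            const double xp = ix < nx - 1 ? cur[idx + 1]  : t;
            const double ym = iy > 0      ? cur[idx - nx] : t;
            const double yp = iy < ny - 1 ? cur[idx + nx] : t;
            const double zm = iz > 0      ? cur[idx - (R_xlen_t)nx * ny] : t;
            const double zp = iz < nz - 1 ? cur[idx + (R_xlen_t)nx * ny] : t;
            lap = xm + xp + ym + yp + zm + zp - 6.0 * t;
          }
          double v = t + r * lap;
          if (src_on) v += dt * heat_rate[idx];
          if (iz == 0 && conv > 0.0) v -= conv * (t - ambient);
          nxt[idx] = v;
        }
      }
    }
    cur.swap(nxt);
    if (step % snap_every == 0) {
      std::copy(cur.begin(), cur.end(), snaps.begin() + (R_xlen_t)isnap * N);
      times[isnap] = step * dt;
      ++isnap;
    }
  }

  snaps.attr("dim") = IntegerVector::create(nx, ny, nz, n_snaps);
  return List::create(_["snapshots"] = snaps, _["times"] = times);
}
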