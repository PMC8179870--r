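#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1D lower envelope of parabolas (Felzenszwalb & Huttenlocher, 2012),
// generalized to a per-axis squared sample spacing w2 so anisotropic grids
// get true Euclidean (mm) distances. Entries with f == INF carry "no site
// reachable yet" from earlier passes and are skipped as parabola sources.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w2) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int q = 0; q < n; q++) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      s = ((f[q] - f[v[k]]) / w2 + (double)q * q - (double)v[k] * v[k]) /
          (2.0 * (q - v[k]));
      if (s <= z[k]) {
        k--;
        if (k < 0) break;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; q++) {
    while (z[j + 1] < (double)q) j++;
    double dq = (double)q - (double)v[j];
    d[q] = w2 * dq * dq + f[v[j]];
  }
}

// Exact squared Euclidean distance transform of a 3D site set.
// sites: logical vector (column-major 3D) marking source voxels.
// Returns squared distance from each voxel centre to the nearest site
// centre, in the units implied by spacing.
// [[Rcpp::export(name = ".edt_squared")]]
NumericVector edt_squared(LogicalVector sites, IntegerVector dims,
                          NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sites.size() != n) stop("sites length does not match dims");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = sites[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 2);
  std::vector<int> v(nmax);

  double wx = spacing[0] * spacing[0];
  double wy = spacing[1] * spacing[1];
  double wz = spacing[2] * spacing[2];

  // pass along x (fastest-varying index)
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, v, z, nx, wx);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }

  // pass along y
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, v, z, ny, wy);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)j * nx] = d[j];
    }

  // pass along z
  R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; k++) f[k] = out[base + (R_xlen_t)k * plane];
      dt1d(f, d, v, z, nz, wz);
      for (int k = 0; k < nz; k++) out[base + (R_xlen_t)k * plane] = d[k];
    }

  return out;
}
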