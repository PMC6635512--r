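#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable 1D lower-envelope passes along x, y, z.  Distances are between
// voxel centers, in voxel units; only in-grid feature voxels count (the
// domain boundary is not a feature).

static const double BIG = 1e15;

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector feature, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // init: 0 at feature voxels, BIG elsewhere
  for (R_xlen_t i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
      for (int q = 0; q < nx; ++q) f[q] = out[base + q];
      dt1d(f, d, v, z, nx);
      for (int q = 0; q < nx; ++q) out[base + q] = d[q];
    }
  // pass along y
  for (int kz = 0; kz < nz; ++kz)
    for (int kx = 0; kx < nx; ++kx) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + kx;
      for (int q = 0; q < ny; ++q) f[q] = out[base + (R_xlen_t)q * nx];
      dt1d(f, d, v, z, ny);
      for (int q = 0; q < ny; ++q) out[base + (R_xlen_t)q * nx] = d[q];
    }
  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ++ky)
    for (int kx = 0; kx < nx; ++kx) {
      R_xlen_t base = (R_xlen_t)ky * nx + kx;
      for (int q = 0; q < nz; ++q) f[q] = out[base + (R_xlen_t)q * nxy];
      dt1d(f, d, v, z, nz);
      for (int q = 0; q < nz; ++q) out[base + (R_xlen_t)q * nxy] = d[q];
    }

  // voxels unreachable from any feature stay effectively infinite
  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] >= BIG) out[i] = R_PosInf;
  return out;
}
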