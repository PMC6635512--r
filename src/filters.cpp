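#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 3D spherical median filter and iterated binary dilation.  Neighborhoods
// are truncated at the grid boundary (no padding).  With an even number of
// in-bounds neighbors the upper median (element n/2, 0-based, of the sorted
// values) is taken; interior spherical neighborhoods have odd size, so this
// only matters within `radius` of a face.

// [[Rcpp::export]]
IntegerVector median_filter3d_cpp(IntegerVector vol, IntegerVector dim,
                                  int radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxy * nz;
  IntegerVector out(n);

  std::vector<int> odx, ody, odz;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius) {
          odx.push_back(dx);
          ody.push_back(dy);
          odz.push_back(dz);
        }
  const size_t no = odx.size();
  std::vector<int> buf(no);

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        size_t m = 0;
        for (size_t o = 0; o < no; ++o) {
          int xx = x + odx[o], yy = y + ody[o], zz = z + odz[o];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          buf[m++] = vol[(R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx];
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        out[(R_xlen_t)z * nxy + (R_xlen_t)y * nx + x] = buf[m / 2];
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector dilate3d_cpp(LogicalVector mask, IntegerVector dim, int steps,
                           int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxy * nz;

  std::vector<int> odx, ody, odz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int a = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (a == 0) continue;
        if (connectivity == 6 && a > 1) continue;
        odx.push_back(dx);
        ody.push_back(dy);
        odz.push_back(dz);
      }

  std::vector<char> cur(n), nxt(n);
  for (R_xlen_t i = 0; i < n; ++i) cur[i] = mask[i] ? 1 : 0;

  for (int s = 0; s < steps; ++s) {
    nxt = cur;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t i = (R_xlen_t)z * nxy + (R_xlen_t)y * nx + x;
          if (cur[i]) continue;
          for (size_t o = 0; o < odx.size(); ++o) {
            int xx = x + odx[o], yy = y + ody[o], zz = z + odz[o];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
                zz >= nz)
              continue;
            if (cur[(R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx]) {
              nxt[i] = 1;
              break;
            }
          }
        }
    std::swap(cur, nxt);
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = cur[i] != 0;
  return out;
}
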