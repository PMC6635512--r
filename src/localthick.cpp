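#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Local thickness by maximal inscribed spheres.
//
// For a pore voxel c, the largest sphere centered at c that stays inside the
// pore phase is the open ball of radius D(c), where D(c)^2 is the squared
// Euclidean distance to the nearest non-pore voxel center: it contains every
// voxel u with |u - c|^2 <= D(c)^2 - 1 (squared center distances are
// integers).  The local thickness at v is the largest D(c) over all centers
// c whose ball covers v.  Radii are returned squared, in voxel units, so
// agreement with a brute-force search can be checked exactly.

struct Off { int dx, dy, dz, d2; };

// [[Rcpp::export]]
NumericVector local_thickness_sq_cpp(LogicalVector pore, IntegerVector dim,
                                     NumericVector dbg_sq) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxy * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = 0.0;

  // collect pore centers and the largest squared radius needed
  double maxd2 = 0.0;
  std::vector<R_xlen_t> centers;
  centers.reserve(1024);
  for (R_xlen_t i = 0; i < n; ++i)
    if (pore[i]) {
      centers.push_back(i);
      if (dbg_sq[i] > maxd2) maxd2 = dbg_sq[i];
    }
  if (centers.empty()) return out;
  if (!R_FINITE(maxd2)) {
    // no background anywhere: every pore voxel is covered by an unbounded
    // sphere; report the grid diagonal as a sentinel
    double diag2 = (double)nx * nx + (double)ny * ny + (double)nz * nz;
    for (R_xlen_t i = 0; i < n; ++i)
      if (pore[i]) out[i] = diag2;
    return out;
  }

  // offsets with d2 <= maxd2 - 1, sorted ascending by d2
  int rmax = (int)std::floor(std::sqrt(std::max(0.0, maxd2 - 1.0)));
  std::vector<Off> offs;
  for (int dz = -rmax; dz <= rmax; ++dz)
    for (int dy = -rmax; dy <= rmax; ++dy)
      for (int dx = -rmax; dx <= rmax; ++dx) {
        int d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= maxd2 - 1.0) offs.push_back({dx, dy, dz, d2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Off &a, const Off &b) { return a.d2 < b.d2; });

  for (R_xlen_t ci = 0; ci < (R_xlen_t)centers.size(); ++ci) {
    R_xlen_t c = centers[ci];
    double D2 = dbg_sq[c];
    int cz = (int)(c / nxy);
    int rem = (int)(c - (R_xlen_t)cz * nxy);
    int cy = rem / nx;
    int cx = rem - cy * nx;
    double lim = D2 - 1.0; // ball contains offsets with d2 <= D2 - 1
    for (size_t oi = 0; oi < offs.size(); ++oi) {
      const Off &o = offs[oi];
      if (o.d2 > lim) break;
      int x = cx + o.dx, y = cy + o.dy, z = cz + o.dz;
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
      R_xlen_t v = (R_xlen_t)z * nxy + (R_xlen_t)y * nx + x;
      if (out[v] < D2) out[v] = D2;
    }
  }
  return out;
}
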