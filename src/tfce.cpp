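#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Neighbour offsets for 6/18/26 connectivity on a 3D lattice.
static void neighbour_offsets(int connectivity, std::vector<std::array<int,3>>& off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dx, dy, dz});
      }
}

// Label connected components of a logical 3D mask (column-major, dims nx,ny,nz).
// Returns an integer vector: 0 outside the mask, component id (1..k) inside.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if ((R_xlen_t)nx * ny * nz != mask.size()) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<std::array<int,3>> off;
  neighbour_offsets(connectivity, off);
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<int> q;
  for (int idx = 0; idx < (int)mask.size(); ++idx) {
    if (!mask[idx] || lab[idx] != 0) continue;
    ++next;
    lab[idx] = next;
    q.push(idx);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
      for (const auto& d : off) {
        int x = cx + d[0], y = cy + d[1], z = cz + d[2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        int nb = x + nx * (y + ny * z);
        if (mask[nb] && lab[nb] == 0) { lab[nb] = next; q.push(nb); }
      }
    }
  }
  return lab;
}

// Threshold-free cluster enhancement of a non-negative statistic map.
// For each voxel v: sum_h extent(v,h)^E * h^H * dh over thresholds
// h = dh, 2*dh, ... where extent(v,h) is the size of the supra-threshold
// (stat >= h) connected component containing v. Negative values are ignored;
// callers handle the negative tail by passing -stat.
// [[Rcpp::export(name = ".tfce_3d")]]
NumericVector tfce_3d(NumericVector stat, IntegerVector dim, double E, double H,
                      double dh, int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  if ((R_xlen_t)n != stat.size()) stop("stat length does not match dim");
  if (dh <= 0) stop("dh must be > 0");
  for (int i = 0; i < n; ++i)
    if (!R_finite(stat[i])) stop("non-finite values in statistic map");
  std::vector<std::array<int,3>> off;
  neighbour_offsets(connectivity, off);
  NumericVector out(n, 0.0);
  double mx = 0.0;
  for (int i = 0; i < n; ++i) if (stat[i] > mx) mx = stat[i];
  if (mx <= 0) return out;
  std::vector<int> lab(n);
  std::vector<int> csize;
  std::queue<int> q;
  for (double h = dh; h <= mx + 1e-12; h += dh) {
    std::fill(lab.begin(), lab.end(), 0);
    csize.clear();
    csize.push_back(0); // dummy for id 0
    for (int idx = 0; idx < n; ++idx) {
      if (stat[idx] < h || lab[idx] != 0) continue;
      int id = (int)csize.size();
      csize.push_back(0);
      lab[idx] = id;
      ++csize[id];
      q.push(idx);
      while (!q.empty()) {
        int cur = q.front(); q.pop();
        int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
        for (const auto& d : off) {
          int x = cx + d[0], y = cy + d[1], z = cz + d[2];
          if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
          int nb = x + nx * (y + ny * z);
          if (stat[nb] >= h && lab[nb] == 0) { lab[nb] = id; ++csize[id]; q.push(nb); }
        }
      }
    }
    double hH = std::pow(h, H) * dh;
    for (int idx = 0; idx < n; ++idx)
      if (lab[idx] != 0)
        out[idx] += std::pow((double)csize[lab[idx]], E) * hH;
  }
  return out;
}
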