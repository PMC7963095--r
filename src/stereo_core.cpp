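#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Arrays are stored in R order dim = c(nz, ny, nx): z is the fastest index.
// Linear index (0-based): idx = iz + nz * (iy + ny * ix).

// Assign every voxel centre to the seed minimising the power distance
// |p - c_k|^2 - w_k (additively weighted / Laguerre tessellation).
// seeds: K x 3 matrix of (z, y, x) positions in micrometres.
// With periodic = true distances wrap around the box (toroidal tessellation:
// no boundary cells, homogeneous statistics).
// [[Rcpp::export]]
IntegerVector cpp_lag_assign(IntegerVector dims, NumericVector pitch,
                             NumericMatrix seeds, NumericVector w,
                             bool periodic = false) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dz = pitch[0], dy = pitch[1], dx = pitch[2];
  const double Lz = nz * dz, Ly = ny * dy, Lx = nx * dx;
  const int K = seeds.nrow();
  IntegerVector out(static_cast<R_xlen_t>(nz) * ny * nx);
  std::vector<double> sz(K), sy(K), sx(K), sw(K);
  for (int k = 0; k < K; ++k) {
    sz[k] = seeds(k, 0); sy[k] = seeds(k, 1); sx[k] = seeds(k, 2); sw[k] = w[k];
  }
  R_xlen_t idx = 0;
  for (int ix = 0; ix < nx; ++ix) {
    const double px = (ix + 0.5) * dx;
    for (int iy = 0; iy < ny; ++iy) {
      const double py = (iy + 0.5) * dy;
      for (int iz = 0; iz < nz; ++iz, ++idx) {
        const double pz = (iz + 0.5) * dz;
        double best = R_PosInf; int bk = 0;
        for (int k = 0; k < K; ++k) {
          double az = pz - sz[k], ay = py - sy[k], ax = px - sx[k];
          if (periodic) {
            az = std::abs(az); if (az > Lz - az) az = Lz - az;
            ay = std::abs(ay); if (ay > Ly - ay) ay = Ly - ay;
            ax = std::abs(ax); if (ax > Lx - ax) ax = Lx - ax;
          }
          const double d = az * az + ay * ay + ax * ax - sw[k];
          if (d < best) { best = d; bk = k; }
        }
        out[idx] = bk + 1;
      }
    }
  }
  return out;
}

// Tolerance-based flood fill (the "magic wand"): maximal connected set
// containing the seed with lo <= intensity <= hi. 6-connectivity in 3D;
// passing dims = c(1, ny, nx) yields 4-connectivity in 2D.
// Returns 1-based voxel indices and an overflow flag when the region would
// exceed max_voxels (growth stops immediately in that case).
// [[Rcpp::export]]
List cpp_flood(IntegerVector img, IntegerVector dims, int seed_idx,
               double lo, double hi, int max_voxels) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nz) * ny * nx;
  if (seed_idx < 0 || seed_idx >= n) stop("seed index out of range");
  std::vector<char> visited(n, 0);
  std::vector<int> region;
  bool overflow = false;
  if (img[seed_idx] < lo || img[seed_idx] > hi) {
    return List::create(_["indices"] = IntegerVector(0),
                        _["overflow"] = false);
  }
  std::queue<R_xlen_t> q;
  q.push(seed_idx);
  visited[seed_idx] = 1;
  while (!q.empty()) {
    R_xlen_t v = q.front(); q.pop();
    region.push_back(static_cast<int>(v));
    if ((int)region.size() > max_voxels) { overflow = true; break; }
    const int iz = v % nz;
    const int iy = (v / nz) % ny;
    const int ix = v / (static_cast<R_xlen_t>(nz) * ny);
    const int dzs[6] = {-1, 1, 0, 0, 0, 0};
    const int dys[6] = {0, 0, -1, 1, 0, 0};
    const int dxs[6] = {0, 0, 0, 0, -1, 1};
    for (int d = 0; d < 6; ++d) {
      const int jz = iz + dzs[d], jy = iy + dys[d], jx = ix + dxs[d];
      if (jz < 0 || jz >= nz || jy < 0 || jy >= ny || jx < 0 || jx >= nx)
        continue;
      const R_xlen_t u = jz + static_cast<R_xlen_t>(nz) * (jy + static_cast<R_xlen_t>(ny) * jx);
      if (visited[u]) continue;
      if (img[u] >= lo && img[u] <= hi) {
        visited[u] = 1;
        q.push(u);
      }
    }
  }
  IntegerVector idx(region.size());
  for (size_t i = 0; i < region.size(); ++i) idx[i] = region[i] + 1;
  return List::create(_["indices"] = idx, _["overflow"] = overflow);
}

// 6-connected component labelling of a logical mask (4-connected for 2D
// inputs passed as dims = c(1, ny, nx)). Labels are 1..n_components in
// first-encounter order; background stays 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nz) * ny * nx;
  IntegerVector lab(n);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      const int iz = v % nz;
      const int iy = (v / nz) % ny;
      const int ix = v / (static_cast<R_xlen_t>(nz) * ny);
      const int dzs[6] = {-1, 1, 0, 0, 0, 0};
      const int dys[6] = {0, 0, -1, 1, 0, 0};
      const int dxs[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        const int jz = iz + dzs[d], jy = iy + dys[d], jx = ix + dxs[d];
        if (jz < 0 || jz >= nz || jy < 0 || jy >= ny || jx < 0 || jx >= nx)
          continue;
        const R_xlen_t u = jz + static_cast<R_xlen_t>(nz) * (jy + static_cast<R_xlen_t>(ny) * jx);
        if (mask[u] && lab[u] == 0) {
          lab[u] = next;
          stack.push_back(u);
        }
      }
    }
  }
  return lab;
}
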