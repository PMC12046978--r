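#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
#include <queue>

using namespace Rcpp;

// One-dimensional squared distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher. f holds squared distances, spacing the voxel
// pitch along this axis. Result overwrites d.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double spacing) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double s2 = spacing * spacing;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue; // an empty column never forms the envelope
    bool placed = false;
    double s = 0.0;
    while (!placed) {
      double fv = f[v[k]];
      if (fv == INF) {
        // infinitely high parabola: q replaces it outright
        if (k == 0) {
          v[0] = q; z[0] = -INF; z[1] = INF;
          placed = true;
        } else {
          --k;
        }
        continue;
      }
      s = ((f[q] + (double)q * q * s2) - (fv + (double)v[k] * v[k] * s2)) /
          (2.0 * s2 * (q - v[k]));
      if (s <= z[k]) {
        if (k == 0) {
          v[0] = q; z[0] = -INF; z[1] = INF;
          placed = true;
        } else {
          --k;
        }
      } else {
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
        placed = true;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k; // envelope breakpoints in index units
    double diff = ((double)q - v[k]) * spacing;
    d[q] = diff * diff + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  // initialize: 0 where mask, INF elsewhere
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x (fastest-varying)
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * nx * ny];
      dt1d(f, d, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nx * ny] = std::sqrt(d[z]);
    }
  return out;
}

// Connected-component labelling of a binary volume, 6- or 26-connectivity.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int cz = (int)(cur / ((R_xlen_t)nx * ny));
      int rem = (int)(cur % ((R_xlen_t)nx * ny));
      int cy = rem / nx, cx = rem % nx;
      for (size_t j = 0; j < offx.size(); ++j) {
        int xx = cx + offx[j], yy = cy + offy[j], zz = cz + offz[j];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t idx = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[idx] && !lab[idx]) {
          lab[idx] = next;
          q.push(idx);
        }
      }
    }
  }
  return lab;
}
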