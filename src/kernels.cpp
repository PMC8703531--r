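#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Accumulate truncated Gaussian kernels onto a regular grid.
// Voxel (i,j,k) (0-based) has physical center origin + (i,j,k)*voxel.
// Each atom a contributes w[a] * exp(-r^2 / (2 sigma^2)) for r <= trunc*sigma.
// [[Rcpp::export(name = ".cpp_accumulate_gaussians")]]
NumericVector cpp_accumulate_gaussians(IntegerVector dims,
                                       NumericVector origin,
                                       NumericVector voxel,
                                       NumericMatrix coords,
                                       NumericVector weights,
                                       double sigma,
                                       double trunc) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double rad = trunc * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const int na = coords.nrow();
  for (int a = 0; a < na; ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    const double w = weights[a];
    int i0 = (int)std::ceil((ax - rad - origin[0]) / voxel[0]);
    int i1 = (int)std::floor((ax + rad - origin[0]) / voxel[0]);
    int j0 = (int)std::ceil((ay - rad - origin[1]) / voxel[1]);
    int j1 = (int)std::floor((ay + rad - origin[1]) / voxel[1]);
    int k0 = (int)std::ceil((az - rad - origin[2]) / voxel[2]);
    int k1 = (int)std::floor((az + rad - origin[2]) / voxel[2]);
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;
    if (i0 > i1 || j0 > j1 || k0 > k1) continue;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * voxel[2] - az;
      const double dz2 = dz * dz;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * voxel[1] - ay;
        const double dyz2 = dy * dy + dz2;
        const R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * voxel[0] - ax;
          const double r2 = dx * dx + dyz2;
          if (r2 <= rad * rad) out[base + i] += w * std::exp(-r2 * inv2s2);
        }
      }
    }
  }
  return out;
}

// Label connected components of a logical mask (stored as int 0/1) on an
// nx*ny*nz grid under 6-, 18- or 26-connectivity. Returns integer labels,
// 0 = background, components numbered from 1 in scan order.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  // neighbour offsets
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  const int nn = (int)di.size();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i = (int)(v % nx);
      int j = (int)((v / nx) % ny);
      int k = (int)(v / ((R_xlen_t)nx * ny));
      for (int t = 0; t < nn; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t u = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
        if (mask[u] && !lab[u]) { lab[u] = next; stack.push_back(u); }
      }
    }
  }
  return lab;
}

// All pairs (i from A, j from B) with euclidean distance < cutoff,
// via a uniform cell grid on B. Returns a 3-column matrix (ia, ib, dist),
// 1-based indices.
// [[Rcpp::export(name = ".cpp_close_pairs")]]
NumericMatrix cpp_close_pairs(NumericMatrix A, NumericMatrix B, double cutoff) {
  const int na = A.nrow(), nb = B.nrow();
  std::vector<double> out;
  if (na == 0 || nb == 0) return NumericMatrix(0, 3);
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = B(0, d); hi[d] = B(0, d); }
  for (int j = 0; j < nb; ++j)
    for (int d = 0; d < 3; ++d) {
      if (B(j, d) < lo[d]) lo[d] = B(j, d);
      if (B(j, d) > hi[d]) hi[d] = B(j, d);
    }
  const double cell = cutoff;
  int ncell[3];
  for (int d = 0; d < 3; ++d) {
    ncell[d] = (int)std::floor((hi[d] - lo[d]) / cell) + 1;
    if (ncell[d] < 1) ncell[d] = 1;
  }
  const R_xlen_t ntot = (R_xlen_t)ncell[0] * ncell[1] * ncell[2];
  std::vector<std::vector<int> > bins((size_t)ntot);
  for (int j = 0; j < nb; ++j) {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      c[d] = (int)std::floor((B(j, d) - lo[d]) / cell);
      if (c[d] < 0) c[d] = 0;
      if (c[d] >= ncell[d]) c[d] = ncell[d] - 1;
    }
    bins[(size_t)((R_xlen_t)c[2] * ncell[0] * ncell[1] +
                  (R_xlen_t)c[1] * ncell[0] + c[0])].push_back(j);
  }
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < na; ++i) {
    int c[3];
    bool inrange = true;
    for (int d = 0; d < 3; ++d) {
      c[d] = (int)std::floor((A(i, d) - lo[d]) / cell);
      if (c[d] < -1 || c[d] > ncell[d]) inrange = false;
    }
    if (!inrange) {
      // atom far outside B's bounding box extended by one cell: no pair possible
      bool possible = true;
      for (int d = 0; d < 3; ++d)
        if (A(i, d) < lo[d] - cutoff || A(i, d) > hi[d] + cutoff) possible = false;
      if (!possible) continue;
    }
    for (int dk2 = -1; dk2 <= 1; ++dk2)
      for (int dj2 = -1; dj2 <= 1; ++dj2)
        for (int di2 = -1; di2 <= 1; ++di2) {
          int ii = c[0] + di2, jj = c[1] + dj2, kk = c[2] + dk2;
          if (ii < 0 || ii >= ncell[0] || jj < 0 || jj >= ncell[1] ||
              kk < 0 || kk >= ncell[2])
            continue;
          const std::vector<int>& bin =
            bins[(size_t)((R_xlen_t)kk * ncell[0] * ncell[1] +
                          (R_xlen_t)jj * ncell[0] + ii)];
          for (size_t t = 0; t < bin.size(); ++t) {
            int j = bin[t];
            double dx = A(i, 0) - B(j, 0);
            double dy = A(i, 1) - B(j, 1);
            double dz = A(i, 2) - B(j, 2);
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 < c2) {
              out.push_back(i + 1);
              out.push_back(j + 1);
              out.push_back(std::sqrt(r2));
            }
          }
        }
  }
  const int np = (int)(out.size() / 3);
  NumericMatrix res(np, 3);
  for (int p = 0; p < np; ++p) {
    res(p, 0) = out[3 * p];
    res(p, 1) = out[3 * p + 1];
    res(p, 2) = out[3 * p + 2];
  }
  return res;
}

// Count voxels whose center lies within `radius` of any reference point and
// whose value satisfies value < threshold (strict). Also usable for masking:
// returns the linear (1-based) indices of in-radius voxels when want_indices.
// [[Rcpp::export(name = ".cpp_voxels_near_atoms")]]
IntegerVector cpp_voxels_near_atoms(IntegerVector dims, NumericVector origin,
                                    NumericVector voxel, NumericMatrix coords,
                                    double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> hit((size_t)n, 0);
  const double r2max = radius * radius;
  for (int a = 0; a < coords.nrow(); ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    int i0 = (int)std::ceil((ax - radius - origin[0]) / voxel[0]);
    int i1 = (int)std::floor((ax + radius - origin[0]) / voxel[0]);
    int j0 = (int)std::ceil((ay - radius - origin[1]) / voxel[1]);
    int j1 = (int)std::floor((ay + radius - origin[1]) / voxel[1]);
    int k0 = (int)std::ceil((az - radius - origin[2]) / voxel[2]);
    int k1 = (int)std::floor((az + radius - origin[2]) / voxel[2]);
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + k * voxel[2] - az;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + j * voxel[1] - ay;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > r2max) continue;
        const R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + i * voxel[0] - ax;
          if (dx * dx + dyz2 <= r2max) hit[(size_t)(base + i)] = 1;
        }
      }
    }
  }
  R_xlen_t cnt = 0;
  for (R_xlen_t s = 0; s < n; ++s) if (hit[(size_t)s]) ++cnt;
  IntegerVector idx(cnt);
  R_xlen_t p = 0;
  for (R_xlen_t s = 0; s < n; ++s) if (hit[(size_t)s]) idx[p++] = (int)(s + 1);
  return idx;
}
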