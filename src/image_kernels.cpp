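#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Trilinear interpolation on a 3-D array at fractional 1-based voxel indices.
// Points outside the grid (beyond the outermost voxel centers) return fill.
// [[Rcpp::export]]
NumericVector trilinear_cpp(NumericVector vox, NumericMatrix ijk, double fill) {
  IntegerVector dm = vox.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  int n = ijk.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double x = ijk(p, 0) - 1.0, y = ijk(p, 1) - 1.0, z = ijk(p, 2) - 1.0;
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[p] = fill;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) --i0;
    if (j0 == ny - 1) --j0;
    if (k0 == nz - 1) --k0;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    auto at = [&](int i, int j, int k) {
      return vox[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i];
    };
    double c00 = at(i0, j0, k0) * (1 - fx) + at(i1, j0, k0) * fx;
    double c10 = at(i0, j1, k0) * (1 - fx) + at(i1, j1, k0) * fx;
    double c01 = at(i0, j0, k1) * (1 - fx) + at(i1, j0, k1) * fx;
    double c11 = at(i0, j1, k1) * (1 - fx) + at(i1, j1, k1) * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// 26-connected component labelling by breadth-first search.
// Returns integer array: 0 for background, 1..ncomp labels.
// [[Rcpp::export]]
IntegerVector cc_label26_cpp(LogicalVector mask) {
  IntegerVector dm = mask.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  lab.attr("dim") = dm;
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front();
      q.pop();
      int k = v / ((R_xlen_t)nx * ny);
      int rem = v - (R_xlen_t)k * nx * ny;
      int j = rem / nx, i = rem - j * nx;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            R_xlen_t w = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
            if (mask[w] && lab[w] == 0) {
              lab[w] = cur;
              q.push(w);
            }
          }
    }
  }
  return lab;
}

// Binary dilation (grow=true) or erosion (grow=false) with an arbitrary
// structuring element given as an m x 3 matrix of integer voxel offsets.
// [[Rcpp::export]]
LogicalVector morph_cpp(LogicalVector mask, IntegerMatrix offsets, bool grow) {
  IntegerVector dm = mask.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  out.attr("dim") = dm;
  int m = offsets.nrow();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
        bool acc = !grow;  // erosion: AND over SE; dilation: OR over SE
        for (int o = 0; o < m; ++o) {
          int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
          bool val;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            val = false;  // outside grid counts as background
          else
            val = mask[(R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii];
          if (grow) {
            if (val) { acc = true; break; }
          } else {
            if (!val) { acc = false; break; }
          }
        }
        out[v] = acc;
      }
  return out;
}

// Fill interior cavities: 6-connected flood fill of the background from the
// grid border; unreached background voxels are holes and become foreground.
// [[Rcpp::export]]
LogicalVector fill_holes_cpp(LogicalVector mask) {
  IntegerVector dm = mask.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> reach(n, 0);
  std::queue<R_xlen_t> q;
  auto push_if_bg = [&](int i, int j, int k) {
    R_xlen_t v = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
    if (!mask[v] && !reach[v]) {
      reach[v] = 1;
      q.push(v);
    }
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 || k == nz - 1)
          push_if_bg(i, j, k);
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    R_xlen_t v = q.front();
    q.pop();
    int k = v / ((R_xlen_t)nx * ny);
    int rem = v - (R_xlen_t)k * nx * ny;
    int j = rem / nx, i = rem - j * nx;
    for (int d = 0; d < 6; ++d) {
      int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      push_if_bg(ii, jj, kk);
    }
  }
  LogicalVector out(n);
  out.attr("dim") = dm;
  for (R_xlen_t v = 0; v < n; ++v) out[v] = mask[v] || !reach[v];
  return out;
}
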