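#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// 3D neighborhood offsets for connectivity 6 / 18 / 26
static std::vector<std::array<int, 3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ord = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// Connected-component labeling of a binary 3D array (column-major, R layout).
// Component ids are contiguous from 1 in scan order of the first voxel.
// [[Rcpp::export]]
IntegerVector cc_label_3d(IntegerVector mask, IntegerVector dims,
                          int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);
  auto off = neighbor_offsets(connectivity);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || labels[i] != 0) continue;
    ++next;
    labels[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((R_xlen_t)nx * ny);
      for (auto &d : off) {
        int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[j] != 0 && labels[j] == 0) {
          labels[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  labels.attr("n_components") = next;
  return labels;
}

// Fill interior cavities: background voxels not reachable from the array
// border (6-connectivity on the complement) become foreground.
// [[Rcpp::export]]
IntegerVector fill_holes_3d(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<R_xlen_t> stack;
  auto off = neighbor_offsets(6);
  // seed from every border voxel that is background
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x > 0 && x < nx - 1 && y > 0 && y < ny - 1 && z > 0 && z < nz - 1)
          continue;
        R_xlen_t i = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (mask[i] == 0 && !outside[i]) {
          outside[i] = 1;
          stack.push_back(i);
        }
      }
  while (!stack.empty()) {
    R_xlen_t cur = stack.back();
    stack.pop_back();
    int x = cur % nx, y = (cur / nx) % ny, z = cur / ((R_xlen_t)nx * ny);
    for (auto &d : off) {
      int xx = x + d[0], yy = y + d[1], zz = z + d[2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (mask[j] == 0 && !outside[j]) {
        outside[j] = 1;
        stack.push_back(j);
      }
    }
  }
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (mask[i] != 0 || !outside[i]) ? 1 : 0;
  return out;
}

// Per-component WM ratio of the 26-connected 1-voxel shell.
// shell = 26-dilation of the component minus the component itself; shell
// voxels labeled CSF(1)/GM(2)/WM(3) enter the denominator, WM(3) the
// numerator; background (0) shell voxels are ignored; empty denominator -> 0.
// [[Rcpp::export]]
NumericVector shell_wm_ratio_3d(IntegerVector labels, IntegerVector tissue,
                                IntegerVector dims, int n_components) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  auto off = neighbor_offsets(26);
  std::vector<std::unordered_set<R_xlen_t>> shell(n_components);
  for (R_xlen_t i = 0; i < n; ++i) {
    int lab = labels[i];
    if (lab == 0) continue;
    int x = i % nx, y = (i / nx) % ny, z = i / ((R_xlen_t)nx * ny);
    for (auto &d : off) {
      int xx = x + d[0], yy = y + d[1], zz = z + d[2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t j = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      if (labels[j] != lab) shell[lab - 1].insert(j);
    }
  }
  NumericVector ratio(n_components);
  for (int k = 0; k < n_components; ++k) {
    long wm = 0, denom = 0;
    for (R_xlen_t j : shell[k]) {
      int t = tissue[j];
      if (t >= 1 && t <= 3) {
        ++denom;
        if (t == 3) ++wm;
      }
    }
    ratio[k] = denom > 0 ? (double)wm / (double)denom : 0.0;
  }
  return ratio;
}
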