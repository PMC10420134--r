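#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel grids arrive as R column-major vectors with dims (nx, ny, nz);
// level 0 marks voxels outside the ROI, levels 1..n_levels are inside.

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// 26-neighbourhood offsets; the first 6 are the face-connected subset.
static const int OFF26[26][3] = {
  {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1},
  {1,1,0},{1,-1,0},{-1,1,0},{-1,-1,0},
  {1,0,1},{1,0,-1},{-1,0,1},{-1,0,-1},
  {0,1,1},{0,1,-1},{0,-1,1},{0,-1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1},
  {-1,1,1},{-1,1,-1},{-1,-1,1},{-1,-1,-1}
};

// 13 unique direction vectors (half of the 26-neighbourhood) used for
// distance-1 GLCM pairs and GLRLM run walks.
static const int DIR13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

// [[Rcpp::export]]
IntegerMatrix cpp_glszm(IntegerVector levels, IntegerVector dims,
                        int n_levels, bool conn26) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n_off = conn26 ? 26 : 6;
  std::vector<char> seen(levels.size(), 0);
  std::vector<std::pair<int,int> > zones;  // (level, size)
  struct Vox { int i, j, k; };
  std::vector<Vox> stack;
  int max_size = 0;
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    const int v = idx3(i, j, k, nx, ny);
    const int lev = levels[v];
    if (lev == 0 || seen[v]) continue;
    int size = 0;
    stack.clear();
    stack.push_back(Vox{i, j, k});
    seen[v] = 1;
    while (!stack.empty()) {
      const Vox cur = stack.back(); stack.pop_back();
      ++size;
      for (int o = 0; o < n_off; ++o) {
        const int pi = cur.i + OFF26[o][0], pj = cur.j + OFF26[o][1],
                  pk = cur.k + OFF26[o][2];
        if (pi < 0 || pi >= nx || pj < 0 || pj >= ny || pk < 0 || pk >= nz) continue;
        const int p = idx3(pi, pj, pk, nx, ny);
        if (!seen[p] && levels[p] == lev) {
          seen[p] = 1;
          stack.push_back(Vox{pi, pj, pk});
        }
      }
    }
    zones.push_back(std::make_pair(lev, size));
    if (size > max_size) max_size = size;
  }
  IntegerMatrix P(n_levels, max_size > 0 ? max_size : 1);
  for (size_t z = 0; z < zones.size(); ++z)
    P(zones[z].first - 1, zones[z].second - 1) += 1;
  return P;
}

// [[Rcpp::export]]
IntegerMatrix cpp_gldm(IntegerVector levels, IntegerVector dims,
                       int n_levels, double alpha, bool conn26) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n_off = conn26 ? 26 : 6;
  const int max_dep = n_off + 1;
  IntegerMatrix P(n_levels, max_dep);
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    const int lev = levels[idx3(i, j, k, nx, ny)];
    if (lev == 0) continue;
    int dep = 1;  // the centre voxel always depends on itself
    for (int o = 0; o < n_off; ++o) {
      const int pi = i + OFF26[o][0], pj = j + OFF26[o][1], pk = k + OFF26[o][2];
      if (pi < 0 || pi >= nx || pj < 0 || pj >= ny || pk < 0 || pk >= nz) continue;
      const int plev = levels[idx3(pi, pj, pk, nx, ny)];
      if (plev != 0 && std::abs((double)plev - (double)lev) <= alpha) ++dep;
    }
    P(lev - 1, dep - 1) += 1;
  }
  return P;
}

// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector levels, IntegerVector dims, int n_levels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector n_i(n_levels);
  NumericVector s_i(n_levels);
  for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    const int lev = levels[idx3(i, j, k, nx, ny)];
    if (lev == 0) continue;
    double sum = 0.0; int cnt = 0;
    for (int o = 0; o < 26; ++o) {
      const int pi = i + OFF26[o][0], pj = j + OFF26[o][1], pk = k + OFF26[o][2];
      if (pi < 0 || pi >= nx || pj < 0 || pj >= ny || pk < 0 || pk >= nz) continue;
      const int plev = levels[idx3(pi, pj, pk, nx, ny)];
      if (plev != 0) { sum += plev; ++cnt; }
    }
    n_i[lev - 1] += 1;
    if (cnt > 0) s_i[lev - 1] += std::fabs((double)lev - sum / cnt);
  }
  return List::create(_["n_i"] = n_i, _["s_i"] = s_i);
}

// Symmetric co-occurrence counts along each of the 13 directions (each
// unordered voxel pair contributes to both (i,j) and (j,i)).
// [[Rcpp::export]]
IntegerVector cpp_glcm(IntegerVector levels, IntegerVector dims, int n_levels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector P(n_levels * n_levels * 13);
  for (int d = 0; d < 13; ++d) {
    const int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    const int base = d * n_levels * n_levels;
    for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
      const int lev = levels[idx3(i, j, k, nx, ny)];
      if (lev == 0) continue;
      const int pi = i + dx, pj = j + dy, pk = k + dz;
      if (pi < 0 || pi >= nx || pj < 0 || pj >= ny || pk < 0 || pk >= nz) continue;
      const int plev = levels[idx3(pi, pj, pk, nx, ny)];
      if (plev == 0) continue;
      P[base + (lev - 1) + n_levels * (plev - 1)] += 1;
      P[base + (plev - 1) + n_levels * (lev - 1)] += 1;
    }
  }
  P.attr("dim") = IntegerVector::create(n_levels, n_levels, 13);
  return P;
}

// Run-length counts per direction: a run is a maximal straight segment of
// in-ROI voxels sharing one level; out-of-ROI voxels break runs.
// [[Rcpp::export]]
IntegerVector cpp_glrlm(IntegerVector levels, IntegerVector dims, int n_levels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int max_run = std::max(std::max(nx, ny), nz);
  IntegerVector P(n_levels * max_run * 13);
  for (int d = 0; d < 13; ++d) {
    const int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    const int base = d * n_levels * max_run;
    for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
      const int lev = levels[idx3(i, j, k, nx, ny)];
      if (lev == 0) continue;
      // only start a walk where the run begins
      const int qi = i - dx, qj = j - dy, qk = k - dz;
      if (qi >= 0 && qi < nx && qj >= 0 && qj < ny && qk >= 0 && qk < nz &&
          levels[idx3(qi, qj, qk, nx, ny)] == lev) continue;
      int len = 1;
      int pi = i + dx, pj = j + dy, pk = k + dz;
      while (pi >= 0 && pi < nx && pj >= 0 && pj < ny && pk >= 0 && pk < nz &&
             levels[idx3(pi, pj, pk, nx, ny)] == lev) {
        ++len; pi += dx; pj += dy; pk += dz;
      }
      P[base + (lev - 1) + n_levels * (len - 1)] += 1;
    }
  }
  P.attr("dim") = IntegerVector::create(n_levels, max_run, 13);
  return P;
}

// Resampling onto an isotropic grid.  Input voxel centres sit at physical
// position index * spacing per axis; the output grid samples positions
// index * target, so the physical extent is preserved to within one voxel.
// [[Rcpp::export]]
List cpp_resample_trilinear(NumericVector vol, IntegerVector dims,
                            NumericVector spacing, double target) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int mx = (int)std::floor((nx - 1) * spacing[0] / target + 1e-9) + 1;
  int my = (int)std::floor((ny - 1) * spacing[1] / target + 1e-9) + 1;
  int mz = (int)std::floor((nz - 1) * spacing[2] / target + 1e-9) + 1;
  NumericVector out((R_xlen_t)mx * my * mz);
  for (int k = 0; k < mz; ++k) {
    double w = k * target / spacing[2];
    int k0 = (int)std::floor(w); if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
    double fz = w - k0; if (fz < 0) fz = 0; if (fz > 1) fz = 1;
    for (int j = 0; j < my; ++j) {
      double v = j * target / spacing[1];
      int j0 = (int)std::floor(v); if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
      double fy = v - j0; if (fy < 0) fy = 0; if (fy > 1) fy = 1;
      for (int i = 0; i < mx; ++i) {
        double u = i * target / spacing[0];
        int i0 = (int)std::floor(u); if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
        double fx = u - i0; if (fx < 0) fx = 0; if (fx > 1) fx = 1;
        const double c000 = vol[idx3(i0,     j0,     k0,     nx, ny)];
        const double c100 = vol[idx3(i0 + 1, j0,     k0,     nx, ny)];
        const double c010 = vol[idx3(i0,     j0 + 1, k0,     nx, ny)];
        const double c110 = vol[idx3(i0 + 1, j0 + 1, k0,     nx, ny)];
        const double c001 = vol[idx3(i0,     j0,     k0 + 1, nx, ny)];
        const double c101 = vol[idx3(i0 + 1, j0,     k0 + 1, nx, ny)];
        const double c011 = vol[idx3(i0,     j0 + 1, k0 + 1, nx, ny)];
        const double c111 = vol[idx3(i0 + 1, j0 + 1, k0 + 1, nx, ny)];
        const double c00 = c000 * (1 - fx) + c100 * fx;
        const double c10 = c010 * (1 - fx) + c110 * fx;
        const double c01 = c001 * (1 - fx) + c101 * fx;
        const double c11 = c011 * (1 - fx) + c111 * fx;
        out[idx3(i, j, k, mx, my)] =
          (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz;
      }
    }
  }
  return List::create(_["values"] = out,
                      _["dim"] = IntegerVector::create(mx, my, mz));
}

// [[Rcpp::export]]
List cpp_resample_nearest(IntegerVector vol, IntegerVector dims,
                          NumericVector spacing, double target) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int mx = (int)std::floor((nx - 1) * spacing[0] / target + 1e-9) + 1;
  int my = (int)std::floor((ny - 1) * spacing[1] / target + 1e-9) + 1;
  int mz = (int)std::floor((nz - 1) * spacing[2] / target + 1e-9) + 1;
  IntegerVector out((R_xlen_t)mx * my * mz);
  for (int k = 0; k < mz; ++k) {
    int k0 = (int)std::floor(k * target / spacing[2] + 0.5);
    if (k0 > nz - 1) k0 = nz - 1;
    for (int j = 0; j < my; ++j) {
      int j0 = (int)std::floor(j * target / spacing[1] + 0.5);
      if (j0 > ny - 1) j0 = ny - 1;
      for (int i = 0; i < mx; ++i) {
        int i0 = (int)std::floor(i * target / spacing[0] + 0.5);
        if (i0 > nx - 1) i0 = nx - 1;
        out[idx3(i, j, k, mx, my)] = vol[idx3(i0, j0, k0, nx, ny)];
      }
    }
  }
  return List::create(_["values"] = out,
                      _["dim"] = IntegerVector::create(mx, my, mz));
}

// Binary erosion; voxels beyond the array border count as background.
// [[Rcpp::export]]
IntegerVector cpp_erode(IntegerVector mask, IntegerVector dims,
                        bool conn26, int iterations) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n_off = conn26 ? 26 : 6;
  IntegerVector cur = clone(mask);
  for (int it = 0; it < iterations; ++it) {
    IntegerVector nxt(cur.size());
    for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
      const int v = idx3(i, j, k, nx, ny);
      if (cur[v] == 0) continue;
      bool keep = true;
      for (int o = 0; o < n_off && keep; ++o) {
        const int pi = i + OFF26[o][0], pj = j + OFF26[o][1], pk = k + OFF26[o][2];
        if (pi < 0 || pi >= nx || pj < 0 || pj >= ny || pk < 0 || pk >= nz ||
            cur[idx3(pi, pj, pk, nx, ny)] == 0) keep = false;
      }
      if (keep) nxt[v] = 1;
    }
    cur = nxt;
  }
  cur.attr("dim") = dims;
  return cur;
}
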