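#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Separable squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher lower-envelope-of-parabolas, O(n) per line).
// Sites are TRUE voxels; the result is the squared distance, in voxel units,
// from every voxel to its nearest site. Voxels outside the array are treated
// as non-sites, so borders behave as "no information" rather than background.

static const double DT_INF = 1e30;

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_squared_cpp")]]
NumericVector edt_squared_cpp(LogicalVector sites, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sites.size() != n) stop("dim does not match length of sites");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (sites[i] == TRUE) ? 0.0 : DT_INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, nx);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, v, z, ny);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = out[base + nxy * k];
      dt1d(f, d, v, z, nz);
      for (int k = 0; k < nz; ++k) out[base + nxy * k] = d[k];
    }
  return out;
}

// Connected-component labeling of a 3D logical array with 6- or
// 26-connectivity, via an explicit-stack flood fill. Labels are 1..n in
// order of first (column-major) encounter.

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("dim does not match length of mask");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  IntegerVector lab(n, 0);
  std::vector<int> di, dj, dk;
  for (int ck = -1; ck <= 1; ++ck)
    for (int cj = -1; cj <= 1; ++cj)
      for (int ci = -1; ci <= 1; ++ci) {
        if (ci == 0 && cj == 0 && ck == 0) continue;
        int manh = std::abs(ci) + std::abs(cj) + std::abs(ck);
        if (connectivity == 6 && manh != 1) continue;
        di.push_back(ci); dj.push_back(cj); dk.push_back(ck);
      }
  const int nnb = (int)di.size();
  const R_xlen_t nxy = (R_xlen_t)nx * ny;

  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] != TRUE || lab[s] != 0) continue;
    ++next_label;
    lab[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int k = (int)(cur / nxy);
      R_xlen_t rem = cur - (R_xlen_t)k * nxy;
      int j = (int)(rem / nx);
      int i = (int)(rem - (R_xlen_t)j * nx);
      for (int b = 0; b < nnb; ++b) {
        int ii = i + di[b], jj = j + dj[b], kk = k + dk[b];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t q = ii + (R_xlen_t)nx * jj + nxy * kk;
        if (mask[q] == TRUE && lab[q] == 0) {
          lab[q] = next_label;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}
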