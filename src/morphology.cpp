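#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
#include <cmath>

using namespace Rcpp;

// 1D squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// with grid step `h` so anisotropic voxels are handled per axis.
static void edt1d(const std::vector<double>& f, std::vector<double>& d,
                  double h, std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
      if (s > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) to the nearest nonzero voxel of `mask`.
// mask: integer array with dim (nz, ny, nx); spacing: (dz, dy, dx) in mm.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(IntegerVector mask, NumericVector spacing) {
  IntegerVector dims = mask.attr("dim");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const double INF = 1e30;
  NumericVector out(mask.size());
  out.attr("dim") = dims;

  std::vector<double> f, d;
  std::vector<int> v;
  std::vector<double> z;
  int nmax = std::max(nz, std::max(ny, nx));
  f.resize(nmax); d.resize(nmax); v.resize(nmax); z.resize(nmax + 1);

  // init: 0 at foreground, INF elsewhere
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = mask[i] != 0 ? 0.0 : INF;

  // pass along z (fastest-varying index)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)x * nz * ny + (R_xlen_t)y * nz;
      for (int q = 0; q < nz; ++q) f[q] = out[base + q];
      f.resize(nz); d.resize(nz);
      edt1d(f, d, dz, v, z);
      for (int q = 0; q < nz; ++q) out[base + q] = d[q];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int q0 = 0; q0 < nz; ++q0) {
      R_xlen_t base = (R_xlen_t)x * nz * ny + q0;
      for (int q = 0; q < ny; ++q) f[q] = out[base + (R_xlen_t)q * nz];
      f.resize(ny); d.resize(ny);
      edt1d(f, d, dy, v, z);
      for (int q = 0; q < ny; ++q) out[base + (R_xlen_t)q * nz] = d[q];
      f.resize(nmax); d.resize(nmax);
    }
  // pass along x
  for (int y = 0; y < ny; ++y)
    for (int q0 = 0; q0 < nz; ++q0) {
      R_xlen_t base = (R_xlen_t)y * nz + q0;
      for (int q = 0; q < nx; ++q) f[q] = out[base + (R_xlen_t)q * nz * ny];
      f.resize(nx); d.resize(nx);
      edt1d(f, d, dx, v, z);
      for (int q = 0; q < nx; ++q) out[base + (R_xlen_t)q * nz * ny] = d[q];
      f.resize(nmax); d.resize(nmax);
    }
  return out;
}

// 26-connected labelling of the nonzero voxels of a 3D array (8-connected
// when nz == 1, i.e. a single slice). Labels are assigned in first-voxel
// (column-major) order, so ties between equal-sized components are broken
// deterministically by label order.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(IntegerVector mask) {
  IntegerVector dims = mask.attr("dim");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector lab(mask.size());
  lab.attr("dim") = dims;
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int x = (int)(cur / ((R_xlen_t)nz * ny));
      int rem = (int)(cur % ((R_xlen_t)nz * ny));
      int y = rem / nz;
      int zc = rem % nz;
      for (int ddx = -1; ddx <= 1; ++ddx)
        for (int ddy = -1; ddy <= 1; ++ddy)
          for (int ddz = -1; ddz <= 1; ++ddz) {
            if (!ddx && !ddy && !ddz) continue;
            int xx = x + ddx, yy = y + ddy, zz = zc + ddz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            R_xlen_t ni = (R_xlen_t)xx * nz * ny + (R_xlen_t)yy * nz + zz;
            if (mask[ni] != 0 && lab[ni] == 0) {
              lab[ni] = next;
              q.push(ni);
            }
          }
    }
  }
  return lab;
}
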