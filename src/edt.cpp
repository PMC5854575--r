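#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas), separable per axis, honouring anisotropic voxel
// spacing. Input f holds 0 at seed voxels and +Inf elsewhere; output is the
// squared distance to the nearest seed.

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double s) {
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double sint;
    while (true) {
      int p = v[k];
      sint = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (sint <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = sint; z[k + 1] = INF;
  }
  if (f[v[0]] == INF) {   // no seed in this scan line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double dq = s * (q - v[kk]);
    d[q] = dq * dq + f[v[kk]];
  }
}

// mask: (z, y, x) logical array of seed voxels; spacing: (dz, dy, dx) um.
// Returns Euclidean distance (um) from every voxel centre to the nearest
// seed voxel centre; +Inf if the mask is empty.
// [[Rcpp::export]]
NumericVector edt_3d(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along z (first index, fastest varying)
  f.resize(nz); d.resize(nz);
  for (int k = 0; k < nx; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nz * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nz; ++i) f[i] = out[base + i];
      dt1d(f, d, nz, spacing[0]);
      for (int i = 0; i < nz; ++i) out[base + i] = d[i];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nx; ++k)
    for (int i = 0; i < nz; ++i) {
      R_xlen_t base = i + (R_xlen_t)nz * ny * (R_xlen_t)k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nz * j];
      dt1d(f, d, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nz * j] = d[j];
    }
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nz; ++i) {
      R_xlen_t base = i + (R_xlen_t)nz * j;
      for (int k = 0; k < nx; ++k) f[k] = out[base + (R_xlen_t)nz * ny * (R_xlen_t)k];
      dt1d(f, d, nx, spacing[2]);
      for (int k = 0; k < nx; ++k) out[base + (R_xlen_t)nz * ny * (R_xlen_t)k] = d[k];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (out[i] == INF) ? INF : std::sqrt(out[i]);
  return out;
}
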