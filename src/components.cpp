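#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling on a (z, y, x) logical array.
// connectivity: 6 (faces) or 26 (faces + edges + corners).
// Labels are assigned in raster-scan order; callers wanting a different
// deterministic ordering (e.g. by centroid) relabel afterwards.
// [[Rcpp::export]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  // neighbour offsets in (dz, dy, dx)
  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && std::abs(a) + std::abs(b) + std::abs(c) != 1) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const int nn = (int)dz.size();

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int k = (int)(v / ((R_xlen_t)nz * ny));
      int rem = (int)(v % ((R_xlen_t)nz * ny));
      int j = rem / nz;
      int i = rem % nz;
      for (int t = 0; t < nn; ++t) {
        int ii = i + dz[t], jj = j + dy[t], kk = k + dx[t];
        if (ii < 0 || ii >= nz || jj < 0 || jj >= ny || kk < 0 || kk >= nx) continue;
        R_xlen_t w = ii + (R_xlen_t)nz * (jj + (R_xlen_t)ny * kk);
        if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}
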