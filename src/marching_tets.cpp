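#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra: each cell of the voxel grid
// is split into 6 tetrahedra around the main diagonal (the same split for
// every cell, so face diagonals agree between neighbouring cells). Within a
// tetrahedron the surface cases are unambiguous, so the resulting mesh of a
// level set that does not touch the volume border is a closed 2-manifold.
// Grid values live at voxel centres; physical coords are 0-based index *
// spacing. "Inside" means value > iso (strict).

struct MTState {
  std::unordered_map<unsigned long long, int> edge_vert;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
};

static inline int edge_vertex(MTState& st, unsigned long long n_total,
                              R_xlen_t ida, R_xlen_t idb,
                              double va, double vb,
                              const double* pa, const double* pb,
                              double iso) {
  if (ida > idb) { std::swap(ida, idb); std::swap(va, vb); std::swap(pa, pb); }
  unsigned long long key = (unsigned long long)ida * n_total + (unsigned long long)idb;
  auto it = st.edge_vert.find(key);
  if (it != st.edge_vert.end()) return it->second;
  double t = (iso - va) / (vb - va);
  st.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  st.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  st.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  int idx = (int)st.vx.size();  // 1-based
  st.edge_vert[key] = idx;
  return idx;
}

static inline void add_tri(MTState& st, int a, int b, int c,
                           const double in_cent[3]) {
  if (a == b || b == c || a == c) return;
  const double* p0 = NULL;
  // fetch positions (1-based indices)
  double A[3] = { st.vx[a - 1], st.vy[a - 1], st.vz[a - 1] };
  double B[3] = { st.vx[b - 1], st.vy[b - 1], st.vz[b - 1] };
  double C[3] = { st.vx[c - 1], st.vy[c - 1], st.vz[c - 1] };
  (void)p0;
  double u[3] = { B[0] - A[0], B[1] - A[1], B[2] - A[2] };
  double v[3] = { C[0] - A[0], C[1] - A[1], C[2] - A[2] };
  double nvec[3] = { u[1] * v[2] - u[2] * v[1],
                     u[2] * v[0] - u[0] * v[2],
                     u[0] * v[1] - u[1] * v[0] };
  double cent[3] = { (A[0] + B[0] + C[0]) / 3.0,
                     (A[1] + B[1] + C[1]) / 3.0,
                     (A[2] + B[2] + C[2]) / 3.0 };
  double ref[3] = { in_cent[0] - cent[0], in_cent[1] - cent[1], in_cent[2] - cent[2] };
  double dp = nvec[0] * ref[0] + nvec[1] * ref[1] + nvec[2] * ref[2];
  if (dp > 0) std::swap(b, c);  // outward normal: away from the inside corners
  st.tri.push_back(a); st.tri.push_back(b); st.tri.push_back(c);
}

// vol: (z, y, x) numeric array; spacing: (dz, dy, dx) um.
// Returns vertices (n x 3, columns x,y,z in um) and 1-based faces (m x 3).
// [[Rcpp::export]]
List marching_tetrahedra(NumericVector vol, IntegerVector dims,
                         NumericVector spacing, double iso) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const unsigned long long n_total = (unsigned long long)nz * ny * nx;

  // cube corner offsets in (ox, oy, oz); main diagonal corner0 -> corner6
  static const int CO[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
  };
  static const int TETS[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}
  };

  MTState st;
  double pos[8][3];
  double val[8];
  R_xlen_t pid[8];

  for (int k = 0; k < nx - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nz - 1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int cx = k + CO[c][0], cy = j + CO[c][1], cz = i + CO[c][2];
          R_xlen_t id = cz + (R_xlen_t)nz * (cy + (R_xlen_t)ny * cx);
          pid[c] = id;
          val[c] = vol[id];
          pos[c][0] = cx * sx; pos[c][1] = cy * sy; pos[c][2] = cz * sz;
          if (val[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int ins[4], nin = 0, outs[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (val[T[c]] > iso) ins[nin++] = T[c]; else outs[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          double in_cent[3] = {0, 0, 0};
          for (int c = 0; c < nin; ++c)
            for (int d = 0; d < 3; ++d) in_cent[d] += pos[ins[c]][d] / nin;
          if (nin == 1 || nin == 3) {
            int a = (nin == 1) ? ins[0] : outs[0];
            int o1, o2, o3;
            if (nin == 1) { o1 = outs[0]; o2 = outs[1]; o3 = outs[2]; }
            else          { o1 = ins[0];  o2 = ins[1];  o3 = ins[2]; }
            int e1 = edge_vertex(st, n_total, pid[a], pid[o1], val[a], val[o1], pos[a], pos[o1], iso);
            int e2 = edge_vertex(st, n_total, pid[a], pid[o2], val[a], val[o2], pos[a], pos[o2], iso);
            int e3 = edge_vertex(st, n_total, pid[a], pid[o3], val[a], val[o3], pos[a], pos[o3], iso);
            add_tri(st, e1, e2, e3, in_cent);
          } else {  // 2 in, 2 out -> quad
            int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
            int q0 = edge_vertex(st, n_total, pid[a], pid[c], val[a], val[c], pos[a], pos[c], iso);
            int q1 = edge_vertex(st, n_total, pid[a], pid[d], val[a], val[d], pos[a], pos[d], iso);
            int q2 = edge_vertex(st, n_total, pid[b], pid[d], val[b], val[d], pos[b], pos[d], iso);
            int q3 = edge_vertex(st, n_total, pid[b], pid[c], val[b], val[c], pos[b], pos[c], iso);
            add_tri(st, q0, q1, q2, in_cent);
            add_tri(st, q0, q2, q3, in_cent);
          }
        }
      }

  int nv = (int)st.vx.size();
  int nf = (int)st.tri.size() / 3;
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = st.vx[i]; verts(i, 1) = st.vy[i]; verts(i, 2) = st.vz[i];
  }
  IntegerMatrix faces(nf, 3);
  for (int i = 0; i < nf; ++i) {
    faces(i, 0) = st.tri[3 * i];
    faces(i, 1) = st.tri[3 * i + 1];
    faces(i, 2) = st.tri[3 * i + 2];
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
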