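// Low-level 3D voxel kernels shared by the pipeline stages.
// Arrays arrive in R column-major order, dims = (nx, ny, nz), z = slice axis.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline R_xlen_t lin_idx(int x, int y, int z, const int* d) {
  return (R_xlen_t)x + (R_xlen_t)d[0] * ((R_xlen_t)y + (R_xlen_t)d[1] * (R_xlen_t)z);
}

// ---------------------------------------------------------------------------
// Separable 1D correlation along one axis.
// mode 0: replicate edges (smoothing, derivatives); mode 1: zero padding.
// Kernel is applied as a sliding inner product centred on each voxel.
// [[Rcpp::export]]
NumericVector conv1d_axis_cpp(NumericVector x, IntegerVector dim,
                              NumericVector kernel, int axis, int mode) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const int n = d[axis];
  const int klen = kernel.size();
  const int kr = (klen - 1) / 2;
  NumericVector out(x.size());

  // strides for walking a line along `axis` and enumerating the other axes
  R_xlen_t stride[3] = {1, (R_xlen_t)d[0], (R_xlen_t)d[0] * d[1]};
  int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  std::vector<double> line(n), res(n);

  for (int j2 = 0; j2 < d[a2]; ++j2) {
    for (int j1 = 0; j1 < d[a1]; ++j1) {
      R_xlen_t base = stride[a1] * j1 + stride[a2] * j2;
      for (int i = 0; i < n; ++i) line[i] = x[base + stride[axis] * i];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int k = 0; k < klen; ++k) {
          int p = i + k - kr;
          double v;
          if (p < 0)       v = (mode == 0) ? line[0] : 0.0;
          else if (p >= n) v = (mode == 0) ? line[n - 1] : 0.0;
          else             v = line[p];
          acc += kernel[k] * v;
        }
        res[i] = acc;
      }
      for (int i = 0; i < n; ++i) out[base + stride[axis] * i] = res[i];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected component labeling. Returns integer labels, 0 = background,
// components numbered 1..k in raster order of their first voxel.
// [[Rcpp::export]]
IntegerVector cc_label_26_cpp(LogicalVector mask, IntegerVector dim) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        R_xlen_t i = lin_idx(x, y, z, d);
        if (!mask[i] || lab[i]) continue;
        lab[i] = ++next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t cur = stack.back(); stack.pop_back();
          int cx = cur % d[0];
          int cy = (cur / d[0]) % d[1];
          int cz = cur / ((R_xlen_t)d[0] * d[1]);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int nx = cx + dx, ny = cy + dy, nz = cz + dz;
                if (nx < 0 || ny < 0 || nz < 0 ||
                    nx >= d[0] || ny >= d[1] || nz >= d[2]) continue;
                R_xlen_t ni = lin_idx(nx, ny, nz, d);
                if (mask[ni] && !lab[ni]) {
                  lab[ni] = next;
                  stack.push_back(ni);
                }
              }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// 3D hole filling: flood the background 6-connectedly from the volume faces;
// unreached background voxels are interior holes and become foreground.
// [[Rcpp::export]]
LogicalVector fill_holes_cpp(LogicalVector mask, IntegerVector dim) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  std::vector<char> outside(mask.size(), 0);
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        if (x > 0 && x < d[0] - 1 && y > 0 && y < d[1] - 1 &&
            z > 0 && z < d[2] - 1) continue;
        R_xlen_t i = lin_idx(x, y, z, d);
        if (!mask[i] && !outside[i]) { outside[i] = 1; stack.push_back(i); }
      }
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!stack.empty()) {
    R_xlen_t cur = stack.back(); stack.pop_back();
    int cx = cur % d[0];
    int cy = (cur / d[0]) % d[1];
    int cz = cur / ((R_xlen_t)d[0] * d[1]);
    for (int k = 0; k < 6; ++k) {
      int nx = cx + off[k][0], ny = cy + off[k][1], nz = cz + off[k][2];
      if (nx < 0 || ny < 0 || nz < 0 ||
          nx >= d[0] || ny >= d[1] || nz >= d[2]) continue;
      R_xlen_t ni = lin_idx(nx, ny, nz, d);
      if (!mask[ni] && !outside[ni]) { outside[ni] = 1; stack.push_back(ni); }
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = mask[i] || !outside[i];
  return out;
}

// ---------------------------------------------------------------------------
// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// anisotropic: sample positions along each axis are spaced `spacing` apart.
// Input: logical feature mask; output: squared distance (in spacing units)
// from every voxel to the nearest feature voxel. All-false mask -> +Inf.
static const double DT_BIG = 1e30;  // finite stand-in for "no feature"

static void dt1d(const std::vector<double>& f, std::vector<double>& dout,
                 int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double s2 = s * s;
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY; z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double sint;
    while (true) {
      int p = v[k];
      sint = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) /
             (2.0 * s2 * (q - p));
      if (k > 0 && sint <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = INFINITY;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double dq = s * (q - v[kk]);
    dout[q] = dq * dq + f[v[kk]];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = mask[i] ? 0.0 : DT_BIG;
  R_xlen_t stride[3] = {1, (R_xlen_t)d[0], (R_xlen_t)d[0] * d[1]};
  for (int axis = 0; axis < 3; ++axis) {
    int n = d[axis];
    int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
    std::vector<double> line(n), res(n);
    for (int j2 = 0; j2 < d[a2]; ++j2)
      for (int j1 = 0; j1 < d[a1]; ++j1) {
        R_xlen_t base = stride[a1] * j1 + stride[a2] * j2;
        bool any_feature = false;
        for (int i = 0; i < n; ++i) {
          line[i] = out[base + stride[axis] * i];
          if (line[i] < DT_BIG) any_feature = true;
        }
        if (!any_feature) continue;
        dt1d(line, res, n, spacing[axis]);
        for (int i = 0; i < n; ++i) out[base + stride[axis] * i] = res[i];
      }
  }
  for (R_xlen_t i = 0; i < out.size(); ++i)
    if (out[i] >= DT_BIG) out[i] = R_PosInf;
  return out;
}

// ---------------------------------------------------------------------------
// Topology-preserving sequential 3D thinning (26-connected foreground,
// 6-connected background). A border voxel is deleted when it is a simple
// point (Malandain-Bertrand characterization) and not a curve endpoint.
// Six directional sub-iterations with raster-order sequential deletion give
// a deterministic, roughly medial curve skeleton.

// neighborhood cell index: (dx+1) + 3*(dy+1) + 9*(dz+1); centre = 13
static void get_neighborhood(const LogicalVector& m, const int* d,
                             int x, int y, int z, bool nb[27]) {
  int c = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++c) {
        int nx = x + dx, ny = y + dy, nz = z + dz;
        if (nx < 0 || ny < 0 || nz < 0 ||
            nx >= d[0] || ny >= d[1] || nz >= d[2]) { nb[c] = false; continue; }
        nb[c] = m[lin_idx(nx, ny, nz, d)];
      }
}

static inline void cell_xyz(int c, int& dx, int& dy, int& dz) {
  dx = c % 3 - 1; dy = (c / 3) % 3 - 1; dz = c / 9 - 1;
}

// number of 26-components of the foreground 26-neighborhood (centre excluded)
static int t26_object(const bool nb[27]) {
  int comp = 0;
  bool seen[27] = {false};
  for (int c = 0; c < 27; ++c) {
    if (c == 13 || !nb[c] || seen[c]) continue;
    ++comp;
    std::vector<int> st(1, c);
    seen[c] = true;
    while (!st.empty()) {
      int cur = st.back(); st.pop_back();
      int cx, cy, cz; cell_xyz(cur, cx, cy, cz);
      for (int o = 0; o < 27; ++o) {
        if (o == 13 || !nb[o] || seen[o]) continue;
        int ox, oy, oz; cell_xyz(o, ox, oy, oz);
        if (std::abs(ox - cx) <= 1 && std::abs(oy - cy) <= 1 &&
            std::abs(oz - cz) <= 1) { seen[o] = true; st.push_back(o); }
      }
    }
  }
  return comp;
}

// number of 6-components of the background 18-neighborhood 6-adjacent to the
// centre (corner cells excluded; adjacency = face adjacency between cells)
static int t6_background(const bool nb[27]) {
  bool in18[27];
  for (int c = 0; c < 27; ++c) {
    int dx, dy, dz; cell_xyz(c, dx, dy, dz);
    int nnz = (dx != 0) + (dy != 0) + (dz != 0);
    in18[c] = (c != 13) && (nnz <= 2);
  }
  int comp = 0;
  bool seen[27] = {false};
  for (int c = 0; c < 27; ++c) {
    if (!in18[c] || nb[c] || seen[c]) continue;
    int dx, dy, dz; cell_xyz(c, dx, dy, dz);
    bool touches_face = ((dx != 0) + (dy != 0) + (dz != 0)) == 1;
    std::vector<int> st(1, c);
    seen[c] = true;
    while (!st.empty()) {
      int cur = st.back(); st.pop_back();
      int cx, cy, cz; cell_xyz(cur, cx, cy, cz);
      if (((cx != 0) + (cy != 0) + (cz != 0)) == 1) touches_face = true;
      for (int o = 0; o < 27; ++o) {
        if (!in18[o] || nb[o] || seen[o]) continue;
        int ox, oy, oz; cell_xyz(o, ox, oy, oz);
        int man = std::abs(ox - cx) + std::abs(oy - cy) + std::abs(oz - cz);
        if (man == 1) { seen[o] = true; st.push_back(o); }
      }
    }
    if (touches_face) ++comp;
  }
  return comp;
}

static inline int count_fg(const bool nb[27]) {
  int n = 0;
  for (int c = 0; c < 27; ++c) if (c != 13 && nb[c]) ++n;
  return n;
}

static inline bool is_simple(const bool nb[27]) {
  return t26_object(nb) == 1 && t6_background(nb) == 1;
}

// [[Rcpp::export]]
LogicalVector thin_3d_cpp(LogicalVector mask, IntegerVector dim) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  LogicalVector m = clone(mask);
  // direction order: -z, +z, -y, +y, -x, +x (cell offsets into the 27-box)
  const int dir_off[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},
                             {-1,0,0},{1,0,0}};
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      int doff = (dir_off[dir][0] + 1) + 3 * (dir_off[dir][1] + 1) +
                 9 * (dir_off[dir][2] + 1);
      std::vector<R_xlen_t> cand;
      for (int z = 0; z < d[2]; ++z)
        for (int y = 0; y < d[1]; ++y)
          for (int x = 0; x < d[0]; ++x) {
            R_xlen_t i = lin_idx(x, y, z, d);
            if (!m[i]) continue;
            get_neighborhood(m, d, x, y, z, nb);
            if (nb[doff]) continue;              // not a border voxel this way
            if (count_fg(nb) <= 1) continue;     // curve endpoint: keep
            if (is_simple(nb)) cand.push_back(i);
          }
      // sequential deletion with re-check preserves topology exactly
      for (R_xlen_t ci = 0; ci < (R_xlen_t)cand.size(); ++ci) {
        R_xlen_t i = cand[ci];
        int x = i % d[0];
        int y = (i / d[0]) % d[1];
        int z = i / ((R_xlen_t)d[0] * d[1]);
        get_neighborhood(m, d, x, y, z, nb);
        if (nb[doff]) continue;
        if (count_fg(nb) <= 1) continue;
        if (!is_simple(nb)) continue;
        m[i] = false;
        changed = true;
      }
    }
  }
  return m;
}

// ---------------------------------------------------------------------------
// Batch eigenvalues of symmetric 3x3 matrices (analytic, trigonometric),
// returned sorted by increasing absolute value (|l1| <= |l2| <= |l3|).
// [[Rcpp::export]]
NumericMatrix eig_sym3_cpp(NumericVector xx, NumericVector yy, NumericVector zz,
                           NumericVector xy, NumericVector xz, NumericVector yz) {
  R_xlen_t n = xx.size();
  NumericMatrix out(n, 3);
  for (R_xlen_t i = 0; i < n; ++i) {
    double a = xx[i], b = yy[i], c = zz[i];
    double de = xy[i], f = yz[i], g = xz[i];
    double e1, e2, e3;
    double p1 = de * de + g * g + f * f;
    if (p1 == 0.0) {
      e1 = a; e2 = b; e3 = c;
    } else {
      double q = (a + b + c) / 3.0;
      double p2 = (a - q) * (a - q) + (b - q) * (b - q) + (c - q) * (c - q) +
                  2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      // r = det(B)/2 with B = (A - qI)/p
      double b11 = (a - q) / p, b22 = (b - q) / p, b33 = (c - q) / p;
      double b12 = de / p, b13 = g / p, b23 = f / p;
      double detB = b11 * (b22 * b33 - b23 * b23) -
                    b12 * (b12 * b33 - b23 * b13) +
                    b13 * (b12 * b23 - b22 * b13);
      double r = detB / 2.0;
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      double phi = std::acos(r) / 3.0;
      e1 = q + 2.0 * p * std::cos(phi);
      e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      e2 = 3.0 * q - e1 - e3;
    }
    double v[3] = {e1, e2, e3};
    // sort by |.| ascending (3 elements: explicit network)
    if (std::fabs(v[0]) > std::fabs(v[1])) std::swap(v[0], v[1]);
    if (std::fabs(v[1]) > std::fabs(v[2])) std::swap(v[1], v[2]);
    if (std::fabs(v[0]) > std::fabs(v[1])) std::swap(v[0], v[1]);
    out(i, 0) = v[0]; out(i, 1) = v[1]; out(i, 2) = v[2];
  }
  return out;
}
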