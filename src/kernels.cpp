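#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Voxel arrays come in as R logical/numeric vectors with dim (ny, nx, nz),
// column-major: linear index = y + ny * (x + nx * z), all 0-based here.

static inline int idx3(int y, int x, int z, int ny, int nx) {
  return y + ny * (x + nx * z);
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const int n = ny * nx * nz;
  IntegerVector labels(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int z0 = 0; z0 < nz; ++z0) for (int x0 = 0; x0 < nx; ++x0)
  for (int y0 = 0; y0 < ny; ++y0) {
    int s = idx3(y0, x0, z0, ny, nx);
    if (!mask[s] || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cy = cur % ny, cx = (cur / ny) % nx, cz = cur / (ny * nx);
      for (int dz = -1; dz <= 1; ++dz) for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        int man = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (connectivity == 6 && man > 1) continue;
        int yy = cy + dy, xx = cx + dx, zz = cz + dz;
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        int t = idx3(yy, xx, zz, ny, nx);
        if (mask[t] && labels[t] == 0) {
          labels[t] = next;
          stack.push_back(t);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// ---- 3D topology-preserving thinning ---------------------------------------
// A border voxel may be deleted when it is a "simple point": deletion does not
// change the topology of object (26-adjacency) or background (6-adjacency).
// Characterization (Bertrand & Malandain): p is simple iff
//   (a) exactly one 26-connected component of foreground in N26(p), and
//   (b) exactly one 6-connected component of background in N18(p) that is
//       6-adjacent to p.
// Endpoints (<= 1 foreground 26-neighbour) are preserved so curve extremities
// survive; iteration peels the 6 face directions in turn until stable.

// cube: 27 bools (local 3x3x3, order dy fastest, then dx, then dz; center 13)
static bool simple_point(const bool cube[27]) {
  // (a) foreground components, 26-connectivity, excluding center
  int compFg = 0;
  bool seen[27] = {false};
  seen[13] = true;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !cube[i] || seen[i]) continue;
    ++compFg;
    if (compFg > 1) return false;
    std::vector<int> st; st.push_back(i); seen[i] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cy = c % 3, cx = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; ++dz) for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = cy + dy, xx = cx + dx, zz = cz + dz;
        if (yy < 0 || yy > 2 || xx < 0 || xx > 2 || zz < 0 || zz > 2) continue;
        int t = yy + 3 * xx + 9 * zz;
        if (t == 13 || seen[t] || !cube[t]) continue;
        seen[t] = true; st.push_back(t);
      }
    }
  }
  if (compFg != 1) return false;
  // (b) background components in the 18-neighbourhood, 6-connectivity,
  //     counted only when they touch a face neighbour of the center
  bool in18[27];
  for (int i = 0; i < 27; ++i) {
    int y = i % 3 - 1, x = (i / 3) % 3 - 1, z = i / 9 - 1;
    in18[i] = (std::abs(y) + std::abs(x) + std::abs(z)) <= 2 && i != 13;
  }
  bool seenB[27] = {false};
  int compBg = 0;
  for (int i = 0; i < 27; ++i) {
    int y = i % 3 - 1, x = (i / 3) % 3 - 1, z = i / 9 - 1;
    bool isFace = (std::abs(y) + std::abs(x) + std::abs(z)) == 1;
    if (!isFace || cube[i] || seenB[i]) continue;
    ++compBg;
    if (compBg > 1) return false;
    std::vector<int> st; st.push_back(i); seenB[i] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cy = c % 3, cx = (c / 3) % 3, cz = c / 9;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int yy = cy + d6[k][0], xx = cx + d6[k][1], zz = cz + d6[k][2];
        if (yy < 0 || yy > 2 || xx < 0 || xx > 2 || zz < 0 || zz > 2) continue;
        int t = yy + 3 * xx + 9 * zz;
        if (t == 13 || seenB[t] || !in18[t] || cube[t]) continue;
        seenB[t] = true; st.push_back(t);
      }
    }
  }
  return compBg == 1;
}

static void get_cube(const std::vector<char> &m, int y, int x, int z,
                     int ny, int nx, int nz, bool cube[27]) {
  for (int dz = -1; dz <= 1; ++dz) for (int dx = -1; dx <= 1; ++dx)
  for (int dy = -1; dy <= 1; ++dy) {
    int yy = y + dy, xx = x + dx, zz = z + dz;
    bool v = false;
    if (yy >= 0 && yy < ny && xx >= 0 && xx < nx && zz >= 0 && zz < nz)
      v = m[idx3(yy, xx, zz, ny, nx)] != 0;
    cube[(dy + 1) + 3 * (dx + 1) + 9 * (dz + 1)] = v;
  }
}

static int n26_count(const bool cube[27]) {
  int c = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && cube[i]) ++c;
  return c;
}

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const int n = ny * nx * nz;
  std::vector<char> m(n);
  for (int i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;
  const int dir[6][3] = { // (dy, dx, dz): U, D, N, S, E, W in z/y/x order
    {0,0,1},{0,0,-1},{-1,0,0},{1,0,0},{0,1,0},{0,-1,0}};
  bool changed = true;
  bool cube[27];
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z) for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        int s = idx3(y, x, z, ny, nx);
        if (!m[s]) continue;
        int yy = y + dir[d][0], xx = x + dir[d][1], zz = z + dir[d][2];
        bool borderHere = !(yy >= 0 && yy < ny && xx >= 0 && xx < nx &&
                            zz >= 0 && zz < nz) ||
                          !m[idx3(yy, xx, zz, ny, nx)];
        if (!borderHere) continue;
        get_cube(m, y, x, z, ny, nx, nz, cube);
        if (n26_count(cube) <= 1) continue;       // endpoint: keep
        if (simple_point(cube)) cand.push_back(s);
      }
      // sequential re-check: earlier deletions can invalidate later candidates
      for (size_t k = 0; k < cand.size(); ++k) {
        int s = cand[k];
        int y = s % ny, x = (s / ny) % nx, z = s / (ny * nx);
        get_cube(m, y, x, z, ny, nx, nz, cube);
        if (n26_count(cube) <= 1) continue;
        if (simple_point(cube)) { m[s] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = m[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// Separable Gaussian convolution; kernels truncated at ceil(3.5*sigma) and
// renormalized at the borders so constant images stay constant.
static void conv_axis(std::vector<double> &v, std::vector<double> &tmp,
                      int ny, int nx, int nz, int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.5 * sigma);
  std::vector<double> k(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
  int len = axis == 0 ? ny : (axis == 1 ? nx : nz);
  for (int z = 0; z < nz; ++z) for (int x = 0; x < nx; ++x)
  for (int y = 0; y < ny; ++y) {
    int pos = axis == 0 ? y : (axis == 1 ? x : z);
    double acc = 0, wsum = 0;
    for (int o = -r; o <= r; ++o) {
      int p = pos + o;
      if (p < 0 || p >= len) continue;
      int yy = axis == 0 ? p : y, xx = axis == 1 ? p : x, zz = axis == 2 ? p : z;
      acc += k[o + r] * v[idx3(yy, xx, zz, ny, nx)];
      wsum += k[o + r];
    }
    tmp[idx3(y, x, z, ny, nx)] = acc / wsum;
  }
  v.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector img, IntegerVector dims,
                          double sigma_y, double sigma_x, double sigma_z) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const int n = ny * nx * nz;
  std::vector<double> v(img.begin(), img.end()), tmp(n);
  conv_axis(v, tmp, ny, nx, nz, 0, sigma_y);
  conv_axis(v, tmp, ny, nx, nz, 1, sigma_x);
  conv_axis(v, tmp, ny, nx, nz, 2, sigma_z);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dims;
  return out;
}

// Distance from a point to a segment, anisotropic physical coordinates.
static double pt_seg_d2(double px, double py, double pz,
                        double ax, double ay, double az,
                        double bx, double by, double bz) {
  double vx = bx - ax, vy = by - ay, vz = bz - az;
  double wx = px - ax, wy = py - ay, wz = pz - az;
  double vv = vx * vx + vy * vy + vz * vz;
  double t = vv > 0 ? (wx * vx + wy * vy + wz * vz) / vv : 0.0;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  double dx = wx - t * vx, dy = wy - t * vy, dz = wz - t * vz;
  return dx * dx + dy * dy + dz * dz;
}

// Tube occupancy per voxel. Voxel center of index i along an axis with
// spacing d sits at (i + 0.5) * d. With subsampling (nsub > 1 per axis) the
// returned value is the covered fraction of each voxel (partial-volume
// emulation, what an integrating detector records); with nsub = 1 it is the
// binary center-in-tube indicator. Coverage is accumulated as a maximum over
// the densely resampled segments (consecutive segments are near-collinear,
// so the maximum matches the union).
// [[Rcpp::export]]
NumericVector cpp_tube_fill(IntegerVector dims, NumericVector voxel_size,
                            NumericMatrix polyline, double radius,
                            IntegerVector nsub) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const double dx = voxel_size[0], dy = voxel_size[1], dz = voxel_size[2];
  const int sx = nsub[0], sy = nsub[1], sz = nsub[2];
  NumericVector out(ny * nx * nz, 0.0);
  const double r2 = radius * radius;
  std::vector<double> offx(sx), offy(sy), offz(sz);
  for (int i = 0; i < sx; ++i) offx[i] = ((i + 0.5) / sx - 0.5) * dx;
  for (int i = 0; i < sy; ++i) offy[i] = ((i + 0.5) / sy - 0.5) * dy;
  for (int i = 0; i < sz; ++i) offz[i] = ((i + 0.5) / sz - 0.5) * dz;
  const double pad = radius + 0.5 * std::max(dx, std::max(dy, dz));
  for (int s = 0; s + 1 < polyline.nrow(); ++s) {
    double ax = polyline(s, 0), ay = polyline(s, 1), az = polyline(s, 2);
    double bx = polyline(s + 1, 0), by = polyline(s + 1, 1), bz = polyline(s + 1, 2);
    int x0 = std::max(0, (int)std::floor((std::min(ax, bx) - pad) / dx - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil((std::max(ax, bx) + pad) / dx - 0.5));
    int y0 = std::max(0, (int)std::floor((std::min(ay, by) - pad) / dy - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil((std::max(ay, by) + pad) / dy - 0.5));
    int z0 = std::max(0, (int)std::floor((std::min(az, bz) - pad) / dz - 0.5));
    int z1 = std::min(nz - 1, (int)std::ceil((std::max(az, bz) + pad) / dz - 0.5));
    for (int z = z0; z <= z1; ++z) for (int x = x0; x <= x1; ++x)
    for (int y = y0; y <= y1; ++y) {
      int lin = idx3(y, x, z, ny, nx);
      if (out[lin] >= 1.0) continue;
      double cx = (x + 0.5) * dx, cy = (y + 0.5) * dy, cz = (z + 0.5) * dz;
      int inside = 0;
      for (int iz = 0; iz < sz; ++iz) for (int ix = 0; ix < sx; ++ix)
      for (int iy = 0; iy < sy; ++iy) {
        if (pt_seg_d2(cx + offx[ix], cy + offy[iy], cz + offz[iz],
                      ax, ay, az, bx, by, bz) <= r2) ++inside;
      }
      double cov = (double)inside / (sx * sy * sz);
      if (cov > out[lin]) out[lin] = cov;
    }
  }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
double cpp_max_pairwise(NumericMatrix pts) {
  double best = 0;
  int n = pts.nrow();
  for (int i = 0; i < n; ++i) for (int j = i + 1; j < n; ++j) {
    double dx = pts(i, 0) - pts(j, 0);
    double dy = pts(i, 1) - pts(j, 1);
    double dz = pts(i, 2) - pts(j, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 > best) best = d2;
  }
  return std::sqrt(best);
}
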