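#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 1D squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// grid positions i * s for sample spacing s (mm).
static void dt1d(std::vector<double> &f, int n, double s) {
  if (n == 1) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double sep;
    while (true) {
      double xv = v[k] * s;
      sep = (f[q] + xq * xq - f[v[k]] - xv * xv) / (2.0 * (xq - xv));
      if (sep > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = sep;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest TRUE
// voxel, with per-axis physical spacing.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // large finite sentinel instead of +Inf keeps the parabola intersections
  // well-defined on lines with no foreground voxel
  const double BIG = 1e30;
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = mask[i] ? 0.0 : BIG;
  std::vector<double> line;
  // x pass
  line.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) line[i] = out[base + i];
      dt1d(line, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = line[i];
    }
  // y pass
  line.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) line[j] = out[base + (R_xlen_t)nx * j];
      dt1d(line, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = line[j];
    }
  // z pass
  line.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; ++k) line[k] = out[base + stride * k];
      dt1d(line, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) out[base + stride * k] = line[k];
    }
  return out;
}

// Separable truncated-Gaussian smoothing, reflecting boundaries.
// sigma given in voxels per axis; sigma <= 0 skips that axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector arr, IntegerVector dim,
                               NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector cur = clone(arr);
  int dims[3] = {nx, ny, nz};
  R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int rad = (int)std::ceil(3.0 * s);
    if (rad < 1) rad = 1;
    std::vector<double> w(2 * rad + 1);
    double tot = 0;
    for (int t = -rad; t <= rad; ++t) {
      w[t + rad] = std::exp(-0.5 * t * t / (s * s));
      tot += w[t + rad];
    }
    for (size_t t = 0; t < w.size(); ++t) w[t] /= tot;
    NumericVector nxt(n);
    int m = dims[ax];
    R_xlen_t str = strides[ax];
    // iterate over all lines along axis ax
    int oa = (ax == 0) ? 1 : 0;          // first other axis
    int ob = (ax == 2) ? 1 : 2;          // second other axis
    for (int b = 0; b < dims[ob]; ++b)
      for (int a = 0; a < dims[oa]; ++a) {
        R_xlen_t base = strides[oa] * a + strides[ob] * b;
        for (int p = 0; p < m; ++p) {
          double acc = 0;
          for (int t = -rad; t <= rad; ++t) {
            int q = p + t;
            if (q < 0) q = -q - 1;                 // reflect
            if (q >= m) q = 2 * m - q - 1;
            if (q < 0) q = 0;
            if (q >= m) q = m - 1;
            acc += w[t + rad] * cur[base + str * q];
          }
          nxt[base + str * p] = acc;
        }
      }
    cur = nxt;
  }
  return cur;
}

// Symmetric GLCM counts for one in-plane offset, pooled over transverse
// slices. q holds quantized levels 1..levels inside the mask, 0 outside.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(IntegerVector q, IntegerVector dim, int levels,
                              int dx, int dy) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix counts(levels, levels);
  for (int k = 0; k < nz; ++k) {
    R_xlen_t zoff = (R_xlen_t)nx * ny * k;
    for (int j = 0; j < ny; ++j) {
      int j2 = j + dy;
      if (j2 < 0 || j2 >= ny) continue;
      for (int i = 0; i < nx; ++i) {
        int i2 = i + dx;
        if (i2 < 0 || i2 >= nx) continue;
        int a = q[zoff + (R_xlen_t)nx * j + i];
        if (a == 0) continue;
        int b = q[zoff + (R_xlen_t)nx * j2 + i2];
        if (b == 0) continue;
        counts(a - 1, b - 1) += 1.0;
        counts(b - 1, a - 1) += 1.0;
      }
    }
  }
  return counts;
}

static inline double triArea(const double *p0, const double *p1,
                             const double *p2) {
  double u[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  double v[3] = {p2[0] - p0[0], p2[1] - p0[1], p2[2] - p0[2]};
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Surface area (mm^2) of the iso-surface of a scalar field sampled at voxel
// centers, by marching tetrahedra (6 tetrahedra per cell, linear edge
// interpolation). Caller pads the field so the surface is closed.
// [[Rcpp::export]]
double cpp_mesh_area(NumericVector f, IntegerVector dim,
                     NumericVector spacing, double iso) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  static const int corner[8][3] = {{0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
                                   {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
                                 {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  double area = 0.0;
  double v[8];
  double pos[8][3];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool anyAbove = false, anyBelow = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + corner[c][0], jj = j + corner[c][1],
              kk = k + corner[c][2];
          v[c] = f[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
          pos[c][0] = ii * spacing[0];
          pos[c][1] = jj * spacing[1];
          pos[c][2] = kk * spacing[2];
          if (v[c] >= iso) anyAbove = true; else anyBelow = true;
        }
        if (!anyAbove || !anyBelow) continue;
        for (int t = 0; t < 6; ++t) {
          int idx[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int above[4], below[4];
          int na = 0, nb = 0;
          for (int c = 0; c < 4; ++c) {
            if (v[idx[c]] >= iso) above[na++] = idx[c];
            else below[nb++] = idx[c];
          }
          if (na == 0 || na == 4) continue;
          // edge intersection helper
          double pts[4][3];
          int np = 0;
          if (na == 1 || na == 3) {
            int lone = (na == 1) ? above[0] : below[0];
            int *rest = (na == 1) ? below : above;
            for (int c = 0; c < 3; ++c) {
              double t0 = (iso - v[lone]) / (v[rest[c]] - v[lone]);
              for (int d = 0; d < 3; ++d)
                pts[np][d] =
                    pos[lone][d] + t0 * (pos[rest[c]][d] - pos[lone][d]);
              ++np;
            }
            area += triArea(pts[0], pts[1], pts[2]);
          } else { // 2-2: quad from the four crossing edges
            int pairs[4][2] = {{above[0], below[0]},
                               {above[0], below[1]},
                               {above[1], below[1]},
                               {above[1], below[0]}};
            for (int c = 0; c < 4; ++c) {
              int a = pairs[c][0], b = pairs[c][1];
              double t0 = (iso - v[a]) / (v[b] - v[a]);
              for (int d = 0; d < 3; ++d)
                pts[np][d] = pos[a][d] + t0 * (pos[b][d] - pos[a][d]);
              ++np;
            }
            area += triArea(pts[0], pts[1], pts[2]);
            area += triArea(pts[0], pts[2], pts[3]);
          }
        }
      }
  return area;
}

// Largest 6-connected component of a binary mask.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> label(n, 0);
  int nlab = 0;
  R_xlen_t bestSize = 0;
  int bestLab = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || label[s]) continue;
    ++nlab;
    R_xlen_t size = 0;
    stack.clear();
    stack.push_back(s);
    label[s] = nlab;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      ++size;
      int i = cur % nx;
      int j = (cur / nx) % ny;
      int k = cur / ((R_xlen_t)nx * ny);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t idx = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[idx] && !label[idx]) {
          label[idx] = nlab;
          stack.push_back(idx);
        }
      }
    }
    if (size > bestSize) {
      bestSize = size;
      bestLab = nlab;
    }
  }
  LogicalVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = (label[s] == bestLab);
  return out;
}

// Mask voxels with at least one face-adjacent background neighbor
// (voxels on the array edge count as boundary).
// [[Rcpp::export]]
LogicalVector cpp_boundary(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[idx]) continue;
        bool bd = false;
        const int di[6] = {-1, 1, 0, 0, 0, 0};
        const int dj[6] = {0, 0, -1, 1, 0, 0};
        const int dk[6] = {0, 0, 0, 0, -1, 1};
        for (int d = 0; d < 6 && !bd; ++d) {
          int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            bd = true;
          else if (!mask[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)])
            bd = true;
        }
        out[idx] = bd;
      }
  return out;
}

// Directed Hausdorff distance between two point sets (rows = points, mm).
// [[Rcpp::export]]
double cpp_directed_hd(NumericMatrix a, NumericMatrix b) {
  int na = a.nrow(), nb = b.nrow();
  double worst = 0.0;
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        if (best <= worst) break; // cannot raise the max
      }
    }
    if (best > worst) worst = best;
  }
  return std::sqrt(worst);
}

// Maximum pairwise distance within one point set (mm).
// [[Rcpp::export]]
double cpp_max_pairwise(NumericMatrix a) {
  int n = a.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = a(i, 0) - a(j, 0), dy = a(i, 1) - a(j, 1),
             dz = a(i, 2) - a(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
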