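// Fast voxel-volume primitives: trilinear sampling at world points, affine
// resampling onto a reference grid, 6-connected component labelling, mean
// pooling, and intensity-weighted component centroids.

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static inline double tri_sample(const double* v, const int* d, double ix,
                                double iy, double iz, double bg) {
  // ix, iy, iz are continuous 0-based voxel indices
  if (ix < 0 || iy < 0 || iz < 0 || ix > d[0] - 1 || iy > d[1] - 1 ||
      iz > d[2] - 1)
    return bg;
  int x0 = (int)std::floor(ix), y0 = (int)std::floor(iy),
      z0 = (int)std::floor(iz);
  if (x0 == d[0] - 1) x0--;
  if (y0 == d[1] - 1) y0--;
  if (z0 == d[2] - 1) z0--;
  double fx = ix - x0, fy = iy - y0, fz = iz - z0;
  const size_t sx = 1, sy = d[0], sz = (size_t)d[0] * d[1];
  const double* p = v + x0 * sx + y0 * sy + z0 * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_sample_points(NumericVector vol, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix pts, double background) {
  int d[3] = {dim[0], dim[1], dim[2]};
  const double* v = vol.begin();
  int n = pts.nrow();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double ix = (pts(k, 0) - origin[0]) / spacing[0];
    double iy = (pts(k, 1) - origin[1]) / spacing[1];
    double iz = (pts(k, 2) - origin[2]) / spacing[2];
    out[k] = tri_sample(v, d, ix, iy, iz, background);
  }
  return out;
}

// Resample `vol` onto the grid given by out_dim/out_spacing/out_origin.
// For each output voxel with world coordinate y, the source is sampled at
// x = R %*% (y - center) + center + t  (rigid map fixed -> moving).
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector vol, IntegerVector dim,
                                  NumericVector spacing, NumericVector origin,
                                  IntegerVector out_dim,
                                  NumericVector out_spacing,
                                  NumericVector out_origin, NumericMatrix R,
                                  NumericVector t, NumericVector center,
                                  double background) {
  int d[3] = {dim[0], dim[1], dim[2]};
  const double* v = vol.begin();
  int nx = out_dim[0], ny = out_dim[1], nz = out_dim[2];
  NumericVector out((size_t)nx * ny * nz);
  double* o = out.begin();
  size_t idx = 0;
  for (int kz = 0; kz < nz; ++kz) {
    double wz = out_origin[2] + kz * out_spacing[2] - center[2];
    for (int ky = 0; ky < ny; ++ky) {
      double wy = out_origin[1] + ky * out_spacing[1] - center[1];
      for (int kx = 0; kx < nx; ++kx, ++idx) {
        double wx = out_origin[0] + kx * out_spacing[0] - center[0];
        double sx = R(0, 0) * wx + R(0, 1) * wy + R(0, 2) * wz + center[0] + t[0];
        double sy = R(1, 0) * wx + R(1, 1) * wy + R(1, 2) * wz + center[1] + t[1];
        double sz = R(2, 0) * wx + R(2, 1) * wy + R(2, 2) * wz + center[2] + t[2];
        double ix = (sx - origin[0]) / spacing[0];
        double iy = (sy - origin[1]) / spacing[1];
        double iz = (sz - origin[2]) / spacing[2];
        o[idx] = tri_sample(v, d, ix, iy, iz, background);
      }
    }
  }
  out.attr("dim") = out_dim;
  return out;
}

// 6-connected component labelling of a binary mask; labels 1..ncomp.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  const int* m = mask.begin();
  int* L = lab.begin();
  const size_t sy = nx, sz = (size_t)nx * ny;
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!m[s] || L[s]) continue;
    ++cur;
    stack.clear();
    stack.push_back(s);
    L[s] = cur;
    while (!stack.empty()) {
      size_t p = stack.back();
      stack.pop_back();
      int z = p / sz;
      int y = (p - (size_t)z * sz) / sy;
      int x = p - (size_t)z * sz - (size_t)y * sy;
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        size_t q = xx + (size_t)yy * sy + (size_t)zz * sz;
        if (m[q] && !L[q]) {
          L[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  lab.attr("ncomp") = cur;
  return lab;
}

// Weighted centroids per label: returns ncomp x 5 matrix
// (count, sum_w, sum_w*ix, sum_w*iy, sum_w*iz) with 0-based voxel indices.
// [[Rcpp::export]]
NumericMatrix cpp_component_centroids(IntegerVector lab, IntegerVector dim,
                                      NumericVector w, int ncomp) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ncomp, 5);
  const int* L = lab.begin();
  const double* W = w.begin();
  size_t s = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++s) {
        int l = L[s];
        if (l > 0) {
          double wv = W[s];
          out(l - 1, 0) += 1.0;
          out(l - 1, 1) += wv;
          out(l - 1, 2) += wv * x;
          out(l - 1, 3) += wv * y;
          out(l - 1, 4) += wv * z;
        }
      }
  return out;
}

// Mean pooling by integer factors (truncating partial blocks).
// [[Rcpp::export]]
NumericVector cpp_downsample_mean(NumericVector vol, IntegerVector dim,
                                  IntegerVector f) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int fx = f[0], fy = f[1], fz = f[2];
  int ox = nx / fx, oy = ny / fy, oz = nz / fz;
  NumericVector out((size_t)ox * oy * oz);
  const double* v = vol.begin();
  double* o = out.begin();
  const size_t sy = nx, sz = (size_t)nx * ny;
  double inv = 1.0 / ((double)fx * fy * fz);
  size_t idx = 0;
  for (int kz = 0; kz < oz; ++kz)
    for (int ky = 0; ky < oy; ++ky)
      for (int kx = 0; kx < ox; ++kx, ++idx) {
        double s = 0.0;
        for (int z = kz * fz; z < (kz + 1) * fz; ++z)
          for (int y = ky * fy; y < (ky + 1) * fy; ++y) {
            const double* p = v + (size_t)kx * fx + (size_t)y * sy + (size_t)z * sz;
            for (int x = 0; x < fx; ++x) s += p[x];
          }
        o[idx] = s * inv;
      }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}
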