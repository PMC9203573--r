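#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Column-major 3D indexing throughout: idx = x + nx*(y + ny*z), 0-based.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Reflect index into [0, n-1] (whole-sample symmetric, period 2n-2).
static inline int reflecti(int i, int n) {
  if (n == 1) return 0;
  const int p = 2 * n - 2;
  i = i % p;
  if (i < 0) i += p;
  return (i < n) ? i : p - i;
}

// In-place cubic B-spline prefilter along one line (Unser 1993),
// whole-sample symmetric boundaries.
static void bspline_prefilter_line(double *c, int n, int stride) {
  if (n < 2) return;
  const double z = std::sqrt(3.0) - 2.0;           // single pole of cubic B-spline
  const double lambda = (1.0 - z) * (1.0 - 1.0 / z);
  for (int i = 0; i < n; ++i) c[i * stride] *= lambda;
  // causal initialization: truncated sum of the mirrored signal
  int horizon = (int)std::ceil(std::log(1e-12) / std::log(std::fabs(z)));
  if (horizon > 2 * n - 2) horizon = 2 * n - 2;
  double zn = z, sum = c[0];
  for (int i = 1; i <= horizon; ++i) {
    sum += zn * c[reflecti(i, n) * stride];
    zn *= z;
  }
  c[0] = sum;
  for (int i = 1; i < n; ++i) c[i * stride] += z * c[(i - 1) * stride];
  c[(n - 1) * stride] = (z / (z * z - 1.0)) *
    (c[(n - 1) * stride] + z * c[(n - 2) * stride]);
  for (int i = n - 2; i >= 0; --i)
    c[i * stride] = z * (c[(i + 1) * stride] - c[i * stride]);
}

// [[Rcpp::export]]
NumericVector cpp_bspline_prefilter(NumericVector arr, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(arr);
  double *p = REAL(out);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      bspline_prefilter_line(p + (size_t)nx * (y + (size_t)ny * z), nx, 1);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      bspline_prefilter_line(p + x + (size_t)nx * ny * z, ny, nx);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      bspline_prefilter_line(p + x + (size_t)nx * y, nz, nx * ny);
  return out;
}

static inline void bspline_weights(double t, double w[4]) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// Resample `src` (prefiltered when mode == 3) onto a grid of `outdims`
// voxels through the voxel-to-voxel affine map v_src = A v_out + b.
// mode: 0 nearest neighbour, 1 trilinear, 3 cubic B-spline.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector src, IntegerVector dims,
                                  NumericMatrix A, NumericVector b,
                                  IntegerVector outdims, int mode,
                                  double background) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = outdims[0], oy = outdims[1], oz = outdims[2];
  NumericVector out((size_t)ox * oy * oz);
  const double *s = REAL(src);
  double *o = REAL(out);
  const double a00 = A(0, 0), a01 = A(0, 1), a02 = A(0, 2);
  const double a10 = A(1, 0), a11 = A(1, 1), a12 = A(1, 2);
  const double a20 = A(2, 0), a21 = A(2, 1), a22 = A(2, 2);
  size_t idx = 0;
  for (int z = 0; z < oz; ++z) {
    for (int y = 0; y < oy; ++y) {
      for (int x = 0; x < ox; ++x, ++idx) {
        const double sx = a00 * x + a01 * y + a02 * z + b[0];
        const double sy = a10 * x + a11 * y + a12 * z + b[1];
        const double sz = a20 * x + a21 * y + a22 * z + b[2];
        if (sx < -0.5 || sx > nx - 0.5 || sy < -0.5 || sy > ny - 0.5 ||
            sz < -0.5 || sz > nz - 0.5) {
          o[idx] = background;
          continue;
        }
        if (mode == 0) {
          const int ix = clampi((int)std::lround(sx), 0, nx - 1);
          const int iy = clampi((int)std::lround(sy), 0, ny - 1);
          const int iz = clampi((int)std::lround(sz), 0, nz - 1);
          o[idx] = s[ix + (size_t)nx * (iy + (size_t)ny * iz)];
        } else if (mode == 1) {
          const int ix = (int)std::floor(sx), iy = (int)std::floor(sy),
                    iz = (int)std::floor(sz);
          const double fx = sx - ix, fy = sy - iy, fz = sz - iz;
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int jx = clampi(ix + dx, 0, nx - 1);
                const int jy = clampi(iy + dy, 0, ny - 1);
                const int jz = clampi(iz + dz, 0, nz - 1);
                const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                                 (dz ? fz : 1 - fz);
                acc += w * s[jx + (size_t)nx * (jy + (size_t)ny * jz)];
              }
          o[idx] = acc;
        } else {
          const int ix = (int)std::floor(sx), iy = (int)std::floor(sy),
                    iz = (int)std::floor(sz);
          double wx[4], wy[4], wz[4];
          bspline_weights(sx - ix, wx);
          bspline_weights(sy - iy, wy);
          bspline_weights(sz - iz, wz);
          double acc = 0.0;
          for (int dz = 0; dz < 4; ++dz) {
            const int jz = reflecti(iz - 1 + dz, nz);
            for (int dy = 0; dy < 4; ++dy) {
              const int jy = reflecti(iy - 1 + dy, ny);
              const double wyz = wy[dy] * wz[dz];
              for (int dx = 0; dx < 4; ++dx) {
                const int jx = reflecti(ix - 1 + dx, nx);
                acc += wx[dx] * wyz * s[jx + (size_t)nx * (jy + (size_t)ny * jz)];
              }
            }
          }
          o[idx] = acc;
        }
      }
    }
  }
  return out;
}

// Backward warp of a binary mask with nearest-neighbour sampling.
// Displacements are in voxel units on the same grid.
// [[Rcpp::export]]
NumericVector cpp_warp_nn(NumericVector mask, IntegerVector dims,
                          NumericVector dx, NumericVector dy,
                          NumericVector dz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((size_t)nx * ny * nz);
  const double *m = REAL(mask);
  double *o = REAL(out);
  size_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        const int ix = (int)std::lround(x + dx[idx]);
        const int iy = (int)std::lround(y + dy[idx]);
        const int iz = (int)std::lround(z + dz[idx]);
        o[idx] = (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 ||
                  iz >= nz)
                     ? 0.0
                     : m[ix + (size_t)nx * (iy + (size_t)ny * iz)];
      }
  return out;
}
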