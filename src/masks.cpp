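#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 0-based coordinates of mask boundary voxels: foreground voxels at the
// volume edge or with at least one background 6-neighbour.
// [[Rcpp::export]]
IntegerMatrix cpp_boundary(NumericVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *m = REAL(mask);
  std::vector<int> xs, ys, zs;
  size_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        if (m[idx] == 0) continue;
        bool edge = x == 0 || x == nx - 1 || y == 0 || y == ny - 1 ||
                    z == 0 || z == nz - 1;
        if (!edge) {
          edge = m[idx - 1] == 0 || m[idx + 1] == 0 ||
                 m[idx - nx] == 0 || m[idx + nx] == 0 ||
                 m[idx - (size_t)nx * ny] == 0 ||
                 m[idx + (size_t)nx * ny] == 0;
        }
        if (edge) { xs.push_back(x); ys.push_back(y); zs.push_back(z); }
      }
  IntegerMatrix out(xs.size(), 3);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i]; out(i, 1) = ys[i]; out(i, 2) = zs[i];
  }
  return out;
}

// 1D squared-EDT lower envelope (Felzenszwalb & Huttenlocher), sample
// positions i * s (physical spacing s). Exact for voxel-centre seeds.
static void edt1d(const double *f, double *d, int n, double s, int *v,
                  double *z) {
  int kk = 0;
  v[0] = 0;
  z[0] = -R_PosInf;
  z[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    const double xq = q * s;
    double sep;
    while (true) {
      const double xv = v[kk] * s;
      sep = ((f[q] + xq * xq) - (f[v[kk]] + xv * xv)) / (2 * xq - 2 * xv);
      if (sep > z[kk]) break;
      --kk;
    }
    ++kk;
    v[kk] = q;
    z[kk] = sep;
    z[kk + 1] = R_PosInf;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * s;
    while (z[kk + 1] < xq) ++kk;
    const double xv = v[kk] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[kk]];
  }
}

// Exact squared Euclidean distance transform (mm^2) to the nonzero voxels
// of `seed`, with per-axis spacing.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(NumericVector seed, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector out(nvox);
  double *d = REAL(out);
  const double *m = REAL(seed);
  // large finite sentinel keeps the envelope arithmetic NaN-free
  for (size_t i = 0; i < nvox; ++i) d[i] = m[i] != 0 ? 0.0 : 1e20;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x axis
  for (int zz = 0; zz < nz; ++zz)
    for (int y = 0; y < ny; ++y) {
      double *line = d + (size_t)nx * (y + (size_t)ny * zz);
      edt1d(line, f.data(), nx, spacing[0], v.data(), z.data());
      std::copy(f.begin(), f.begin() + nx, line);
    }
  // y axis
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      double *base = d + x + (size_t)nx * ny * zz;
      for (int y = 0; y < ny; ++y) f[y] = base[(size_t)nx * y];
      edt1d(f.data(), g.data(), ny, spacing[1], v.data(), z.data());
      for (int y = 0; y < ny; ++y) base[(size_t)nx * y] = g[y];
    }
  // z axis
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      double *base = d + x + (size_t)nx * y;
      for (int zz = 0; zz < nz; ++zz) f[zz] = base[(size_t)nx * ny * zz];
      edt1d(f.data(), g.data(), nz, spacing[2], v.data(), z.data());
      for (int zz = 0; zz < nz; ++zz) base[(size_t)nx * ny * zz] = g[zz];
    }
  return out;
}

// Maximum pairwise Euclidean distance within a point set (mm).
// [[Rcpp::export]]
double cpp_max_pairwise(NumericMatrix A) {
  const int n = A.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = A(i, 0) - A(j, 0), dy = A(i, 1) - A(j, 1),
                   dz = A(i, 2) - A(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}

// Count exposed faces of the voxel union (surface area = count * face area
// is done per-axis in R since faces differ in area on anisotropic grids).
// Returns counts of exposed faces normal to x, y, z.
// [[Rcpp::export]]
IntegerVector cpp_exposed_faces(NumericVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *m = REAL(mask);
  int cx = 0, cy = 0, cz = 0;
  size_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        if (m[idx] == 0) continue;
        if (x == 0 || m[idx - 1] == 0) ++cx;
        if (x == nx - 1 || m[idx + 1] == 0) ++cx;
        if (y == 0 || m[idx - nx] == 0) ++cy;
        if (y == ny - 1 || m[idx + nx] == 0) ++cy;
        if (z == 0 || m[idx - (size_t)nx * ny] == 0) ++cz;
        if (z == nz - 1 || m[idx + (size_t)nx * ny] == 0) ++cz;
      }
  return IntegerVector::create(cx, cy, cz);
}
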