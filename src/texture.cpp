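#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// `disc` holds discretized gray levels 1..ng inside the ROI and 0 outside.
// 13 unique 3D direction offsets (half of the 26-neighbourhood).
static const int DIR[13][3] = {
    {1, 0, 0},  {0, 1, 0},  {0, 0, 1},  {1, 1, 0},  {1, -1, 0},
    {1, 0, 1},  {1, 0, -1}, {0, 1, 1},  {0, 1, -1}, {1, 1, 1},
    {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};

static inline int gl(const int *d, int nx, int ny, int nz, int x, int y,
                     int z) {
  if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
  return d[x + (size_t)nx * (y + (size_t)ny * z)];
}

// Symmetric gray-level co-occurrence counts, distance 1, per direction.
// Returns an ng x ng x 13 array.
// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector disc, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int *d = INTEGER(disc);
  NumericVector out((size_t)ng * ng * 13);
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  double *o = REAL(out);
  size_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        const int g1 = d[idx];
        if (g1 == 0) continue;
        for (int k = 0; k < 13; ++k) {
          const int g2 =
              gl(d, nx, ny, nz, x + DIR[k][0], y + DIR[k][1], z + DIR[k][2]);
          if (g2 == 0) continue;
          o[(g1 - 1) + (size_t)ng * (g2 - 1) + (size_t)ng * ng * k] += 1.0;
          o[(g2 - 1) + (size_t)ng * (g1 - 1) + (size_t)ng * ng * k] += 1.0;
        }
      }
  return out;
}

// Gray-level run-length counts per direction: ng x maxlen x 13.
// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector disc, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int *d = INTEGER(disc);
  const int lmax = std::max(nx, std::max(ny, nz));
  NumericVector out((size_t)ng * lmax * 13);
  out.attr("dim") = IntegerVector::create(ng, lmax, 13);
  double *o = REAL(out);
  for (int k = 0; k < 13; ++k) {
    const int dx = DIR[k][0], dy = DIR[k][1], dz = DIR[k][2];
    size_t idx = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++idx) {
          const int g = d[idx];
          if (g == 0) continue;
          // run starts where the previous voxel along the direction differs
          if (gl(d, nx, ny, nz, x - dx, y - dy, z - dz) == g) continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (gl(d, nx, ny, nz, cx, cy, cz) == g) {
            ++len;
            cx += dx; cy += dy; cz += dz;
          }
          o[(g - 1) + (size_t)ng * (len - 1) + (size_t)ng * lmax * k] += 1.0;
        }
  }
  return out;
}

// Gray-level size-zone counts (26-connected zones): ng x maxsize.
// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector disc, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int *d = INTEGER(disc);
  const size_t nvox = (size_t)nx * ny * nz;
  std::vector<char> seen(nvox, 0);
  std::vector<std::pair<int, int> > zones;  // (gray level, size)
  int maxsize = 1;
  for (size_t start = 0; start < nvox; ++start) {
    if (seen[start] || d[start] == 0) continue;
    const int g = d[start];
    int size = 0;
    std::queue<size_t> q;
    q.push(start);
    seen[start] = 1;
    while (!q.empty()) {
      const size_t cur = q.front();
      q.pop();
      ++size;
      const int x = cur % nx, y = (cur / nx) % ny, z = cur / ((size_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int jx = x + dx, jy = y + dy, jz = z + dz;
            if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 ||
                jz >= nz)
              continue;
            const size_t j = jx + (size_t)nx * (jy + (size_t)ny * jz);
            if (!seen[j] && d[j] == g) { seen[j] = 1; q.push(j); }
          }
    }
    zones.push_back(std::make_pair(g, size));
    if (size > maxsize) maxsize = size;
  }
  NumericMatrix out(ng, maxsize);
  for (size_t i = 0; i < zones.size(); ++i)
    out(zones[i].first - 1, zones[i].second - 1) += 1.0;
  return out;
}

// Gray-level dependence counts: ng x 27 (dependence 0..26 neighbours with
// |gray difference| <= alpha); column j holds dependence j.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector disc, IntegerVector dims, int ng,
                       int alpha) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int *d = INTEGER(disc);
  NumericMatrix out(ng, 27);
  size_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        const int g = d[idx];
        if (g == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              const int g2 = gl(d, nx, ny, nz, x + dx, y + dy, z + dz);
              if (g2 != 0 && std::abs(g2 - g) <= alpha) ++dep;
            }
        out(g - 1, dep) += 1.0;
      }
  return out;
}

// Neighbourhood gray-tone difference: per level, occurrence count n_i and
// summed absolute difference s_i from the mean of in-ROI 26-neighbours.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector disc, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int *d = INTEGER(disc);
  NumericVector s(ng), n(ng);
  size_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        const int g = d[idx];
        if (g == 0) continue;
        double acc = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              const int g2 = gl(d, nx, ny, nz, x + dx, y + dy, z + dz);
              if (g2 != 0) { acc += g2; ++cnt; }
            }
        if (cnt > 0) {
          s[g - 1] += std::fabs(g - acc / cnt);
          n[g - 1] += 1.0;
        }
      }
  return List::create(_["s"] = s, _["n"] = n);
}
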