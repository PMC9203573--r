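#include <Rcpp.h>
using namespace Rcpp;

// Half-sample symmetric reflection (... a1 a0 | a0 a1 ...), period 2n.
static inline int symreflect(int i, int n) {
  const int p = 2 * n;
  i = i % p;
  if (i < 0) i += p;
  return (i < n) ? i : p - 1 - i;
}

// Correlate one axis with kernel k; centre at floor((L-1)/2).
static void conv_axis(const double *in, double *out, int nx, int ny, int nz,
                      int axis, const NumericVector &k) {
  const int L = k.size();
  const int off = (L - 1) / 2;
  const int n[3] = {nx, ny, nz};
  const size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  const int na = n[axis];
  const size_t sa = stride[axis];
  const int b1 = axis == 0 ? 1 : 0;
  const int b2 = axis == 2 ? 1 : 2;
  // gather each line into a padded contiguous buffer so the inner loop is
  // cache-friendly even along strided axes
  std::vector<double> buf(na + L);
  double *line = buf.data() + off;
  const double *kp = REAL(k);
  for (int j2 = 0; j2 < n[b2]; ++j2)
    for (int j1 = 0; j1 < n[b1]; ++j1) {
      const size_t base = stride[b1] * j1 + stride[b2] * j2;
      for (int i = 0; i < na; ++i) line[i] = in[base + sa * i];
      for (int i = -off; i < 0; ++i) line[i] = line[symreflect(i, na)];
      for (int i = na; i < na + (L - 1 - off); ++i)
        line[i] = line[symreflect(i, na)];
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        const double *p = line + i - off;
        for (int t = 0; t < L; ++t) acc += kp[t] * p[t];
        out[base + sa * i] = acc;
      }
    }
}

// Separable 3D correlation with per-axis kernels, symmetric padding.
// [[Rcpp::export]]
NumericVector cpp_sepconv3(NumericVector arr, IntegerVector dims,
                           NumericVector kx, NumericVector ky,
                           NumericVector kz) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector buf = clone(arr);
  NumericVector out((size_t)nx * ny * nz);
  const bool ix = !(kx.size() == 1 && kx[0] == 1.0);
  const bool iy = !(ky.size() == 1 && ky[0] == 1.0);
  const bool iz = !(kz.size() == 1 && kz[0] == 1.0);
  double *a = REAL(buf), *b = REAL(out);
  if (ix) { conv_axis(a, b, nx, ny, nz, 0, kx); std::swap(a, b); }
  if (iy) { conv_axis(a, b, nx, ny, nz, 1, ky); std::swap(a, b); }
  if (iz) { conv_axis(a, b, nx, ny, nz, 2, kz); std::swap(a, b); }
  if (a == REAL(buf)) return buf;
  return out;
}
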