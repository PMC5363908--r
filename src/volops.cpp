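#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <queue>
using namespace Rcpp;

// Fill internal cavities: background components not 6-connected to the
// volume border become foreground.
// [[Rcpp::export]]
IntegerVector cpp_fill_cavities(IntegerVector bin, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::queue<size_t> q;
  auto push_if_bg = [&](int x, int y, int z) {
    size_t i = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
    if (!bin[i] && !outside[i]) { outside[i] = 1; q.push(i); }
  };
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++)
        if (x == 0 || y == 0 || z == 0 || x == nx - 1 || y == ny - 1 || z == nz - 1)
          push_if_bg(x, y, z);
  while (!q.empty()) {
    size_t i = q.front(); q.pop();
    int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / ((size_t)nx * ny));
    if (x > 0) push_if_bg(x - 1, y, z);
    if (x < nx - 1) push_if_bg(x + 1, y, z);
    if (y > 0) push_if_bg(x, y - 1, z);
    if (y < ny - 1) push_if_bg(x, y + 1, z);
    if (z > 0) push_if_bg(x, y, z - 1);
    if (z < nz - 1) push_if_bg(x, y, z + 1);
  }
  IntegerVector out((R_xlen_t)n);
  for (size_t i = 0; i < n; i++) out[i] = (bin[i] || !outside[i]) ? 1 : 0;
  return out;
}

// Separable 3D Gaussian with reflective boundaries (d c b a | a b c d).
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dims, double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  if (sigma <= 0) return clone(vol);
  int R = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * R + 1);
  double s = 0;
  for (int i = -R; i <= R; i++) {
    k[i + R] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + R];
  }
  for (int i = 0; i <= 2 * R; i++) k[i] /= s;
  auto reflect = [](int i, int nn) {
    // reflect including the edge sample: ... 1 0 | 0 1 ...
    while (i < 0 || i >= nn) {
      if (i < 0) i = -i - 1;
      if (i >= nn) i = 2 * nn - i - 1;
    }
    return i;
  };
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  // along x
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      size_t base = (size_t)nx * (y + (size_t)ny * z);
      for (int x = 0; x < nx; x++) {
        double acc = 0;
        for (int j = -R; j <= R; j++) acc += k[j + R] * a[base + reflect(x + j, nx)];
        b[base + x] = acc;
      }
    }
  // along y
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++)
      for (int y = 0; y < ny; y++) {
        double acc = 0;
        for (int j = -R; j <= R; j++)
          acc += k[j + R] * b[(size_t)x + (size_t)nx * (reflect(y + j, ny) + (size_t)ny * z)];
        a[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] = acc;
      }
  // along z
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++)
      for (int z = 0; z < nz; z++) {
        double acc = 0;
        for (int j = -R; j <= R; j++)
          acc += k[j + R] * a[(size_t)x + (size_t)nx * (y + (size_t)ny * reflect(z + j, nz))];
        b[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] = acc;
      }
  return NumericVector(b.begin(), b.end());
}

// Nearest-neighbour resampling of a volume under an inverse voxel-frame map:
// out(x) = in(round(Minv %*% x + tinv)), indices 0-based; fill outside.
// [[Rcpp::export]]
NumericVector cpp_resample_nn(NumericVector vol, IntegerVector dims,
                              NumericVector Minv, NumericVector tinv,
                              double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz, fill);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        double sx = Minv[0] * x + Minv[3] * y + Minv[6] * z + tinv[0];
        double sy = Minv[1] * x + Minv[4] * y + Minv[7] * z + tinv[1];
        double sz = Minv[2] * x + Minv[5] * y + Minv[8] * z + tinv[2];
        int ix = (int)std::lround(sx), iy = (int)std::lround(sy), iz = (int)std::lround(sz);
        if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz) continue;
        out[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] =
          vol[(size_t)ix + (size_t)nx * (iy + (size_t)ny * iz)];
      }
  return out;
}
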