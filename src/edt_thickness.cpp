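#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// one 1-D lower-envelope pass. f holds squared distances, result overwrites f.
static void edt1d(std::vector<double> &f, std::vector<double> &d,
                  std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s;
    for (;;) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared EDT (in voxel units) of the foreground, distance to nearest
// background voxel centre; voxels outside the grid count as background.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector bin, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int px = nx + 2, py = ny + 2, pz = nz + 2;
  const double INF = 1e18;
  std::vector<double> g((size_t)px * py * pz, 0.0);
  // pad with background (0 distance); interior: 0 if background, INF if bone
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        size_t pi = (size_t)(x + 1) + (size_t)px * ((y + 1) + (size_t)py * (z + 1));
        g[pi] = bin[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] ? INF : 0.0;
      }
  int nmax = std::max(px, std::max(py, pz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along x
  for (int zz = 0; zz < pz; zz++)
    for (int yy = 0; yy < py; yy++) {
      size_t base = (size_t)px * (yy + (size_t)py * zz);
      for (int x = 0; x < px; x++) f[x] = g[base + x];
      edt1d(f, d, v, z, px);
      for (int x = 0; x < px; x++) g[base + x] = d[x];
    }
  // pass along y
  for (int zz = 0; zz < pz; zz++)
    for (int xx = 0; xx < px; xx++) {
      for (int y = 0; y < py; y++) f[y] = g[(size_t)xx + (size_t)px * (y + (size_t)py * zz)];
      edt1d(f, d, v, z, py);
      for (int y = 0; y < py; y++) g[(size_t)xx + (size_t)px * (y + (size_t)py * zz)] = d[y];
    }
  // pass along z
  for (int yy = 0; yy < py; yy++)
    for (int xx = 0; xx < px; xx++) {
      for (int zz = 0; zz < pz; zz++) f[zz] = g[(size_t)xx + (size_t)px * (yy + (size_t)py * zz)];
      edt1d(f, d, v, z, pz);
      for (int zz = 0; zz < pz; zz++) g[(size_t)xx + (size_t)px * (yy + (size_t)py * zz)] = d[zz];
    }
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int zz = 0; zz < nz; zz++)
    for (int yy = 0; yy < ny; yy++)
      for (int xx = 0; xx < nx; xx++)
        out[(size_t)xx + (size_t)nx * (yy + (size_t)ny * zz)] =
          g[(size_t)(xx + 1) + (size_t)px * ((yy + 1) + (size_t)py * (zz + 1))];
  return out;
}

// Model-independent local thickness (largest inscribed sphere), in voxel
// units (diameter). Distance ridge -> sphere painting.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(IntegerVector bin, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  NumericVector d2v = cpp_edt_sq(bin, dims);
  std::vector<double> rad(n);
  for (size_t i = 0; i < n; i++) rad[i] = std::sqrt(d2v[i]);

  // neighbour offsets (26-connectivity) with distances
  std::vector<int> noff;
  std::vector<double> ndist;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (!dx && !dy && !dz) continue;
        noff.push_back(dx); noff.push_back(dy); noff.push_back(dz);
        ndist.push_back(std::sqrt((double)(dx * dx + dy * dy + dz * dz)));
      }

  // distance ridge: a sphere not contained in any single neighbour's sphere
  std::vector<size_t> ridge;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        size_t i = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
        if (rad[i] <= 0) continue;
        bool covered = false;
        for (size_t k = 0; k < ndist.size() && !covered; k++) {
          int qx = x + noff[3 * k], qy = y + noff[3 * k + 1], qz = z + noff[3 * k + 2];
          if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) continue;
          size_t q = (size_t)qx + (size_t)nx * (qy + (size_t)ny * qz);
          if (rad[q] >= rad[i] + ndist[k] - 1e-9) covered = true;
        }
        if (!covered) ridge.push_back(i);
      }

  // paint spheres in decreasing radius order
  std::sort(ridge.begin(), ridge.end(),
            [&](size_t a, size_t b) { return rad[a] > rad[b]; });
  NumericVector out((R_xlen_t)n);
  for (size_t r = 0; r < ridge.size(); r++) {
    size_t i = ridge[r];
    double ri = rad[i];
    double diam = 2.0 * ri;
    int cx = (int)(i % nx);
    int cy = (int)((i / nx) % ny);
    int cz = (int)(i / ((size_t)nx * ny));
    int R = (int)std::ceil(ri);
    double r2 = d2v[i]; // exact squared radius (integer-valued)
    for (int dz = -R; dz <= R; dz++) {
      int z = cz + dz; if (z < 0 || z >= nz) continue;
      for (int dy = -R; dy <= R; dy++) {
        int y = cy + dy; if (y < 0 || y >= ny) continue;
        double dyz = (double)dz * dz + (double)dy * dy;
        if (dyz >= r2) continue;
        size_t rowb = (size_t)nx * (y + (size_t)ny * z);
        for (int dx = -R; dx <= R; dx++) {
          int x = cx + dx; if (x < 0 || x >= nx) continue;
          if (dyz + (double)dx * dx < r2 - 1e-9) {
            size_t j = rowb + x;
            if (out[j] < diam) out[j] = diam;
          }
        }
      }
    }
  }
  // any foreground voxel missed (thin sliver) gets its own diameter
  for (size_t i = 0; i < n; i++)
    if (rad[i] > 0 && out[i] < 2.0 * rad[i]) out[i] = 2.0 * rad[i];
  return out;
}
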