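#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// ---- isosurface by marching tetrahedra -------------------------------------
// Grid nodes sit at voxel centres, world coordinate = 0-based index * voxel.
// Each cell is split into the 6 tetrahedra sharing the main diagonal
// (0,0,0)-(1,1,1); every cell face is cut along the (0,0)-(1,1) diagonal, so
// the decomposition is translation-consistent and the surface is crack-free.

struct MTState {
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  std::unordered_map<uint64_t, int> edge_vertex;
};

static inline uint64_t edge_key(uint64_t a, uint64_t b) {
  if (a > b) std::swap(a, b);
  return (a << 32) | b;
}

static int interp_vertex(MTState &S, uint64_t ia, uint64_t ib,
                         const double *pa, const double *pb,
                         double fa, double fb, double iso) {
  uint64_t key = edge_key(ia, ib);
  auto it = S.edge_vertex.find(key);
  if (it != S.edge_vertex.end()) return it->second;
  double t = (fb == fa) ? 0.5 : (iso - fa) / (fb - fa);
  if (t < 0) t = 0; if (t > 1) t = 1;
  S.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  S.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  S.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  int id = (int)S.vx.size() - 1;
  S.edge_vertex[key] = id;
  return id;
}

// append triangle (a,b,c), flipping if its normal does not point from the
// inside corners towards the outside corners of the tetrahedron
static void push_tri(MTState &S, int a, int b, int c,
                     const double *dir_out) {
  double ux = S.vx[b] - S.vx[a], uy = S.vy[b] - S.vy[a], uz = S.vz[b] - S.vz[a];
  double wx = S.vx[c] - S.vx[a], wy = S.vy[c] - S.vy[a], wz = S.vz[c] - S.vz[a];
  double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
  double dp = nx * dir_out[0] + ny * dir_out[1] + nz * dir_out[2];
  if (dp >= 0) { S.f0.push_back(a); S.f1.push_back(b); S.f2.push_back(c); }
  else         { S.f0.push_back(a); S.f1.push_back(c); S.f2.push_back(b); }
}

static void do_tet(MTState &S, const uint64_t idx[4], const double P[4][3],
                   const double F[4], double iso) {
  int inside[4], nin = 0, nout = 0, in_id[4], out_id[4];
  for (int i = 0; i < 4; i++) {
    inside[i] = F[i] > iso;
    if (inside[i]) in_id[nin++] = i; else out_id[nout++] = i;
  }
  if (nin == 0 || nin == 4) return;
  // outward direction: centroid(outside) - centroid(inside)
  double ci[3] = {0, 0, 0}, co[3] = {0, 0, 0};
  for (int k = 0; k < nin; k++)
    for (int d = 0; d < 3; d++) ci[d] += P[in_id[k]][d] / nin;
  for (int k = 0; k < nout; k++)
    for (int d = 0; d < 3; d++) co[d] += P[out_id[k]][d] / nout;
  double dir[3] = {co[0] - ci[0], co[1] - ci[1], co[2] - ci[2]};

  if (nin == 1) {
    int a = in_id[0];
    int v0 = interp_vertex(S, idx[a], idx[out_id[0]], P[a], P[out_id[0]], F[a], F[out_id[0]], iso);
    int v1 = interp_vertex(S, idx[a], idx[out_id[1]], P[a], P[out_id[1]], F[a], F[out_id[1]], iso);
    int v2 = interp_vertex(S, idx[a], idx[out_id[2]], P[a], P[out_id[2]], F[a], F[out_id[2]], iso);
    push_tri(S, v0, v1, v2, dir);
  } else if (nin == 3) {
    int a = out_id[0];
    int v0 = interp_vertex(S, idx[a], idx[in_id[0]], P[a], P[in_id[0]], F[a], F[in_id[0]], iso);
    int v1 = interp_vertex(S, idx[a], idx[in_id[1]], P[a], P[in_id[1]], F[a], F[in_id[1]], iso);
    int v2 = interp_vertex(S, idx[a], idx[in_id[2]], P[a], P[in_id[2]], F[a], F[in_id[2]], iso);
    push_tri(S, v0, v1, v2, dir);
  } else { // 2 in, 2 out -> quad
    int a = in_id[0], b = in_id[1], c = out_id[0], d = out_id[1];
    int vac = interp_vertex(S, idx[a], idx[c], P[a], P[c], F[a], F[c], iso);
    int vad = interp_vertex(S, idx[a], idx[d], P[a], P[d], F[a], F[d], iso);
    int vbc = interp_vertex(S, idx[b], idx[c], P[b], P[c], F[b], F[c], iso);
    int vbd = interp_vertex(S, idx[b], idx[d], P[b], P[d], F[b], F[d], iso);
    push_tri(S, vac, vad, vbd, dir);
    push_tri(S, vac, vbd, vbc, dir);
  }
}

// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dims, double iso,
                    double voxel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // corner order: bit0 -> +x, bit1 -> +y, bit2 -> +z
  static const int TETS[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  MTState S;
  double cf[8];
  uint64_t ci[8];
  double cp[8][3];
  for (int z = 0; z + 1 < nz; z++)
    for (int y = 0; y + 1 < ny; y++)
      for (int x = 0; x + 1 < nx; x++) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; c++) {
          int cx = x + (c & 1), cy = y + ((c >> 1) & 1), cz = z + ((c >> 2) & 1);
          uint64_t gi = (uint64_t)cx + (uint64_t)nx * (cy + (uint64_t)ny * cz);
          ci[c] = gi;
          cf[c] = field[gi];
          cp[c][0] = cx * voxel; cp[c][1] = cy * voxel; cp[c][2] = cz * voxel;
          if (cf[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; t++) {
          uint64_t ti[4];
          double tp[4][3], tf[4];
          for (int k = 0; k < 4; k++) {
            int c = TETS[t][k];
            ti[k] = ci[c]; tf[k] = cf[c];
            tp[k][0] = cp[c][0]; tp[k][1] = cp[c][1]; tp[k][2] = cp[c][2];
          }
          do_tet(S, ti, tp, tf, iso);
        }
      }
  int nv = (int)S.vx.size(), nf = (int)S.f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nv; i++) { V(i, 0) = S.vx[i]; V(i, 1) = S.vy[i]; V(i, 2) = S.vz[i]; }
  for (int i = 0; i < nf; i++) { Fm(i, 0) = S.f0[i] + 1; Fm(i, 1) = S.f1[i] + 1; Fm(i, 2) = S.f2[i] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// ---- voxelization of a closed mesh -----------------------------------------
// Parity counting along +x rays through voxel centres; voxel centre world
// coordinate = 0-based index * voxel. Ray origins are nudged by a tiny
// irrational offset in (y,z) so rays never hit triangle edges exactly.

// [[Rcpp::export]]
IntegerVector cpp_voxelize(NumericMatrix verts, IntegerMatrix faces,
                           IntegerVector dims, double voxel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ey = 1.3173e-4 * voxel, ez = 0.7317e-4 * voxel;
  std::vector<std::vector<double> > cross((size_t)ny * nz);
  const int nf = faces.nrow();
  for (int f = 0; f < nf; f++) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    double ay = verts(a, 1), az = verts(a, 2), ax = verts(a, 0);
    double by = verts(b, 1), bz = verts(b, 2), bx = verts(b, 0);
    double cy = verts(c, 1), cz = verts(c, 2), cx = verts(c, 0);
    double ylo = std::min(ay, std::min(by, cy)), yhi = std::max(ay, std::max(by, cy));
    double zlo = std::min(az, std::min(bz, cz)), zhi = std::max(az, std::max(bz, cz));
    int j0 = std::max(0, (int)std::ceil((ylo - ey) / voxel - 1e-9));
    int j1 = std::min(ny - 1, (int)std::floor((yhi - ey) / voxel + 1e-9));
    int k0 = std::max(0, (int)std::ceil((zlo - ez) / voxel - 1e-9));
    int k1 = std::min(nz - 1, (int)std::floor((zhi - ez) / voxel + 1e-9));
    double det = (by - ay) * (cz - az) - (bz - az) * (cy - ay);
    if (det == 0) continue; // ray-parallel triangle: zero-area projection
    for (int k = k0; k <= k1; k++) {
      double pz = k * voxel + ez;
      for (int j = j0; j <= j1; j++) {
        double py = j * voxel + ey;
        // barycentric in the (y,z) projection
        double l1 = ((py - ay) * (cz - az) - (pz - az) * (cy - ay)) / det;
        double l2 = ((by - ay) * (pz - az) - (bz - az) * (py - ay)) / det;
        if (l1 < 0 || l2 < 0 || l1 + l2 > 1) continue;
        double xhit = ax + l1 * (bx - ax) + l2 * (cx - ax);
        cross[(size_t)j + (size_t)ny * k].push_back(xhit);
      }
    }
  }
  IntegerVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      std::vector<double> &cs = cross[(size_t)j + (size_t)ny * k];
      if (cs.empty()) continue;
      std::sort(cs.begin(), cs.end());
      size_t m = cs.size() - (cs.size() % 2); // defensive: drop unpaired hit
      for (size_t p = 0; p + 1 < m; p += 2) {
        int i0 = std::max(0, (int)std::ceil(cs[p] / voxel - 1e-12));
        int i1 = std::min(nx - 1, (int)std::floor(cs[p + 1] / voxel + 1e-12));
        for (int i = i0; i <= i1; i++)
          out[(size_t)i + (size_t)nx * (j + (size_t)ny * k)] = 1;
      }
    }
  return out;
}

// ---- nearest neighbour on a uniform grid -----------------------------------

// [[Rcpp::export]]
List cpp_grid_nn(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  double lo[3], hi[3];
  for (int d = 0; d < 3; d++) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < nr; i++)
    for (int d = 0; d < 3; d++) {
      if (ref(i, d) < lo[d]) lo[d] = ref(i, d);
      if (ref(i, d) > hi[d]) hi[d] = ref(i, d);
    }
  double ext[3], vol = 1.0;
  for (int d = 0; d < 3; d++) {
    ext[d] = std::max(hi[d] - lo[d], 1e-9);
    vol *= ext[d];
  }
  double h = std::max(1.5 * std::cbrt(vol / std::max(nr, 1)), 1e-9);
  int gd[3];
  for (int d = 0; d < 3; d++)
    gd[d] = std::max(1, std::min(256, (int)std::ceil(ext[d] / h)));
  double cell[3];
  for (int d = 0; d < 3; d++) cell[d] = ext[d] / gd[d];
  std::vector<std::vector<int> > buckets((size_t)gd[0] * gd[1] * gd[2]);
  auto cell_of = [&](double x, int d) {
    int c = (int)((x - lo[d]) / cell[d]);
    if (c < 0) c = 0; if (c >= gd[d]) c = gd[d] - 1;
    return c;
  };
  for (int i = 0; i < nr; i++) {
    int cx = cell_of(ref(i, 0), 0), cy = cell_of(ref(i, 1), 1), cz = cell_of(ref(i, 2), 2);
    buckets[(size_t)cx + (size_t)gd[0] * (cy + (size_t)gd[1] * cz)].push_back(i);
  }
  IntegerVector idx(nq);
  NumericVector dist(nq);
  double hmin = std::min(cell[0], std::min(cell[1], cell[2]));
  int smax = std::max(gd[0], std::max(gd[1], gd[2]));
  for (int q = 0; q < nq; q++) {
    double px = query(q, 0), py = query(q, 1), pz = query(q, 2);
    int cx = cell_of(px, 0), cy = cell_of(py, 1), cz = cell_of(pz, 2);
    double best = R_PosInf;
    int besti = -1;
    for (int s = 0; s < smax + 1; s++) {
      // shell s of cells (Chebyshev ring)
      int x0 = cx - s, x1 = cx + s, y0 = cy - s, y1 = cy + s, z0 = cz - s, z1 = cz + s;
      for (int z = z0; z <= z1; z++) {
        if (z < 0 || z >= gd[2]) continue;
        for (int y = y0; y <= y1; y++) {
          if (y < 0 || y >= gd[1]) continue;
          for (int x = x0; x <= x1; x++) {
            if (x < 0 || x >= gd[0]) continue;
            if (s > 0 && std::abs(x - cx) != s && std::abs(y - cy) != s &&
                std::abs(z - cz) != s) continue;
            const std::vector<int> &b =
              buckets[(size_t)x + (size_t)gd[0] * (y + (size_t)gd[1] * z)];
            for (size_t t = 0; t < b.size(); t++) {
              int i = b[t];
              double dx = ref(i, 0) - px, dy = ref(i, 1) - py, dz = ref(i, 2) - pz;
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best) { best = d2; besti = i; }
            }
          }
        }
      }
      // stop once the found neighbour cannot be beaten by farther shells
      if (besti >= 0 && std::sqrt(best) <= s * hmin) break;
    }
    idx[q] = besti + 1;
    dist[q] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// ---- closest point on a triangle mesh --------------------------------------
// Correspondences for surface registration: for each query point, the
// closest location on the source surface. Candidate triangles are those
// incident to the grid-nearest vertices (2-ring), with exact
// point-in-triangle projection (Ericson's method).

static void closest_on_tri(const double p[3], const double a[3],
                           const double b[3], const double c[3],
                           double out[3]) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; i++) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i = 0; i < 3; i++) out[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; i++) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i = 0; i < 3; i++) out[i] = b[i]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; i++) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; i++) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i = 0; i < 3; i++) out[i] = c[i]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; i++) out[i] = a[i] + w * ac[i];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; i++) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; i++) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix query, NumericMatrix verts,
                         IntegerMatrix faces) {
  const int nq = query.nrow(), nf = faces.nrow(), nv = verts.nrow();
  // vertex -> incident faces (CSR)
  std::vector<int> deg(nv, 0);
  for (int f = 0; f < nf; f++)
    for (int k = 0; k < 3; k++) deg[faces(f, k) - 1]++;
  std::vector<int> start(nv + 1, 0);
  for (int i = 0; i < nv; i++) start[i + 1] = start[i] + deg[i];
  std::vector<int> inc(start[nv]);
  std::vector<int> fill(nv, 0);
  for (int f = 0; f < nf; f++)
    for (int k = 0; k < 3; k++) {
      int v = faces(f, k) - 1;
      inc[start[v] + fill[v]++] = f;
    }
  List nn = cpp_grid_nn(query, verts);
  IntegerVector nni = nn["index"];
  NumericMatrix closest(nq, 3);
  NumericVector dist(nq);
  std::vector<char> seen(nf, 0);
  std::vector<int> cand;
  for (int qi = 0; qi < nq; qi++) {
    double p[3] = {query(qi, 0), query(qi, 1), query(qi, 2)};
    int v0 = nni[qi] - 1;
    cand.clear();
    // faces incident to the nearest vertex and to its 1-ring
    for (int s = start[v0]; s < start[v0 + 1]; s++) {
      int f = inc[s];
      for (int k = 0; k < 3; k++) {
        int v2 = faces(f, k) - 1;
        for (int s2 = start[v2]; s2 < start[v2 + 1]; s2++)
          if (!seen[inc[s2]]) { seen[inc[s2]] = 1; cand.push_back(inc[s2]); }
      }
    }
    double best = R_PosInf, bp[3] = {0, 0, 0};
    for (size_t t = 0; t < cand.size(); t++) {
      int f = cand[t];
      seen[f] = 0;
      double a[3] = {verts(faces(f, 0) - 1, 0), verts(faces(f, 0) - 1, 1), verts(faces(f, 0) - 1, 2)};
      double b[3] = {verts(faces(f, 1) - 1, 0), verts(faces(f, 1) - 1, 1), verts(faces(f, 1) - 1, 2)};
      double c[3] = {verts(faces(f, 2) - 1, 0), verts(faces(f, 2) - 1, 1), verts(faces(f, 2) - 1, 2)};
      double cp[3];
      closest_on_tri(p, a, b, c, cp);
      double d2 = (cp[0] - p[0]) * (cp[0] - p[0]) + (cp[1] - p[1]) * (cp[1] - p[1]) +
                  (cp[2] - p[2]) * (cp[2] - p[2]);
      if (d2 < best) { best = d2; bp[0] = cp[0]; bp[1] = cp[1]; bp[2] = cp[2]; }
    }
    if (!R_finite(best)) { // isolated vertex: fall back to the vertex itself
      NumericVector nd = nn["dist"];
      bp[0] = verts(v0, 0); bp[1] = verts(v0, 1); bp[2] = verts(v0, 2);
      best = nd[qi] * nd[qi];
    }
    closest(qi, 0) = bp[0]; closest(qi, 1) = bp[1]; closest(qi, 2) = bp[2];
    dist[qi] = std::sqrt(best);
  }
  return List::create(_["point"] = closest, _["dist"] = dist);
}
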