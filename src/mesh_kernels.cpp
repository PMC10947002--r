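#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// Tetrahedral isosurfacing on the Kuhn (6-tetrahedra) subdivision of each
// grid cube.  The subdivision is translation-invariant, so face diagonals of
// neighbouring cubes coincide and the extracted surface is watertight.
// Vertices lie on tetrahedron edges and are welded through an edge-keyed map.

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// Kuhn subdivision: six tetrahedra, each a monotone lattice path from corner
// (0,0,0) to corner (1,1,1) of the unit cube.  Corner bit order: x + 2y + 4z.
const int TETS[6][4] = {
  {0, 1, 3, 7},  // +x +y +z
  {0, 1, 5, 7},  // +x +z +y
  {0, 2, 3, 7},  // +y +x +z
  {0, 2, 6, 7},  // +y +z +x
  {0, 4, 5, 7},  // +z +x +y
  {0, 4, 6, 7}   // +z +y +x
};

}  // namespace

// [[Rcpp::export(name = ".mt_isosurface")]]
List mt_isosurface(NumericVector field, IntegerVector dims, double level,
                   NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  std::unordered_map<uint64_t, int> edge_vertex;
  edge_vertex.reserve(1 << 16);

  const double* F = REAL(field);
  auto gid = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
  };

  // world position of grid point (voxel-centre convention)
  auto gpos = [&](int64_t g) -> Vec3 {
    int i = (int)(g % nx);
    int j = (int)((g / nx) % ny);
    int k = (int)(g / ((int64_t)nx * ny));
    return Vec3{ox + i * sx, oy + j * sy, oz + k * sz};
  };

  auto edge_point = [&](int64_t ga, int64_t gb, double fa, double fb) -> int {
    if (ga > gb) {
      std::swap(ga, gb);
      std::swap(fa, fb);
    }
    uint64_t key = (uint64_t)ga * (uint64_t)(nx) * (uint64_t)(ny) * (uint64_t)(nz)
                   + (uint64_t)gb;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = (level - fa) / (fb - fa);
    Vec3 pa = gpos(ga), pb = gpos(gb);
    vx.push_back(pa.x + t * (pb.x - pa.x));
    vy.push_back(pa.y + t * (pb.y - pa.y));
    vz.push_back(pa.z + t * (pb.z - pa.z));
    int idx = (int)vx.size() - 1;
    edge_vertex.emplace(key, idx);
    return idx;
  };

  // emit a triangle oriented so its normal points from the inside (field >
  // level) toward the outside: outward for a solid region
  auto emit = [&](int a, int b, int c, const Vec3& out_dir) {
    Vec3 p0{vx[a], vy[a], vz[a]}, p1{vx[b], vy[b], vz[b]}, p2{vx[c], vy[c], vz[c]};
    Vec3 n = cross(sub(p1, p0), sub(p2, p0));
    if (dot(n, out_dir) < 0.0) std::swap(b, c);
    f0.push_back(a);
    f1.push_back(b);
    f2.push_back(c);
  };

  int64_t cg[8];
  double cf[8];
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          cg[c] = gid(i + di, j + dj, k + dk);
          cf[c] = F[cg[c]];
          (cf[c] > level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          int64_t tg[4];
          double tf[4];
          bool in[4];
          int n_in = 0;
          for (int c = 0; c < 4; ++c) {
            tg[c] = cg[TETS[t][c]];
            tf[c] = cf[TETS[t][c]];
            in[c] = tf[c] > level;
            if (in[c]) ++n_in;
          }
          if (n_in == 0 || n_in == 4) continue;

          // direction from inside-corner centroid to outside-corner centroid
          Vec3 ci{0, 0, 0}, co{0, 0, 0};
          for (int c = 0; c < 4; ++c) {
            Vec3 p = gpos(tg[c]);
            if (in[c]) {
              ci.x += p.x; ci.y += p.y; ci.z += p.z;
            } else {
              co.x += p.x; co.y += p.y; co.z += p.z;
            }
          }
          int n_out = 4 - n_in;
          Vec3 out_dir{co.x / n_out - ci.x / n_in, co.y / n_out - ci.y / n_in,
                       co.z / n_out - ci.z / n_in};

          if (n_in == 1 || n_in == 3) {
            int apex = -1;
            bool apex_in = (n_in == 1);
            for (int c = 0; c < 4; ++c)
              if (in[c] == apex_in) apex = c;
            int e[3], m = 0;
            for (int c = 0; c < 4; ++c) {
              if (c == apex) continue;
              e[m++] = edge_point(tg[apex], tg[c], tf[apex], tf[c]);
            }
            emit(e[0], e[1], e[2], out_dir);
          } else {  // 2 in, 2 out: quad split into two triangles
            int ain[2], aout[2], mi = 0, mo = 0;
            for (int c = 0; c < 4; ++c) (in[c] ? ain[mi++] : aout[mo++]) = c;
            int e00 = edge_point(tg[ain[0]], tg[aout[0]], tf[ain[0]], tf[aout[0]]);
            int e01 = edge_point(tg[ain[0]], tg[aout[1]], tf[ain[0]], tf[aout[1]]);
            int e10 = edge_point(tg[ain[1]], tg[aout[0]], tf[ain[1]], tf[aout[0]]);
            int e11 = edge_point(tg[ain[1]], tg[aout[1]], tf[ain[1]], tf[aout[1]]);
            // cycle e00 -> e01 -> e11 -> e10
            emit(e00, e01, e11, out_dir);
            emit(e00, e11, e10, out_dir);
          }
        }
      }
    }
  }

  int nv = (int)vx.size(), nf = (int)f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = vx[i];
    V(i, 1) = vy[i];
    V(i, 2) = vz[i];
  }
  for (int i = 0; i < nf; ++i) {
    Fm(i, 0) = f0[i] + 1;
    Fm(i, 1) = f1[i] + 1;
    Fm(i, 2) = f2[i] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// Even-odd parity voxelization: a voxel centre is inside iff a +z ray from it
// crosses the surface an odd number of times.  Triangles are binned by their
// xy bounding box so each column only tests overlapping triangles.  Ray
// origins are jittered by a fixed sub-voxel offset to avoid edge/vertex hits.

// [[Rcpp::export(name = ".voxelize_mesh")]]
IntegerVector voxelize_mesh(NumericMatrix V, IntegerMatrix F, IntegerVector dims,
                            NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int nf = F.nrow();
  const double jx = 0.254869 * sx * 1e-3, jy = 0.613728 * sy * 1e-3;

  std::vector<std::vector<int>> bins((size_t)nx * ny);
  for (int f = 0; f < nf; ++f) {
    double x0 = V(F(f, 0) - 1, 0), x1 = V(F(f, 1) - 1, 0), x2 = V(F(f, 2) - 1, 0);
    double y0 = V(F(f, 0) - 1, 1), y1 = V(F(f, 1) - 1, 1), y2 = V(F(f, 2) - 1, 1);
    double xmin = std::min({x0, x1, x2}), xmax = std::max({x0, x1, x2});
    double ymin = std::min({y0, y1, y2}), ymax = std::max({y0, y1, y2});
    int i0 = std::max(0, (int)std::ceil((xmin - ox - jx) / sx - 1e-9));
    int i1 = std::min(nx - 1, (int)std::floor((xmax - ox - jx) / sx + 1e-9));
    int j0 = std::max(0, (int)std::ceil((ymin - oy - jy) / sy - 1e-9));
    int j1 = std::min(ny - 1, (int)std::floor((ymax - oy - jy) / sy + 1e-9));
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) bins[(size_t)i + (size_t)nx * j].push_back(f);
  }

  IntegerVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> hits;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const std::vector<int>& cand = bins[(size_t)i + (size_t)nx * j];
      if (cand.empty()) continue;
      const double px = ox + i * sx + jx, py = oy + j * sy + jy;
      hits.clear();
      for (int f : cand) {
        int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
        double ax = V(a, 0) - px, ay = V(a, 1) - py;
        double bx = V(b, 0) - px, by = V(b, 1) - py;
        double cx = V(c, 0) - px, cy = V(c, 1) - py;
        // signed areas of the projected sub-triangles
        double d0 = ax * by - ay * bx;
        double d1 = bx * cy - by * cx;
        double d2 = cx * ay - cy * ax;
        bool pos = d0 > 0 && d1 > 0 && d2 > 0;
        bool neg = d0 < 0 && d1 < 0 && d2 < 0;
        if (!pos && !neg) continue;
        double s = d0 + d1 + d2;
        double w0 = d1 / s, w1 = d2 / s, w2 = d0 / s;
        hits.push_back(w0 * V(a, 2) + w1 * V(b, 2) + w2 * V(c, 2));
      }
      if (hits.size() < 2) continue;
      std::sort(hits.begin(), hits.end());
      size_t np = hits.size() / 2;
      for (size_t p = 0; p < np; ++p) {
        double zlo = hits[2 * p], zhi = hits[2 * p + 1];
        int k0 = std::max(0, (int)std::ceil((zlo - oz) / sz - 1e-12));
        int k1 = std::min(nz - 1, (int)std::floor((zhi - oz) / sz + 1e-12));
        for (int k = k0; k <= k1; ++k)
          out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = 1;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// 6-connected component labelling of a binary 3D mask (BFS).

// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::queue<R_xlen_t> q;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front();
      q.pop();
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
      for (int d = 0; d < 6; ++d) {
        int ii = i + dx[d], jj = j + dy[d], kk = k + dz[d];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        R_xlen_t w = (R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[w] && !lab[w]) {
          lab[w] = next;
          q.push(w);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// separable Gaussian smoothing of a 3D field (replicate padding), sigma in
// voxel units; used for sub-voxel boundary placement before isosurfacing

// [[Rcpp::export(name = ".gauss_smooth3d")]]
NumericVector gauss_smooth3d(NumericVector field, IntegerVector dims,
                             double sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double ksum = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    ksum += k[i + r];
  }
  for (double& v : k) v /= ksum;

  NumericVector a = clone(field);
  NumericVector b((R_xlen_t)nx * ny * nz);
  auto idx = [&](int i, int j, int l) -> R_xlen_t {
    return (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * l);
  };
  for (int pass = 0; pass < 3; ++pass) {
    for (int l = 0; l < nz; ++l)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double s = 0.0;
          for (int d = -r; d <= r; ++d) {
            int ii = i, jj = j, ll = l;
            if (pass == 0) ii = std::min(std::max(i + d, 0), nx - 1);
            else if (pass == 1) jj = std::min(std::max(j + d, 0), ny - 1);
            else ll = std::min(std::max(l + d, 0), nz - 1);
            s += k[d + r] * a[idx(ii, jj, ll)];
          }
          b[idx(i, j, l)] = s;
        }
    std::swap(a, b);
  }
  a.attr("dim") = dims;
  return a;
}
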