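// Core compiled routines: triangle-mesh scene with uniform subvolume grid,
// segment-triangle intersection queries, the random-walk engine, and the
// electrostatic-repulsion direction optimizer.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-free splittable RNG: one master seed spawns an independent stream
// per particle, so results do not depend on loop order.
// ---------------------------------------------------------------------------
static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoroshiro {
  uint64_t s0, s1;
  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master ^ (stream * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL);
    s0 = splitmix64(x);
    s1 = splitmix64(x);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  static inline uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  inline uint64_t next() {
    uint64_t a = s0, b = s1;
    uint64_t r = a + b;
    b ^= a;
    s0 = rotl(a, 24) ^ b ^ (b << 16);
    s1 = rotl(b, 37);
    return r;
  }
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// ---------------------------------------------------------------------------
// Scene data
// ---------------------------------------------------------------------------
struct Group {
  int nv = 0, nt = 0, ninst = 0;
  std::vector<double> verts;    // 3*nv, template coordinates (um)
  std::vector<int>    tris;     // 3*nt, 0-based vertex indices
  std::vector<double> centers;  // 3*ninst instance translations
  double perm = 0.0;
  bool polar = false;
  double h = 0.0, Dslow = 0.0, Dfast = 0.0;
  int inst_offset = 0;          // global instance id of instance 0
  // radial band of the template surface about its local origin: every
  // surface point s satisfies r_in <= |s| <= r_out (used to bound the
  // distance from a point to an instance's surface without touching tris)
  double r_in = 0.0, r_out = 0.0;
};

struct SceneData {
  std::vector<Group> groups;
  double lo[3], hi[3];
  int dims[3];
  double csz[3];                // cell sizes
  int boundary = 0;             // 0 reflective, 1 periodic
  double eps_len = 0.0;         // post-event nudge (um)
  bool any_polar = false;
  double max_h = 0.0;

  // global triangle table
  int64_t ntri = 0;
  std::vector<int32_t> tri_group, tri_inst, tri_local;
  std::vector<float> bb;        // 6 per tri: lo xyz, hi xyz

  // grid CSR
  std::vector<int64_t> cell_start;
  std::vector<int32_t> cell_items;

  // instance-center index for the polar-layer distance culling
  std::vector<double> ic_pos;        // 3 per instance
  std::vector<int32_t> ic_group;
  std::vector<int64_t> ic_start;     // CSR over a coarse center grid
  std::vector<int32_t> ic_items;
  int ic_dims[3] = { 1, 1, 1 };
  double ic_csz[3] = { 1, 1, 1 };
  double ic_search = 0.0;            // search radius; also the lb cap base
  double lb_cap = 1.0;               // distance lower-bound cap (um)

  // query stamps (dedupe across cells within one query)
  mutable std::vector<int32_t> stamp;
  mutable int32_t stamp_id = 0;

  inline int64_t cell_index(int ix, int iy, int iz) const {
    return (int64_t)ix + (int64_t)dims[0] * ((int64_t)iy + (int64_t)dims[1] * iz);
  }
  inline int clampi(int v, int n) const { return v < 0 ? 0 : (v >= n ? n - 1 : v); }
  inline void cell_of(const double *p, int *c) const {
    for (int a = 0; a < 3; ++a)
      c[a] = clampi((int)std::floor((p[a] - lo[a]) / csz[a]), dims[a]);
  }
  inline void tri_vertices(int64_t t, double *v0, double *v1, double *v2) const {
    const Group &g = groups[tri_group[t]];
    const double *ctr = &g.centers[3 * (size_t)tri_inst[t]];
    const int *tv = &g.tris[3 * (size_t)tri_local[t]];
    for (int a = 0; a < 3; ++a) {
      v0[a] = g.verts[3 * (size_t)tv[0] + a] + ctr[a];
      v1[a] = g.verts[3 * (size_t)tv[1] + a] + ctr[a];
      v2[a] = g.verts[3 * (size_t)tv[2] + a] + ctr[a];
    }
  }
  inline int32_t fresh_stamp() const {
    if (++stamp_id == 0) { std::fill(stamp.begin(), stamp.end(), 0); stamp_id = 1; }
    return stamp_id;
  }
};

// Moller-Trumbore segment-triangle intersection; t in (t_min, t_max].
static inline bool seg_tri(const double *o, const double *d, // origin, full segment vector
                           const double *v0, const double *v1, const double *v2,
                           double t_min, double t_max, double &t_out) {
  double e1[3], e2[3], pv[3], tv[3], qv[3];
  for (int a = 0; a < 3; ++a) { e1[a] = v1[a] - v0[a]; e2[a] = v2[a] - v0[a]; }
  pv[0] = d[1] * e2[2] - d[2] * e2[1];
  pv[1] = d[2] * e2[0] - d[0] * e2[2];
  pv[2] = d[0] * e2[1] - d[1] * e2[0];
  double det = e1[0] * pv[0] + e1[1] * pv[1] + e1[2] * pv[2];
  if (std::fabs(det) < 1e-300) return false;
  double inv = 1.0 / det;
  for (int a = 0; a < 3; ++a) tv[a] = o[a] - v0[a];
  double u = (tv[0] * pv[0] + tv[1] * pv[1] + tv[2] * pv[2]) * inv;
  if (u < -1e-12 || u > 1.0 + 1e-12) return false;
  qv[0] = tv[1] * e1[2] - tv[2] * e1[1];
  qv[1] = tv[2] * e1[0] - tv[0] * e1[2];
  qv[2] = tv[0] * e1[1] - tv[1] * e1[0];
  double v = (d[0] * qv[0] + d[1] * qv[1] + d[2] * qv[2]) * inv;
  if (v < -1e-12 || u + v > 1.0 + 1e-12) return false;
  double t = (e2[0] * qv[0] + e2[1] * qv[1] + e2[2] * qv[2]) * inv;
  if (t <= t_min || t > t_max) return false;
  t_out = t;
  return true;
}

// Squared distance from point to triangle (Ericson, Real-Time Collision Detection).
static inline double point_tri_dist2(const double *p, const double *a,
                                     const double *b, const double *c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  auto dist2 = [&](const double *q) {
    double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
    return dx * dx + dy * dy + dz * dz;
  };
  if (d1 <= 0.0 && d2 <= 0.0) return dist2(a);
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) return dist2(b);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    double q[3] = { a[0] + v * ab[0], a[1] + v * ab[1], a[2] + v * ab[2] };
    return dist2(q);
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) return dist2(c);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    double q[3] = { a[0] + w * ac[0], a[1] + w * ac[1], a[2] + w * ac[2] };
    return dist2(q);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double q[3] = { b[0] + w * (c[0] - b[0]), b[1] + w * (c[1] - b[1]), b[2] + w * (c[2] - b[2]) };
    return dist2(q);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double q[3] = { a[0] + ab[0] * v + ac[0] * w, a[1] + ab[1] * v + ac[1] * w,
                  a[2] + ab[2] * v + ac[2] * w };
  return dist2(q);
}

// ---------------------------------------------------------------------------
// Scene construction
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_scene_build(List groups, NumericVector lo, NumericVector hi,
                     IntegerVector dims, int boundary) {
  SceneData *S = new SceneData();
  for (int a = 0; a < 3; ++a) {
    S->lo[a] = lo[a]; S->hi[a] = hi[a]; S->dims[a] = dims[a];
    S->csz[a] = (hi[a] - lo[a]) / dims[a];
  }
  S->boundary = boundary;
  double dx = hi[0] - lo[0], dy = hi[1] - lo[1], dz = hi[2] - lo[2];
  S->eps_len = 1e-9 * std::sqrt(dx * dx + dy * dy + dz * dz);

  int64_t ntri = 0;
  int inst_off = 0;
  for (int gi = 0; gi < groups.size(); ++gi) {
    List gl = groups[gi];
    Group g;
    NumericMatrix V = gl["vertices"];
    IntegerMatrix T = gl["triangles"];   // 0-based
    NumericMatrix C = gl["centers"];
    g.nv = V.nrow(); g.nt = T.nrow(); g.ninst = C.nrow();
    g.verts.resize(3 * (size_t)g.nv);
    for (int i = 0; i < g.nv; ++i)
      for (int a = 0; a < 3; ++a) g.verts[3 * (size_t)i + a] = V(i, a);
    g.tris.resize(3 * (size_t)g.nt);
    for (int i = 0; i < g.nt; ++i)
      for (int a = 0; a < 3; ++a) g.tris[3 * (size_t)i + a] = T(i, a);
    g.centers.resize(3 * (size_t)g.ninst);
    for (int i = 0; i < g.ninst; ++i)
      for (int a = 0; a < 3; ++a) g.centers[3 * (size_t)i + a] = C(i, a);
    g.perm = as<double>(gl["permeability"]);
    g.polar = as<bool>(gl["polar"]);
    if (g.polar) {
      g.h = as<double>(gl["h"]);
      g.Dslow = as<double>(gl["Dslow"]);
      g.Dfast = as<double>(gl["Dfast"]);
      S->any_polar = true;
      S->max_h = std::max(S->max_h, g.h);
    }
    g.inst_offset = inst_off;
    inst_off += g.ninst;
    ntri += (int64_t)g.nt * g.ninst;
    // radial band of the template surface about the local origin
    double o[3] = { 0, 0, 0 };
    double rin2 = std::numeric_limits<double>::infinity(), rout2 = 0.0;
    for (int i = 0; i < g.nv; ++i) {
      double n2 = 0;
      for (int a = 0; a < 3; ++a) n2 += g.verts[3 * (size_t)i + a] * g.verts[3 * (size_t)i + a];
      rout2 = std::max(rout2, n2);
    }
    for (int t2 = 0; t2 < g.nt; ++t2) {
      const int *tv = &g.tris[3 * (size_t)t2];
      rin2 = std::min(rin2, point_tri_dist2(o, &g.verts[3 * (size_t)tv[0]],
                                            &g.verts[3 * (size_t)tv[1]],
                                            &g.verts[3 * (size_t)tv[2]]));
    }
    g.r_in = g.nt > 0 ? std::sqrt(rin2) : 0.0;
    g.r_out = std::sqrt(rout2);
    S->groups.push_back(std::move(g));
  }

  // instance-center index (polar-layer culling): covers every membrane
  // instance, since the layer is defined by distance to any surface
  if (S->any_polar) {
    for (size_t gi = 0; gi < S->groups.size(); ++gi) {
      const Group &g = S->groups[gi];
      for (int k = 0; k < g.ninst; ++k) {
        for (int a = 0; a < 3; ++a) S->ic_pos.push_back(g.centers[3 * (size_t)k + a]);
        S->ic_group.push_back((int32_t)gi);
      }
    }
    double max_band = 0.0;
    for (auto &g : S->groups) max_band = std::max(max_band, g.r_out + S->max_h);
    S->ic_search = max_band + S->lb_cap;
    int64_t nic = (int64_t)S->ic_group.size();
    for (int a = 0; a < 3; ++a) {
      double cs = std::max(S->ic_search / 2.0, (hi[a] - lo[a]) / 256.0);
      S->ic_dims[a] = std::max(1, (int)std::floor((hi[a] - lo[a]) / cs));
      S->ic_csz[a] = (hi[a] - lo[a]) / S->ic_dims[a];
    }
    int64_t nc = (int64_t)S->ic_dims[0] * S->ic_dims[1] * S->ic_dims[2];
    std::vector<int64_t> cnt(nc + 1, 0);
    auto ic_cell = [&](const double *p) {
      int c[3];
      for (int a = 0; a < 3; ++a) {
        int v = (int)std::floor((p[a] - S->lo[a]) / S->ic_csz[a]);
        c[a] = std::min(std::max(v, 0), S->ic_dims[a] - 1);
      }
      return (int64_t)c[0] + (int64_t)S->ic_dims[0] * (c[1] + (int64_t)S->ic_dims[1] * c[2]);
    };
    for (int64_t i = 0; i < nic; ++i) ++cnt[ic_cell(&S->ic_pos[3 * i]) + 1];
    S->ic_start.resize(nc + 1);
    S->ic_start[0] = 0;
    for (int64_t c = 0; c < nc; ++c) S->ic_start[c + 1] = S->ic_start[c] + cnt[c + 1];
    S->ic_items.resize(nic);
    std::vector<int64_t> fil(S->ic_start.begin(), S->ic_start.end() - 1);
    for (int64_t i = 0; i < nic; ++i)
      S->ic_items[fil[ic_cell(&S->ic_pos[3 * i])]++] = (int32_t)i;
  }

  S->ntri = ntri;
  S->tri_group.resize(ntri); S->tri_inst.resize(ntri); S->tri_local.resize(ntri);
  S->bb.resize(6 * (size_t)ntri);
  int64_t t = 0;
  for (size_t gi = 0; gi < S->groups.size(); ++gi) {
    const Group &g = S->groups[gi];
    for (int k = 0; k < g.ninst; ++k) {
      const double *ctr = &g.centers[3 * (size_t)k];
      for (int lt = 0; lt < g.nt; ++lt, ++t) {
        S->tri_group[t] = (int32_t)gi;
        S->tri_inst[t] = k;
        S->tri_local[t] = lt;
        const int *tv = &g.tris[3 * (size_t)lt];
        float *b = &S->bb[6 * (size_t)t];
        for (int a = 0; a < 3; ++a) { b[a] = 3.4e38f; b[3 + a] = -3.4e38f; }
        for (int j = 0; j < 3; ++j)
          for (int a = 0; a < 3; ++a) {
            float v = (float)(g.verts[3 * (size_t)tv[j] + a] + ctr[a]);
            if (v < b[a]) b[a] = v;
            if (v > b[3 + a]) b[3 + a] = v;
          }
      }
    }
  }

  // grid registration (two-pass CSR)
  int64_t ncell = (int64_t)S->dims[0] * S->dims[1] * S->dims[2];
  std::vector<int64_t> count(ncell + 1, 0);
  auto cell_range = [&](int64_t tt, int *c0, int *c1) {
    const float *b = &S->bb[6 * (size_t)tt];
    for (int a = 0; a < 3; ++a) {
      c0[a] = S->clampi((int)std::floor((b[a] - S->lo[a]) / S->csz[a]), S->dims[a]);
      c1[a] = S->clampi((int)std::floor((b[3 + a] - S->lo[a]) / S->csz[a]), S->dims[a]);
    }
  };
  for (int64_t tt = 0; tt < ntri; ++tt) {
    int c0[3], c1[3];
    cell_range(tt, c0, c1);
    for (int iz = c0[2]; iz <= c1[2]; ++iz)
      for (int iy = c0[1]; iy <= c1[1]; ++iy)
        for (int ix = c0[0]; ix <= c1[0]; ++ix)
          ++count[S->cell_index(ix, iy, iz) + 1];
  }
  S->cell_start.resize(ncell + 1);
  S->cell_start[0] = 0;
  for (int64_t c = 0; c < ncell; ++c) S->cell_start[c + 1] = S->cell_start[c] + count[c + 1];
  S->cell_items.resize(S->cell_start[ncell]);
  std::vector<int64_t> fill(S->cell_start.begin(), S->cell_start.end() - 1);
  for (int64_t tt = 0; tt < ntri; ++tt) {
    int c0[3], c1[3];
    cell_range(tt, c0, c1);
    for (int iz = c0[2]; iz <= c1[2]; ++iz)
      for (int iy = c0[1]; iy <= c1[1]; ++iy)
        for (int ix = c0[0]; ix <= c1[0]; ++ix)
          S->cell_items[fill[S->cell_index(ix, iy, iz)]++] = (int32_t)tt;
  }
  S->stamp.assign(ntri, 0);
  S->stamp_id = 0;

  XPtr<SceneData> ptr(S, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_scene_stats(SEXP scene) {
  XPtr<SceneData> S(scene);
  int64_t ncell = (int64_t)S->dims[0] * S->dims[1] * S->dims[2];
  int64_t nonempty = 0;
  for (int64_t c = 0; c < ncell; ++c)
    if (S->cell_start[c + 1] > S->cell_start[c]) ++nonempty;
  int ninst = 0;
  for (auto &g : S->groups) ninst += g.ninst;
  return List::create(_["n_triangles"] = (double)S->ntri,
                      _["n_instances"] = ninst,
                      _["n_registrations"] = (double)S->cell_items.size(),
                      _["n_cells"] = (double)ncell,
                      _["n_nonempty_cells"] = (double)nonempty);
}

// ---------------------------------------------------------------------------
// Grid traversal: first intersection of segment p0 -> p1 (3D DDA).
// Returns t in (t_min, 1], the global triangle, and candidate-test count.
// ---------------------------------------------------------------------------
struct Hit {
  bool found = false;
  double t = std::numeric_limits<double>::infinity();
  int64_t tri = -1;
  int64_t tested = 0;
};

static Hit grid_first_hit(const SceneData *S, const double *p0, const double *p1,
                          double t_min) {
  Hit h;
  if (S->ntri == 0) return h;
  double d[3];
  for (int a = 0; a < 3; ++a) d[a] = p1[a] - p0[a];
  double seg_lo[3], seg_hi[3];
  int32_t qs = S->fresh_stamp();

  int c[3];
  S->cell_of(p0, c);
  int step[3]; double t_next[3], t_delta[3];
  for (int a = 0; a < 3; ++a) {
    if (d[a] > 0) {
      step[a] = 1;
      double edge = S->lo[a] + (c[a] + 1) * S->csz[a];
      t_next[a] = (edge - p0[a]) / d[a];
      t_delta[a] = S->csz[a] / d[a];
    } else if (d[a] < 0) {
      step[a] = -1;
      double edge = S->lo[a] + c[a] * S->csz[a];
      t_next[a] = (edge - p0[a]) / d[a];
      t_delta[a] = -S->csz[a] / d[a];
    } else {
      step[a] = 0;
      t_next[a] = std::numeric_limits<double>::infinity();
      t_delta[a] = std::numeric_limits<double>::infinity();
    }
  }
  for (int a = 0; a < 3; ++a) {
    seg_lo[a] = std::min(p0[a], p1[a]);
    seg_hi[a] = std::max(p0[a], p1[a]);
  }

  while (true) {
    double t_exit = std::min(t_next[0], std::min(t_next[1], t_next[2]));
    int64_t ci = S->cell_index(c[0], c[1], c[2]);
    for (int64_t it = S->cell_start[ci]; it < S->cell_start[ci + 1]; ++it) {
      int32_t tt = S->cell_items[it];
      if (S->stamp[tt] == qs) continue;
      S->stamp[tt] = qs;
      ++h.tested;   // candidate triangles examined per query
      const float *b = &S->bb[6 * (size_t)tt];
      if (seg_lo[0] > b[3] || seg_hi[0] < b[0] ||
          seg_lo[1] > b[4] || seg_hi[1] < b[1] ||
          seg_lo[2] > b[5] || seg_hi[2] < b[2]) continue;
      double v0[3], v1[3], v2[3], t;
      S->tri_vertices(tt, v0, v1, v2);
      if (seg_tri(p0, d, v0, v1, v2, t_min, 1.0, t) && t < h.t) {
        h.t = t; h.tri = tt; h.found = true;
      }
    }
    if (h.found && h.t <= t_exit + 1e-12) break;
    if (t_exit >= 1.0) break;
    int axis = (t_next[0] <= t_next[1] && t_next[0] <= t_next[2]) ? 0
             : (t_next[1] <= t_next[2] ? 1 : 2);
    c[axis] += step[axis];
    if (c[axis] < 0 || c[axis] >= S->dims[axis]) break;
    t_next[axis] += t_delta[axis];
  }
  return h;
}

// [[Rcpp::export]]
List cpp_first_intersection(SEXP scene, NumericVector p0, NumericVector p1,
                            double t_min = 1e-12) {
  XPtr<SceneData> S(scene);
  double a[3] = { p0[0], p0[1], p0[2] }, b[3] = { p1[0], p1[1], p1[2] };
  Hit h = grid_first_hit(S, a, b, t_min);
  if (!h.found)
    return List::create(_["hit"] = false, _["tested"] = (double)h.tested);
  NumericVector pt(3);
  for (int i = 0; i < 3; ++i) pt[i] = a[i] + h.t * (b[i] - a[i]);
  int gi = S->tri_group[h.tri];
  return List::create(_["hit"] = true, _["t"] = h.t, _["point"] = pt,
                      _["triangle"] = (double)(h.tri + 1),
                      _["group"] = gi + 1,
                      _["instance"] = S->groups[gi].inst_offset + S->tri_inst[h.tri] + 1,
                      _["local_triangle"] = S->tri_local[h.tri] + 1,
                      _["tested"] = (double)h.tested);
}

// Which membrane instance contains each point (-1 if none): parity of
// crossings along a ray to the +z boundary, accumulated per instance.
// [[Rcpp::export]]
IntegerVector cpp_locate_points(SEXP scene, NumericMatrix pts) {
  XPtr<SceneData> S(scene);
  int n = pts.nrow();
  IntegerVector out(n);
  // tiny direction jitter avoids edge-aligned rays in lattice scenes
  std::vector<int64_t> hit_tris;
  for (int i = 0; i < n; ++i) {
    double p0[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    double far = (S->hi[2] - S->lo[2]) + (S->hi[0] - S->lo[0]);
    double p1[3] = { p0[0] + 1.000003e-4 * far, p0[1] + 1.700007e-4 * far, p0[2] + far };
    hit_tris.clear();
    // collect all crossings via repeated clipped queries would be O(k^2);
    // instead walk cells once and test every candidate (no early stop).
    double d[3] = { p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2] };
    int32_t qs = S->fresh_stamp();
    int c[3];
    S->cell_of(p0, c);
    int stepv[3]; double t_next[3], t_delta[3];
    for (int a = 0; a < 3; ++a) {
      if (d[a] > 0) {
        stepv[a] = 1;
        t_next[a] = (S->lo[a] + (c[a] + 1) * S->csz[a] - p0[a]) / d[a];
        t_delta[a] = S->csz[a] / d[a];
      } else if (d[a] < 0) {
        stepv[a] = -1;
        t_next[a] = (S->lo[a] + c[a] * S->csz[a] - p0[a]) / d[a];
        t_delta[a] = -S->csz[a] / d[a];
      } else {
        stepv[a] = 0;
        t_next[a] = t_delta[a] = std::numeric_limits<double>::infinity();
      }
    }
    while (true) {
      int64_t ci = S->cell_index(c[0], c[1], c[2]);
      for (int64_t it = S->cell_start[ci]; it < S->cell_start[ci + 1]; ++it) {
        int32_t tt = S->cell_items[it];
        if (S->stamp[tt] == qs) continue;
        S->stamp[tt] = qs;
        double v0[3], v1[3], v2[3], t;
        S->tri_vertices(tt, v0, v1, v2);
        if (seg_tri(p0, d, v0, v1, v2, 0.0, 1.0, t)) hit_tris.push_back(tt);
      }
      double t_exit = std::min(t_next[0], std::min(t_next[1], t_next[2]));
      if (t_exit >= 1.0) break;
      int axis = (t_next[0] <= t_next[1] && t_next[0] <= t_next[2]) ? 0
               : (t_next[1] <= t_next[2] ? 1 : 2);
      c[axis] += stepv[axis];
      if (c[axis] < 0 || c[axis] >= S->dims[axis]) break;
      t_next[axis] += t_delta[axis];
    }
    int found = -1;
    if (!hit_tris.empty()) {
      std::vector<std::pair<int, int>> parity; // global instance -> count
      for (int64_t tt : hit_tris) {
        int gi = S->tri_group[tt];
        int inst = S->groups[gi].inst_offset + S->tri_inst[tt];
        bool seen = false;
        for (auto &pr : parity)
          if (pr.first == inst) { pr.second++; seen = true; break; }
        if (!seen) parity.push_back({ inst, 1 });
      }
      for (auto &pr : parity)
        if (pr.second % 2 == 1) { found = pr.first; break; }
    }
    out[i] = found < 0 ? NA_INTEGER : found + 1;
  }
  return out;
}

// Minimum unsigned distance from each point to any membrane surface, searched
// within `radius`; Inf when no surface is that close.
static inline double min_dist_within(const SceneData *S, const double *p, double radius) {
  double best2 = std::numeric_limits<double>::infinity();
  double r2cap = radius * radius;
  int c0[3], c1[3];
  for (int a = 0; a < 3; ++a) {
    c0[a] = S->clampi((int)std::floor((p[a] - radius - S->lo[a]) / S->csz[a]), S->dims[a]);
    c1[a] = S->clampi((int)std::floor((p[a] + radius - S->lo[a]) / S->csz[a]), S->dims[a]);
  }
  int32_t qs = S->fresh_stamp();
  for (int iz = c0[2]; iz <= c1[2]; ++iz)
    for (int iy = c0[1]; iy <= c1[1]; ++iy)
      for (int ix = c0[0]; ix <= c1[0]; ++ix) {
        int64_t ci = S->cell_index(ix, iy, iz);
        for (int64_t it = S->cell_start[ci]; it < S->cell_start[ci + 1]; ++it) {
          int32_t tt = S->cell_items[it];
          if (S->stamp[tt] == qs) continue;
          S->stamp[tt] = qs;
          const float *b = &S->bb[6 * (size_t)tt];
          double dd = 0.0;
          for (int a = 0; a < 3; ++a) {
            double lo_d = b[a] - p[a], hi_d = p[a] - b[3 + a];
            double m = std::max(0.0, std::max(lo_d, hi_d));
            dd += m * m;
          }
          if (dd >= best2 || dd > r2cap) continue;
          double v0[3], v1[3], v2[3];
          S->tri_vertices(tt, v0, v1, v2);
          double d2 = point_tri_dist2(p, v0, v1, v2);
          if (d2 < best2) best2 = d2;
        }
      }
  return std::sqrt(best2);
}

// [[Rcpp::export]]
NumericVector cpp_min_distance(SEXP scene, NumericMatrix pts, double radius) {
  XPtr<SceneData> S(scene);
  NumericVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) {
    double p[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    out[i] = min_dist_within(S, p, radius);
  }
  return out;
}

// ---------------------------------------------------------------------------
// One diffusion step with membrane interactions: shared by the walk engine
// and the single-step interface. Returns final position, direction, label.
// ---------------------------------------------------------------------------
struct StepResult { int n_events = 0; bool aborted = false; };

static inline StepResult trace_step(const SceneData *S, Xoroshiro &rng,
                                    double *pos, double *dir, double len,
                                    int &label, double *wrap_off = nullptr) {
  StepResult res;
  double remaining = len;
  for (int guard = 0; guard < 100; ++guard) {
    if (remaining <= 0.0) return res;
    double target[3];
    for (int a = 0; a < 3; ++a) target[a] = pos[a] + dir[a] * remaining;

    // nearest boundary-wall crossing
    double t_wall = std::numeric_limits<double>::infinity();
    int wall_axis = -1, wall_side = 0;
    for (int a = 0; a < 3; ++a) {
      if (target[a] < S->lo[a] && dir[a] < 0) {
        double t = (S->lo[a] - pos[a]) / (dir[a] * remaining);
        if (t < t_wall) { t_wall = t; wall_axis = a; wall_side = -1; }
      } else if (target[a] > S->hi[a] && dir[a] > 0) {
        double t = (S->hi[a] - pos[a]) / (dir[a] * remaining);
        if (t < t_wall) { t_wall = t; wall_axis = a; wall_side = 1; }
      }
    }

    Hit h = grid_first_hit(S, pos, target, 1e-12);
    double t_mesh = h.found ? h.t : std::numeric_limits<double>::infinity();

    if (t_mesh >= t_wall && wall_axis >= 0) {
      // scene boundary first
      double travelled = t_wall * remaining;
      for (int a = 0; a < 3; ++a) pos[a] += dir[a] * remaining * t_wall;
      remaining -= travelled;
      ++res.n_events;
      if (S->boundary == 0) {             // reflective
        pos[wall_axis] = wall_side > 0 ? S->hi[wall_axis] : S->lo[wall_axis];
        dir[wall_axis] = -dir[wall_axis];
        for (int a = 0; a < 3; ++a) pos[a] += dir[a] * S->eps_len;
      } else {                            // periodic wrap
        double L = S->hi[wall_axis] - S->lo[wall_axis];
        double shift = wall_side > 0 ? -L : L;
        pos[wall_axis] += shift;
        if (wrap_off) wrap_off[wall_axis] -= shift;  // unwrapped = pos + off
        for (int a = 0; a < 3; ++a) pos[a] += dir[a] * S->eps_len;
      }
      continue;
    }
    if (!h.found) {
      for (int a = 0; a < 3; ++a) pos[a] = target[a];
      return res;
    }

    // membrane encounter
    double travelled = h.t * remaining;
    for (int a = 0; a < 3; ++a) pos[a] += dir[a] * remaining * h.t;
    remaining -= travelled;
    ++res.n_events;
    const Group &g = S->groups[S->tri_group[h.tri]];
    int inst = g.inst_offset + S->tri_inst[h.tri];
    bool transmit = g.perm >= 1.0 || (g.perm > 0.0 && rng.unif() < g.perm);
    if (transmit) {
      label = (label == inst + 1) ? 0 : inst + 1;  // 0 = extracellular
    } else {
      // specular reflection about the triangle normal
      double v0[3], v1[3], v2[3], n[3];
      S->tri_vertices(h.tri, v0, v1, v2);
      double e1[3], e2[3];
      for (int a = 0; a < 3; ++a) { e1[a] = v1[a] - v0[a]; e2[a] = v2[a] - v0[a]; }
      n[0] = e1[1] * e2[2] - e1[2] * e2[1];
      n[1] = e1[2] * e2[0] - e1[0] * e2[2];
      n[2] = e1[0] * e2[1] - e1[1] * e2[0];
      double nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
      if (nn > 0) {
        double dn = (dir[0] * n[0] + dir[1] * n[1] + dir[2] * n[2]) / (nn * nn);
        for (int a = 0; a < 3; ++a) dir[a] -= 2.0 * dn * n[a];
        double dl = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
        for (int a = 0; a < 3; ++a) dir[a] /= dl;
      }
    }
    for (int a = 0; a < 3; ++a) pos[a] += dir[a] * S->eps_len;
  }
  res.aborted = true;
  return res;
}

// local diffusivity at a position given the polar-layer model; the walker
// drifts at most r_max per step, so a lower bound d_lb on the distance to
// the nearest surface licenses skipping the next floor((d_lb - h)/r) - 1
// queries
static inline double local_diffusivity(const SceneData *S, const double *pos,
                                       double D_global, double r_max,
                                       int &skip_counter, bool &in_layer) {
  in_layer = false;
  if (!S->any_polar) return D_global;
  if (skip_counter > 0) { --skip_counter; return D_global; }
  double h = S->max_h;

  // radial-band lower bound from the instance-center index
  double lb = S->ic_search;  // no center within reach: at least this far
  int c0[3], c1[3];
  for (int a = 0; a < 3; ++a) {
    c0[a] = std::min(std::max((int)std::floor((pos[a] - S->ic_search - S->lo[a]) / S->ic_csz[a]), 0), S->ic_dims[a] - 1);
    c1[a] = std::min(std::max((int)std::floor((pos[a] + S->ic_search - S->lo[a]) / S->ic_csz[a]), 0), S->ic_dims[a] - 1);
  }
  for (int iz = c0[2]; iz <= c1[2]; ++iz)
    for (int iy = c0[1]; iy <= c1[1]; ++iy)
      for (int ix = c0[0]; ix <= c1[0]; ++ix) {
        int64_t ci = (int64_t)ix + (int64_t)S->ic_dims[0] * (iy + (int64_t)S->ic_dims[1] * iz);
        for (int64_t it = S->ic_start[ci]; it < S->ic_start[ci + 1]; ++it) {
          int32_t k = S->ic_items[it];
          const double *c = &S->ic_pos[3 * (size_t)k];
          double dx = pos[0] - c[0], dy = pos[1] - c[1], dz = pos[2] - c[2];
          double dc = std::sqrt(dx * dx + dy * dy + dz * dz);
          const Group &g = S->groups[S->ic_group[k]];
          double lbi = dc >= g.r_out ? dc - g.r_out
                      : (dc <= g.r_in ? g.r_in - dc : 0.0);
          if (lbi < lb) lb = lbi;
        }
      }
  if (lb > h) {
    int skip = (int)std::floor((lb - h) / r_max) - 1;
    if (skip > 0) skip_counter = skip;
    return D_global;
  }

  // within the ambiguous band: exact distance against the local triangles
  double d = min_dist_within(S, pos, h + 2.0 * r_max);
  if (d <= h) {
    in_layer = true;
    for (auto &g : S->groups) if (g.polar) return g.Dslow;
  }
  if (std::isfinite(d)) {
    int skip = (int)std::floor((d - h) / r_max) - 1;
    if (skip > 0) skip_counter = skip;
  } else {
    skip_counter = 1;   // searched to h + 2 r_max: safely fast for one more query
  }
  return D_global;
}

// ---------------------------------------------------------------------------
// Random-walk engine.
//   shapes:  n_steps x n_wave effective scalar gradient (T/m, sign includes
//            refocusing flips); orients: n_wave x 3 unit vectors.
//   Phase moments m[p,w] = sum_i shapes[i,w] * dot(orient_w, r_p(t_i)); the
//   caller applies gamma * t_s and unit conversions.
// [[Rcpp::export]]
List cpp_run_walk(SEXP scene, double D, double ts_us, int n_steps,
                  NumericMatrix directions, NumericMatrix init_pos,
                  IntegerVector init_label, NumericMatrix shapes,
                  NumericMatrix orients, int record_stride, double seed) {
  XPtr<SceneData> S(scene);
  int np = init_pos.nrow();
  int M = directions.nrow();
  int n_wave = orients.nrow();
  if (shapes.ncol() != n_wave && n_wave > 0)
    stop("shapes/orients waveform count mismatch");
  if (n_wave > 0 && shapes.nrow() < n_steps)
    stop("waveform shorter than the walk");

  // local copies for fast access
  std::vector<double> dirs(3 * (size_t)M);
  for (int i = 0; i < M; ++i)
    for (int a = 0; a < 3; ++a) dirs[3 * (size_t)i + a] = directions(i, a);
  std::vector<double> sh(n_wave * (size_t)n_steps);
  std::vector<double> orv(3 * (size_t)n_wave);
  for (int w = 0; w < n_wave; ++w) {
    for (int i = 0; i < n_steps; ++i) sh[(size_t)w * n_steps + i] = shapes(i, w);
    for (int a = 0; a < 3; ++a) orv[3 * (size_t)w + a] = orients(w, a);
  }

  int n_rec = record_stride > 0 ? n_steps / record_stride : 0;
  NumericVector traj(record_stride > 0 ? (R_xlen_t)np * 3 * n_rec : 0);
  NumericMatrix final_pos(np, 3);
  NumericMatrix moments(np, std::max(n_wave, 1));
  IntegerVector labels(np);
  NumericVector residence(np);
  IntegerVector aborts(1);

  uint64_t master = (uint64_t)seed;
  std::vector<double> m(n_wave);
  for (int p = 0; p < np; ++p) {
    Xoroshiro rng;
    rng.seed(master, (uint64_t)p + 1);
    double pos[3] = { init_pos(p, 0), init_pos(p, 1), init_pos(p, 2) };
    double off[3] = { 0, 0, 0 };   // periodic unwrap offset: true r = pos + off
    int label = init_label[p];
    std::fill(m.begin(), m.end(), 0.0);
    int in_layer_count = 0;
    int skip_counter = 0;
    double r_fast = std::sqrt(6.0 * D * ts_us);
    for (int i = 0; i < n_steps; ++i) {
      bool in_layer = false;
      double Dl = local_diffusivity(S, pos, D, r_fast, skip_counter, in_layer);
      if (in_layer) ++in_layer_count;
      double r = std::sqrt(6.0 * Dl * ts_us);   // mm^2/s * us == um^2/us -> um
      const double *u = &dirs[3 * (size_t)(rng.next() % (uint64_t)M)];
      double dir[3] = { u[0], u[1], u[2] };
      StepResult sr = trace_step(S, rng, pos, dir, r, label, off);
      if (sr.aborted) ++aborts[0];
      for (int w = 0; w < n_wave; ++w) {
        double g = sh[(size_t)w * n_steps + i];
        if (g != 0.0)
          m[w] += g * (orv[3 * (size_t)w] * (pos[0] + off[0]) +
                       orv[3 * (size_t)w + 1] * (pos[1] + off[1]) +
                       orv[3 * (size_t)w + 2] * (pos[2] + off[2]));
      }
      if (record_stride > 0 && (i + 1) % record_stride == 0) {
        int slot = (i + 1) / record_stride - 1;
        if (slot < n_rec)
          for (int a = 0; a < 3; ++a)
            traj[(R_xlen_t)slot * np * 3 + (R_xlen_t)p * 3 + a] = pos[a] + off[a];
      }
    }
    for (int a = 0; a < 3; ++a) final_pos(p, a) = pos[a];
    for (int w = 0; w < n_wave; ++w) moments(p, w) = m[w];
    labels[p] = label;
    residence[p] = n_steps > 0 ? (double)in_layer_count / n_steps : 0.0;
  }

  List out = List::create(_["final_pos"] = final_pos, _["moments"] = moments,
                          _["labels"] = labels, _["polar_residence"] = residence,
                          _["n_aborted_steps"] = aborts[0]);
  if (record_stride > 0) {
    traj.attr("dim") = IntegerVector::create(3, np, n_rec);
    out["trajectory"] = traj;
  }
  return out;
}

// Single explicit step for each particle (interaction-rule tests).
// [[Rcpp::export]]
List cpp_advance_particles(SEXP scene, NumericMatrix pos, IntegerVector label,
                           NumericMatrix dir, NumericVector len, double seed) {
  XPtr<SceneData> S(scene);
  int np = pos.nrow();
  NumericMatrix new_pos(np, 3), new_dir(np, 3);
  IntegerVector new_label(np), n_events(np);
  LogicalVector aborted(np);
  for (int p = 0; p < np; ++p) {
    Xoroshiro rng;
    rng.seed((uint64_t)seed, (uint64_t)p + 1);
    double ppos[3] = { pos(p, 0), pos(p, 1), pos(p, 2) };
    double pdir[3] = { dir(p, 0), dir(p, 1), dir(p, 2) };
    int lab = label[p];
    StepResult sr = trace_step(S, rng, ppos, pdir, len[p], lab);
    for (int a = 0; a < 3; ++a) { new_pos(p, a) = ppos[a]; new_dir(p, a) = pdir[a]; }
    new_label[p] = lab;
    n_events[p] = sr.n_events;
    aborted[p] = sr.aborted;
  }
  return List::create(_["position"] = new_pos, _["direction"] = new_dir,
                      _["label"] = new_label, _["n_events"] = n_events,
                      _["aborted"] = aborted);
}

// ---------------------------------------------------------------------------
// Electrostatic-repulsion direction optimizer (antipodally symmetric energy
// sum_{i<j} 1/|ui-uj| + 1/|ui+uj|), projected gradient descent with an
// adaptive step from a seeded random start.
// ---------------------------------------------------------------------------
static double energy_and_grad(const std::vector<double> &u, int n,
                              std::vector<double> &grad) {
  std::fill(grad.begin(), grad.end(), 0.0);
  double E = 0.0;
  for (int i = 0; i < n; ++i) {
    const double *ui = &u[3 * (size_t)i];
    for (int j = i + 1; j < n; ++j) {
      const double *uj = &u[3 * (size_t)j];
      double dm[3] = { ui[0] - uj[0], ui[1] - uj[1], ui[2] - uj[2] };
      double dp[3] = { ui[0] + uj[0], ui[1] + uj[1], ui[2] + uj[2] };
      double rm2 = dm[0] * dm[0] + dm[1] * dm[1] + dm[2] * dm[2];
      double rp2 = dp[0] * dp[0] + dp[1] * dp[1] + dp[2] * dp[2];
      double rm = std::sqrt(rm2), rp = std::sqrt(rp2);
      E += 1.0 / rm + 1.0 / rp;
      double cm = 1.0 / (rm2 * rm), cp = 1.0 / (rp2 * rp);
      for (int a = 0; a < 3; ++a) {
        double fm = dm[a] * cm, fp = dp[a] * cp;
        grad[3 * (size_t)i + a] -= fm + fp;
        grad[3 * (size_t)j + a] += fm - fp;
      }
    }
  }
  return E;
}

// [[Rcpp::export]]
List cpp_optimize_directions(int n, int max_iter, double seed, double tol) {
  std::vector<double> u(3 * (size_t)n), g(3 * (size_t)n),
      u_prev(3 * (size_t)n), g_prev(3 * (size_t)n);
  uint64_t st = (uint64_t)seed + 0x5DEECE66DULL;
  for (int i = 0; i < n; ++i) {
    // uniform on the sphere
    double z, x, y;
    do {
      uint64_t r1 = splitmix64(st), r2 = splitmix64(st);
      z = 2.0 * ((r1 >> 11) * (1.0 / 9007199254740992.0)) - 1.0;
      double phi = 2.0 * M_PI * ((r2 >> 11) * (1.0 / 9007199254740992.0));
      double s = std::sqrt(std::max(0.0, 1.0 - z * z));
      x = s * std::cos(phi); y = s * std::sin(phi);
    } while (x * x + y * y + z * z < 1e-12);
    u[3 * (size_t)i] = x; u[3 * (size_t)i + 1] = y; u[3 * (size_t)i + 2] = z;
  }
  // projected gradient descent with Barzilai-Borwein step sizes and an
  // energy-increase safeguard (halve the step and retry from the old point)
  double E_prev = std::numeric_limits<double>::infinity();
  double E = 0.0;
  double stepv = 0.0;
  bool have_prev = false, rejected = false;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    E = energy_and_grad(u, n, g);
    // tangent projection
    for (int i = 0; i < n; ++i) {
      double *ui = &u[3 * (size_t)i], *gi = &g[3 * (size_t)i];
      double dot = ui[0] * gi[0] + ui[1] * gi[1] + ui[2] * gi[2];
      for (int a = 0; a < 3; ++a) gi[a] -= dot * ui[a];
    }
    if (E > E_prev) {
      u = u_prev;
      g = g_prev;
      E = E_prev;
      stepv *= 0.5;
      rejected = true;
      if (stepv < 1e-18) break;
    } else {
      if (!rejected && have_prev && std::fabs(E_prev - E) < tol * std::fabs(E))
        { E_prev = E; break; }
      rejected = false;
      if (have_prev) {
        // BB1 step: <du, dg> / <dg, dg>
        double sy = 0.0, yy = 0.0;
        for (size_t j = 0; j < u.size(); ++j) {
          double du = u[j] - u_prev[j], dg = g[j] - g_prev[j];
          sy += du * dg;
          yy += dg * dg;
        }
        if (yy > 0 && sy > 0) stepv = sy / yy;
      } else {
        double gmax = 0.0;
        for (int i = 0; i < n; ++i) {
          double *gi = &g[3 * (size_t)i];
          double gn = std::sqrt(gi[0] * gi[0] + gi[1] * gi[1] + gi[2] * gi[2]);
          if (gn > gmax) gmax = gn;
        }
        stepv = gmax > 0 ? 0.05 / (std::sqrt((double)n) * gmax) : 0.0;
      }
      E_prev = E;
      u_prev = u;
      g_prev = g;
      have_prev = true;
    }
    for (int i = 0; i < n; ++i) {
      double *ui = &u[3 * (size_t)i];
      const double *gi = &g_prev[3 * (size_t)i];
      for (int a = 0; a < 3; ++a) ui[a] = u_prev[3 * (size_t)i + a] - stepv * gi[a];
      double nn = std::sqrt(ui[0] * ui[0] + ui[1] * ui[1] + ui[2] * ui[2]);
      for (int a = 0; a < 3; ++a) ui[a] /= nn;
    }
  }
  E = E_prev;
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) out(i, a) = u[3 * (size_t)i + a];
  return List::create(_["directions"] = out, _["energy"] = E,
                      _["iterations"] = it, _["converged"] = it < max_iter);
}

// Nearest-neighbor angle (degrees) for each direction in a table.
// [[Rcpp::export]]
NumericVector cpp_nn_angles(NumericMatrix dirs) {
  int n = dirs.nrow();
  std::vector<double> u(3 * (size_t)n);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) u[3 * (size_t)i + a] = dirs(i, a);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = -2.0;
    const double *ui = &u[3 * (size_t)i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double *uj = &u[3 * (size_t)j];
      double d = ui[0] * uj[0] + ui[1] * uj[1] + ui[2] * uj[2];
      if (d > best) best = d;
    }
    best = std::min(1.0, std::max(-1.0, best));
    out[i] = std::acos(best) * 180.0 / M_PI;
  }
  return out;
}
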