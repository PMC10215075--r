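// Compiled core: deterministic RNG, obstacle geometry with a uniform-grid
// spatial index, the stay-and-resample random walker, the Metropolis-style
// platelet perturbation and the O(N) per-lag MSD kernel.
//
// All lengths are nm, all times are s. The walker's step sigma is passed in
// nm. Geometry lists come from R as produced by as_geom_list().

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <sstream>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded via splitmix64, normals via Marsaglia polar.
// Self-contained so walker output is independent of R's global RNG state.
// ---------------------------------------------------------------------------
namespace {

struct RWRng {
  uint64_t s[4];
  bool have_spare;
  double spare;

  explicit RWRng(uint64_t seed) : have_spare(false), spare(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline double normal() {
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

inline uint64_t as_seed(double seed) {
  if (seed < 0) seed = -seed;
  return static_cast<uint64_t>(seed);
}

// ---------------------------------------------------------------------------
// Geometry
// ---------------------------------------------------------------------------

struct Geometry {
  // platelets: oriented boxes. rot stores the 3x3 rotation column-major,
  // columns = local (width, thickness, length) axes in the global W,T,L frame.
  int P;
  std::vector<double> c;    // 3P centers
  std::vector<double> h;    // 3P half dims
  std::vector<double> rot;  // 9P
  std::vector<double> aabb_lo, aabb_hi;  // 3P

  bool bounded;
  double R, R2, len;

  bool hex_on;
  double hex_s, hex_r, hex_r2, hex_H;

  int M;                       // explicit collagen cylinders (L-parallel)
  std::vector<double> cyl;     // 3M: w, t, radius

  // uniform grid over platelet AABBs
  double cell;
  double glo[3];
  int gn[3];
  std::vector<int> cell_start;  // CSR
  std::vector<int> cell_items;
  mutable std::vector<int> stamp;
  mutable int stamp_cur;

  inline int cell_index(int ix, int iy, int iz) const {
    return (iz * gn[1] + iy) * gn[0] + ix;
  }
  inline int clampi(int v, int lo, int hi) const {
    return v < lo ? lo : (v > hi ? hi : v);
  }

  void build_grid() {
    double lo[3], hi[3];
    bool any = false;
    for (int k = 0; k < 3; ++k) {
      lo[k] = 1e300;
      hi[k] = -1e300;
    }
    if (bounded) {
      lo[0] = -R;
      hi[0] = R;
      lo[1] = -R;
      hi[1] = R;
      lo[2] = 0.0;
      hi[2] = len;
      any = true;
    }
    for (int p = 0; p < P; ++p) {
      for (int k = 0; k < 3; ++k) {
        lo[k] = std::min(lo[k], aabb_lo[3 * p + k]);
        hi[k] = std::max(hi[k], aabb_hi[3 * p + k]);
      }
      any = true;
    }
    if (!any) {
      lo[0] = lo[1] = lo[2] = 0.0;
      hi[0] = hi[1] = hi[2] = 1.0;
    }
    cell = 8.0;
    for (int k = 0; k < 3; ++k) {
      glo[k] = lo[k] - 1.0;
      double span = hi[k] - glo[k] + 1.0;
      gn[k] = std::max(1, (int)std::ceil(span / cell));
    }
    const long ncell = (long)gn[0] * gn[1] * gn[2];
    std::vector<int> counts(ncell, 0);
    std::vector<int> plo(3 * P), phi(3 * P);
    for (int p = 0; p < P; ++p) {
      for (int k = 0; k < 3; ++k) {
        int a = clampi((int)std::floor((aabb_lo[3 * p + k] - glo[k]) / cell), 0,
                       gn[k] - 1);
        int b = clampi((int)std::floor((aabb_hi[3 * p + k] - glo[k]) / cell), 0,
                       gn[k] - 1);
        plo[3 * p + k] = a;
        phi[3 * p + k] = b;
      }
      for (int iz = plo[3 * p + 2]; iz <= phi[3 * p + 2]; ++iz)
        for (int iy = plo[3 * p + 1]; iy <= phi[3 * p + 1]; ++iy)
          for (int ix = plo[3 * p]; ix <= phi[3 * p]; ++ix)
            counts[cell_index(ix, iy, iz)]++;
    }
    cell_start.assign(ncell + 1, 0);
    for (long i = 0; i < ncell; ++i) cell_start[i + 1] = cell_start[i] + counts[i];
    cell_items.assign(cell_start[ncell], 0);
    std::vector<int> fill(ncell, 0);
    for (int p = 0; p < P; ++p) {
      for (int iz = plo[3 * p + 2]; iz <= phi[3 * p + 2]; ++iz)
        for (int iy = plo[3 * p + 1]; iy <= phi[3 * p + 1]; ++iy)
          for (int ix = plo[3 * p]; ix <= phi[3 * p]; ++ix) {
            long ci = cell_index(ix, iy, iz);
            cell_items[cell_start[ci] + fill[ci]++] = p;
          }
    }
    stamp.assign(P, -1);
    stamp_cur = 0;
  }

  inline bool point_in_platelet_id(const double* p, int id) const {
    const double* cc = &c[3 * id];
    const double* hh = &h[3 * id];
    const double* Rm = &rot[9 * id];
    const double d0 = p[0] - cc[0], d1 = p[1] - cc[1], d2 = p[2] - cc[2];
    for (int k = 0; k < 3; ++k) {
      const double l = d0 * Rm[3 * k] + d1 * Rm[3 * k + 1] + d2 * Rm[3 * k + 2];
      if (std::fabs(l) > hh[k]) return false;
    }
    return true;
  }

  bool point_in_any_platelet(const double* p) const {
    if (P == 0) return false;
    int ix = (int)std::floor((p[0] - glo[0]) / cell);
    int iy = (int)std::floor((p[1] - glo[1]) / cell);
    int iz = (int)std::floor((p[2] - glo[2]) / cell);
    if (ix < 0 || iy < 0 || iz < 0 || ix >= gn[0] || iy >= gn[1] || iz >= gn[2])
      return false;
    const long ci = cell_index(ix, iy, iz);
    for (int i = cell_start[ci]; i < cell_start[ci + 1]; ++i)
      if (point_in_platelet_id(p, cell_items[i])) return true;
    return false;
  }

  // squared 2D distance from point (w,t) to segment (a->b) projected in W,T
  static inline double seg_point_d2(double aw, double at, double bw, double bt,
                                    double pw, double pt) {
    const double dw = bw - aw, dt = bt - at;
    const double den = dw * dw + dt * dt;
    double u = 0.0;
    if (den > 0) {
      u = ((pw - aw) * dw + (pt - at) * dt) / den;
      u = u < 0 ? 0 : (u > 1 ? 1 : u);
    }
    const double ew = aw + u * dw - pw, et = at + u * dt - pt;
    return ew * ew + et * et;
  }

  bool point_in_collagen(const double* p) const {
    if (hex_on) {
      // nearest lattice point per rectangular sublattice is the rounded one
      for (int sub = 0; sub < 2; ++sub) {
        const double ow = sub ? hex_s * 0.5 : 0.0;
        const double ot = sub ? hex_H * 0.5 : 0.0;
        const double cw = ow + hex_s * std::round((p[0] - ow) / hex_s);
        const double ct = ot + hex_H * std::round((p[1] - ot) / hex_H);
        const double dw = p[0] - cw, dt = p[1] - ct;
        if (dw * dw + dt * dt <= hex_r2) return true;
      }
    }
    for (int m = 0; m < M; ++m) {
      const double dw = p[0] - cyl[3 * m], dt = p[1] - cyl[3 * m + 1];
      if (dw * dw + dt * dt <= cyl[3 * m + 2] * cyl[3 * m + 2]) return true;
    }
    return false;
  }

  bool segment_hits_collagen(const double* a, const double* b) const {
    if (hex_on) {
      const double wlo = std::min(a[0], b[0]) - hex_r,
                   whi = std::max(a[0], b[0]) + hex_r;
      const double tlo = std::min(a[1], b[1]) - hex_r,
                   thi = std::max(a[1], b[1]) + hex_r;
      for (int sub = 0; sub < 2; ++sub) {
        const double ow = sub ? hex_s * 0.5 : 0.0;
        const double ot = sub ? hex_H * 0.5 : 0.0;
        const int i0 = (int)std::ceil((wlo - ow) / hex_s);
        const int i1 = (int)std::floor((whi - ow) / hex_s);
        const int j0 = (int)std::ceil((tlo - ot) / hex_H);
        const int j1 = (int)std::floor((thi - ot) / hex_H);
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            const double cw = ow + i * hex_s, ct = ot + j * hex_H;
            if (seg_point_d2(a[0], a[1], b[0], b[1], cw, ct) <= hex_r2)
              return true;
          }
      }
    }
    for (int m = 0; m < M; ++m) {
      const double r = cyl[3 * m + 2];
      if (seg_point_d2(a[0], a[1], b[0], b[1], cyl[3 * m], cyl[3 * m + 1]) <=
          r * r)
        return true;
    }
    return false;
  }

  bool segment_hits_platelet_id(const double* a, const double* b,
                                int id) const {
    const double* cc = &c[3 * id];
    const double* hh = &h[3 * id];
    const double* Rm = &rot[9 * id];
    double p0[3], p1[3];
    for (int k = 0; k < 3; ++k) {
      const double da0 = a[0] - cc[0], da1 = a[1] - cc[1], da2 = a[2] - cc[2];
      const double db0 = b[0] - cc[0], db1 = b[1] - cc[1], db2 = b[2] - cc[2];
      p0[k] = da0 * Rm[3 * k] + da1 * Rm[3 * k + 1] + da2 * Rm[3 * k + 2];
      p1[k] = db0 * Rm[3 * k] + db1 * Rm[3 * k + 1] + db2 * Rm[3 * k + 2];
    }
    double tmin = 0.0, tmax = 1.0;
    for (int k = 0; k < 3; ++k) {
      const double d = p1[k] - p0[k];
      if (std::fabs(d) < 1e-14) {
        if (std::fabs(p0[k]) > hh[k]) return false;
      } else {
        double t1 = (-hh[k] - p0[k]) / d;
        double t2 = (hh[k] - p0[k]) / d;
        if (t1 > t2) std::swap(t1, t2);
        tmin = std::max(tmin, t1);
        tmax = std::min(tmax, t2);
        if (tmin > tmax) return false;
      }
    }
    return true;
  }

  bool segment_hits_platelets(const double* a, const double* b) const {
    if (P == 0) return false;
    double lo[3], hi[3];
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(a[k], b[k]);
      hi[k] = std::max(a[k], b[k]);
    }
    int i0[3], i1[3];
    for (int k = 0; k < 3; ++k) {
      i0[k] = (int)std::floor((lo[k] - glo[k]) / cell);
      i1[k] = (int)std::floor((hi[k] - glo[k]) / cell);
      if (i1[k] < 0 || i0[k] >= gn[k]) return false;
      i0[k] = clampi(i0[k], 0, gn[k] - 1);
      i1[k] = clampi(i1[k], 0, gn[k] - 1);
    }
    ++stamp_cur;
    for (int iz = i0[2]; iz <= i1[2]; ++iz)
      for (int iy = i0[1]; iy <= i1[1]; ++iy)
        for (int ix = i0[0]; ix <= i1[0]; ++ix) {
          const long ci = cell_index(ix, iy, iz);
          for (int i = cell_start[ci]; i < cell_start[ci + 1]; ++i) {
            const int id = cell_items[i];
            if (stamp[id] == stamp_cur) continue;
            stamp[id] = stamp_cur;
            if (segment_hits_platelet_id(a, b, id)) return true;
          }
        }
    return false;
  }

  // full spec semantics: inside any obstacle or outside the envelope
  bool point_blocked(const double* p, bool include_top) const {
    if (bounded) {
      if (p[0] * p[0] + p[1] * p[1] > R2) return true;
      if (p[2] < 0.0) return true;
      if (include_top && p[2] > len) return true;
    }
    if (point_in_any_platelet(p)) return true;
    return point_in_collagen(p);
  }

  // walker step acceptance: endpoint must stay inside the lateral/bottom
  // envelope (convexity makes endpoint checks sufficient); top is open so
  // the walker can terminate by crossing it; segment must miss all obstacles.
  bool step_blocked(const double* a, const double* b) const {
    if (bounded) {
      if (b[0] * b[0] + b[1] * b[1] > R2) return true;
      if (b[2] < 0.0) return true;
    }
    if (segment_hits_platelets(a, b)) return true;
    return segment_hits_collagen(a, b);
  }
};

Geometry geometry_from_list(List g) {
  Geometry G;
  NumericMatrix cen = g["centers"];
  NumericMatrix hd = g["halfdims"];
  NumericMatrix rt = g["rot"];
  G.P = cen.nrow();
  G.c.resize(3 * G.P);
  G.h.resize(3 * G.P);
  G.rot.resize(9 * G.P);
  for (int p = 0; p < G.P; ++p) {
    for (int k = 0; k < 3; ++k) {
      G.c[3 * p + k] = cen(p, k);
      G.h[3 * p + k] = hd(p, k);
    }
    for (int k = 0; k < 9; ++k) G.rot[9 * p + k] = rt(p, k);
  }
  G.aabb_lo.resize(3 * G.P);
  G.aabb_hi.resize(3 * G.P);
  for (int p = 0; p < G.P; ++p) {
    for (int i = 0; i < 3; ++i) {
      double e = 0.0;
      for (int k = 0; k < 3; ++k)
        e += std::fabs(G.rot[9 * p + 3 * k + i]) * G.h[3 * p + k];
      G.aabb_lo[3 * p + i] = G.c[3 * p + i] - e;
      G.aabb_hi[3 * p + i] = G.c[3 * p + i] + e;
    }
  }
  G.bounded = as<bool>(g["bounded"]);
  G.R = as<double>(g["radius"]);
  G.len = as<double>(g["length"]);
  G.R2 = G.R * G.R;
  G.hex_on = as<bool>(g["hex_on"]);
  G.hex_s = as<double>(g["hex_spacing"]);
  G.hex_r = as<double>(g["hex_radius"]);
  G.hex_r2 = G.hex_r * G.hex_r;
  G.hex_H = G.hex_s * std::sqrt(3.0);
  NumericMatrix cy = g["cylinders"];
  G.M = cy.nrow();
  G.cyl.resize(3 * G.M);
  for (int m = 0; m < G.M; ++m)
    for (int k = 0; k < 3; ++k) G.cyl[3 * m + k] = cy(m, k);
  G.build_grid();
  return G;
}

}  // namespace

// ---------------------------------------------------------------------------
// Exported geometry queries
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_point_blocked(List geom, NumericMatrix pts,
                                bool include_top = true) {
  Geometry G = geometry_from_list(geom);
  const int n = pts.nrow();
  LogicalVector out(n);
  double p[3];
  for (int i = 0; i < n; ++i) {
    p[0] = pts(i, 0);
    p[1] = pts(i, 1);
    p[2] = pts(i, 2);
    out[i] = G.point_blocked(p, include_top);
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_point_in_platelet(List geom, NumericMatrix pts) {
  Geometry G = geometry_from_list(geom);
  const int n = pts.nrow();
  LogicalVector out(n);
  double p[3];
  for (int i = 0; i < n; ++i) {
    p[0] = pts(i, 0);
    p[1] = pts(i, 1);
    p[2] = pts(i, 2);
    out[i] = G.point_in_any_platelet(p);
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_segment_blocked(List geom, NumericMatrix p0,
                                  NumericMatrix p1) {
  Geometry G = geometry_from_list(geom);
  const int n = p0.nrow();
  LogicalVector out(n);
  double a[3], b[3];
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      a[k] = p0(i, k);
      b[k] = p1(i, k);
    }
    bool hit = false;
    if (G.bounded) {
      // exits the envelope (either endpoint outside, incl. the top cap)
      for (int e = 0; e < 2 && !hit; ++e) {
        const double* q = e ? b : a;
        if (q[0] * q[0] + q[1] * q[1] > G.R2 || q[2] < 0.0 || q[2] > G.len)
          hit = true;
      }
    }
    if (!hit) hit = G.segment_hits_platelets(a, b);
    if (!hit) hit = G.segment_hits_collagen(a, b);
    out[i] = hit;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_volume_fraction(List geom, double n_samples, double seed) {
  Geometry G = geometry_from_list(geom);
  if (G.R <= 0 || G.len <= 0)
    stop("volume fraction requires positive envelope dimensions");
  RWRng rng(as_seed(seed));
  const long n = (long)n_samples;
  long inside = 0;
  double p[3];
  for (long i = 0; i < n; ++i) {
    const double r = G.R * std::sqrt(rng.unif());
    const double th = 2.0 * M_PI * rng.unif();
    p[0] = r * std::cos(th);
    p[1] = r * std::sin(th);
    p[2] = G.len * rng.unif();
    if (G.point_in_any_platelet(p)) ++inside;
  }
  return List::create(_["inside"] = (double)inside, _["n"] = (double)n);
}

// ---------------------------------------------------------------------------
// Walker
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_rw_normals(int n, double seed) {
  RWRng rng(as_seed(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.normal();
  return out;
}

static void advance_once(const Geometry& G, RWRng& rng, double sigma_nm,
                         double max_rejections, double* pos, double* out,
                         double* nrej) {
  double cand[3];
  double rej = 0.0;
  for (;;) {
    cand[0] = pos[0] + sigma_nm * rng.normal();
    cand[1] = pos[1] + sigma_nm * rng.normal();
    cand[2] = pos[2] + sigma_nm * rng.normal();
    if (!G.step_blocked(pos, cand)) break;
    rej += 1.0;
    if (rej >= max_rejections) {
      std::ostringstream ss;
      ss << "trapped walker: " << (long)rej
         << " consecutive rejected proposals at position (" << pos[0] << ", "
         << pos[1] << ", " << pos[2] << ") nm";
      stop(ss.str());
    }
  }
  out[0] = cand[0];
  out[1] = cand[1];
  out[2] = cand[2];
  *nrej = rej;
}

// [[Rcpp::export]]
List cpp_advance(List geom, NumericVector position, double sigma_nm,
                 double seed, double max_rejections) {
  Geometry G = geometry_from_list(geom);
  RWRng rng(as_seed(seed));
  double pos[3] = {position[0], position[1], position[2]};
  double out[3], nrej;
  advance_once(G, rng, sigma_nm, max_rejections, pos, out, &nrej);
  return List::create(_["position"] = NumericVector::create(out[0], out[1],
                                                            out[2]),
                      _["n_rejections"] = nrej);
}

// [[Rcpp::export]]
List cpp_simulate(List geom, double sigma_nm, double stop_L, double max_steps,
                  double max_rejections, double seed, int record_stride,
                  Nullable<NumericVector> start = R_NilValue) {
  Geometry G = geometry_from_list(geom);
  RWRng rng(as_seed(seed));

  double pos[3] = {0.0, 0.0, 0.0};
  if (start.isNotNull()) {
    NumericVector s(start);
    pos[0] = s[0];
    pos[1] = s[1];
    pos[2] = s[2];
    if (G.point_blocked(pos, false)) stop("start position is blocked");
  } else if (G.bounded) {
    // uniform over the un-blocked disc at L = 0
    bool ok = false;
    for (long tries = 0; tries < 1000000; ++tries) {
      const double w = G.R * (2.0 * rng.unif() - 1.0);
      const double t = G.R * (2.0 * rng.unif() - 1.0);
      if (w * w + t * t > G.R2) continue;
      pos[0] = w;
      pos[1] = t;
      pos[2] = 0.0;
      if (!G.point_blocked(pos, false)) {
        ok = true;
        break;
      }
    }
    if (!ok) stop("could not sample an un-blocked start position at L = 0");
  }
  // unbounded fixture: start at the origin, no draws consumed

  std::vector<double> rec;
  rec.reserve(3 * 4096);
  rec.push_back(pos[0]);
  rec.push_back(pos[1]);
  rec.push_back(pos[2]);

  double total_rej = 0.0, nrej = 0.0;
  double cand[3];
  long steps = 0;
  std::string termination = "max_steps";
  const long nmax = (long)max_steps;
  if (pos[2] >= stop_L) {
    termination = "reached";  // start plane already at/above the stop plane
  } else
  for (long s = 1; s <= nmax; ++s) {
    advance_once(G, rng, sigma_nm, max_rejections, pos, cand, &nrej);
    total_rej += nrej;
    pos[0] = cand[0];
    pos[1] = cand[1];
    pos[2] = cand[2];
    steps = s;
    const bool reached = pos[2] >= stop_L;
    if (s % record_stride == 0 || reached) {
      rec.push_back(pos[0]);
      rec.push_back(pos[1]);
      rec.push_back(pos[2]);
    }
    if (reached) {
      termination = "reached";
      break;
    }
  }

  const long nrec = (long)rec.size() / 3;
  NumericMatrix positions(nrec, 3);
  for (long i = 0; i < nrec; ++i) {
    positions(i, 0) = rec[3 * i];
    positions(i, 1) = rec[3 * i + 1];
    positions(i, 2) = rec[3 * i + 2];
  }
  return List::create(_["positions"] = positions, _["n_steps"] = (double)steps,
                      _["n_rejections"] = total_rej,
                      _["termination"] = termination);
}

// ---------------------------------------------------------------------------
// Platelet perturbation (random single-platelet trial moves with rejection)
// ---------------------------------------------------------------------------

namespace {

// separating-axis test for two oriented boxes; touching (within eps) does not
// count as overlap so exact lattice gaps are legal
bool obb_overlap(const double* c1, const double* R1, const double* h1,
                 const double* c2, const double* R2, const double* h2) {
  const double EPS = 1e-9;
  double Rm[3][3], AbsR[3][3], t[3], tl[3];
  // rotation of 2 expressed in 1's frame: Rm = R1^T R2
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += R1[3 * i + k] * R2[3 * j + k];
      Rm[i][j] = s;
      AbsR[i][j] = std::fabs(s) + 1e-12;
    }
  for (int k = 0; k < 3; ++k) t[k] = c2[k] - c1[k];
  for (int i = 0; i < 3; ++i)
    tl[i] = t[0] * R1[3 * i] + t[1] * R1[3 * i + 1] + t[2] * R1[3 * i + 2];
  // axes of box 1
  for (int i = 0; i < 3; ++i) {
    const double ra = h1[i];
    const double rb = h2[0] * AbsR[i][0] + h2[1] * AbsR[i][1] + h2[2] * AbsR[i][2];
    if (std::fabs(tl[i]) >= ra + rb - EPS) return false;
  }
  // axes of box 2
  for (int j = 0; j < 3; ++j) {
    const double ra = h1[0] * AbsR[0][j] + h1[1] * AbsR[1][j] + h1[2] * AbsR[2][j];
    const double rb = h2[j];
    const double tp = tl[0] * Rm[0][j] + tl[1] * Rm[1][j] + tl[2] * Rm[2][j];
    if (std::fabs(tp) >= ra + rb - EPS) return false;
  }
  // cross products
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      const int i1 = (i + 1) % 3, i2 = (i + 2) % 3;
      const int j1 = (j + 1) % 3, j2 = (j + 2) % 3;
      const double ra = h1[i1] * AbsR[i2][j] + h1[i2] * AbsR[i1][j];
      const double rb = h2[j1] * AbsR[i][j2] + h2[j2] * AbsR[i][j1];
      const double tp = tl[i2] * Rm[i1][j] - tl[i1] * Rm[i2][j];
      if (std::fabs(tp) >= ra + rb - EPS) return false;
    }
  return true;
}

inline void mat_mul3(const double* A, const double* B, double* C) {
  // column-major 3x3: C = A %*% B
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += A[3 * k + i] * B[3 * j + k];
      C[3 * j + i] = s;
    }
}

inline void orthonormalize(double* Rm) {  // Gram-Schmidt on columns
  for (int j = 0; j < 3; ++j) {
    for (int k = 0; k < j; ++k) {
      double d = 0.0;
      for (int i = 0; i < 3; ++i) d += Rm[3 * j + i] * Rm[3 * k + i];
      for (int i = 0; i < 3; ++i) Rm[3 * j + i] -= d * Rm[3 * k + i];
    }
    double n = 0.0;
    for (int i = 0; i < 3; ++i) n += Rm[3 * j + i] * Rm[3 * j + i];
    n = std::sqrt(n);
    for (int i = 0; i < 3; ++i) Rm[3 * j + i] /= n;
  }
}

inline void small_rotation(double a, double b, double c, double* Rm) {
  // Rz(c) Ry(b) Rx(a), column-major
  const double ca = std::cos(a), sa = std::sin(a);
  const double cb = std::cos(b), sb = std::sin(b);
  const double cc = std::cos(c), sc = std::sin(c);
  Rm[0] = cb * cc;
  Rm[1] = cb * sc;
  Rm[2] = -sb;
  Rm[3] = sa * sb * cc - ca * sc;
  Rm[4] = sa * sb * sc + ca * cc;
  Rm[5] = sa * cb;
  Rm[6] = ca * sb * cc + sa * sc;
  Rm[7] = ca * sb * sc - sa * cc;
  Rm[8] = ca * cb;
}

struct PerturbGrid {
  double cell;
  double lo[3];
  int n[3];
  std::vector<std::vector<int> > cells;
  inline long idx(int ix, int iy, int iz) const {
    return ((long)iz * n[1] + iy) * n[0] + ix;
  }
  inline int clampi(int v, int hi) const {
    return v < 0 ? 0 : (v >= hi ? hi - 1 : v);
  }
  void range(const double* alo, const double* ahi, int* i0, int* i1) const {
    for (int k = 0; k < 3; ++k) {
      i0[k] = clampi((int)std::floor((alo[k] - lo[k]) / cell), n[k]);
      i1[k] = clampi((int)std::floor((ahi[k] - lo[k]) / cell), n[k]);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_perturb(List geom, double n_moves, double max_translation,
                 double max_rotation, double max_inclination, double seed,
                 NumericVector max_displacement) {
  NumericMatrix cen0 = geom["centers"];
  NumericMatrix hd0 = geom["halfdims"];
  NumericMatrix rt0 = geom["rot"];
  const bool bounded = as<bool>(geom["bounded"]);
  const double R = as<double>(geom["radius"]);
  const double len = as<double>(geom["length"]);
  const int P = cen0.nrow();
  RWRng rng(as_seed(seed));

  std::vector<double> c(3 * P), h(3 * P), rot(9 * P), br(P);
  std::vector<double> alo(3 * P), ahi(3 * P);
  for (int p = 0; p < P; ++p) {
    for (int k = 0; k < 3; ++k) {
      c[3 * p + k] = cen0(p, k);
      h[3 * p + k] = hd0(p, k);
    }
    for (int k = 0; k < 9; ++k) rot[9 * p + k] = rt0(p, k);
    br[p] = std::sqrt(h[3 * p] * h[3 * p] + h[3 * p + 1] * h[3 * p + 1] +
                      h[3 * p + 2] * h[3 * p + 2]);
  }
  auto update_aabb = [&](int p, const double* cc, const double* Rm) {
    for (int i = 0; i < 3; ++i) {
      double e = 0.0;
      for (int k = 0; k < 3; ++k) e += std::fabs(Rm[3 * k + i]) * h[3 * p + k];
      alo[3 * p + i] = cc[i] - e;
      ahi[3 * p + i] = cc[i] + e;
    }
  };
  for (int p = 0; p < P; ++p) update_aabb(p, &c[3 * p], &rot[9 * p]);

  // dynamic AABB occupancy grid: AABB-intersecting pairs always share a cell
  PerturbGrid grid;
  grid.cell = 40.0;
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  if (bounded) {
    lo[0] = lo[1] = -R;
    hi[0] = hi[1] = R;
    lo[2] = 0;
    hi[2] = len;
  }
  for (int p = 0; p < P; ++p)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], alo[3 * p + k]);
      hi[k] = std::max(hi[k], ahi[3 * p + k]);
    }
  if (P == 0 && !bounded) {
    lo[0] = lo[1] = lo[2] = 0;
    hi[0] = hi[1] = hi[2] = 1;
  }
  for (int k = 0; k < 3; ++k) {
    grid.lo[k] = lo[k] - 2.0 * max_translation - 2.0;
    const double span = hi[k] - grid.lo[k] + 2.0 * max_translation + 2.0;
    grid.n[k] = std::max(1, (int)std::ceil(span / grid.cell));
  }
  grid.cells.assign((long)grid.n[0] * grid.n[1] * grid.n[2],
                    std::vector<int>());
  auto grid_insert = [&](int p) {
    int i0[3], i1[3];
    grid.range(&alo[3 * p], &ahi[3 * p], i0, i1);
    for (int iz = i0[2]; iz <= i1[2]; ++iz)
      for (int iy = i0[1]; iy <= i1[1]; ++iy)
        for (int ix = i0[0]; ix <= i1[0]; ++ix)
          grid.cells[grid.idx(ix, iy, iz)].push_back(p);
  };
  auto grid_remove = [&](int p) {
    int i0[3], i1[3];
    grid.range(&alo[3 * p], &ahi[3 * p], i0, i1);
    for (int iz = i0[2]; iz <= i1[2]; ++iz)
      for (int iy = i0[1]; iy <= i1[1]; ++iy)
        for (int ix = i0[0]; ix <= i1[0]; ++ix) {
          std::vector<int>& v = grid.cells[grid.idx(ix, iy, iz)];
          for (size_t q = 0; q < v.size(); ++q)
            if (v[q] == p) {
              v[q] = v.back();
              v.pop_back();
              break;
            }
        }
  };
  for (int p = 0; p < P; ++p) grid_insert(p);

  std::vector<int> stamp(P, -1);
  int stamp_cur = 0;
  double n_accepted = 0.0;
  const long NM = (long)n_moves;
  double newc[3], dR[9], newR[9], nlo[3], nhi[3];

  // anchor: platelets stay within max_displacement of their lattice site so
  // the staggered arrangement (and the mineral density) is preserved
  std::vector<double> c0(c);
  for (long mv = 0; mv < NM; ++mv) {
    if (P == 0) break;
    const int p = (int)(rng.next() % (uint64_t)P);
    bool off_site = false;
    for (int k = 0; k < 3; ++k) {
      newc[k] = c[3 * p + k] + max_translation * (2.0 * rng.unif() - 1.0);
      if (std::fabs(newc[k] - c0[3 * p + k]) > max_displacement[k])
        off_site = true;
    }
    if (off_site) continue;
    const double a = max_rotation * (2.0 * rng.unif() - 1.0);
    const double b = max_rotation * (2.0 * rng.unif() - 1.0);
    const double g = max_rotation * (2.0 * rng.unif() - 1.0);
    small_rotation(a, b, g, dR);
    mat_mul3(dR, &rot[9 * p], newR);
    orthonormalize(newR);

    // inclination of the platelet long (local length) axis w.r.t. global L
    const double uz = std::fabs(newR[8]);
    const double incl = std::acos(uz > 1.0 ? 1.0 : uz);
    if (incl > max_inclination) continue;

    // keep the platelet attached to the envelope region
    for (int i = 0; i < 3; ++i) {
      double e = 0.0;
      for (int k = 0; k < 3; ++k)
        e += std::fabs(newR[3 * k + i]) * h[3 * p + k];
      nlo[i] = newc[i] - e;
      nhi[i] = newc[i] + e;
    }
    if (bounded) {
      if (nhi[0] < -R || nlo[0] > R || nhi[1] < -R || nlo[1] > R ||
          nhi[2] < 0 || nlo[2] > len)
        continue;
      if (std::sqrt(newc[0] * newc[0] + newc[1] * newc[1]) > R + br[p])
        continue;
    }

    // overlap against neighbours sharing a grid cell with the new AABB
    int i0[3], i1[3];
    grid.range(nlo, nhi, i0, i1);
    ++stamp_cur;
    bool overlap = false;
    for (int iz = i0[2]; iz <= i1[2] && !overlap; ++iz)
      for (int iy = i0[1]; iy <= i1[1] && !overlap; ++iy)
        for (int ix = i0[0]; ix <= i1[0] && !overlap; ++ix) {
          const std::vector<int>& v = grid.cells[grid.idx(ix, iy, iz)];
          for (size_t q = 0; q < v.size(); ++q) {
            const int j = v[q];
            if (j == p || stamp[j] == stamp_cur) continue;
            stamp[j] = stamp_cur;
            const double dx = newc[0] - c[3 * j], dy = newc[1] - c[3 * j + 1],
                         dz = newc[2] - c[3 * j + 2];
            if (dx * dx + dy * dy + dz * dz > (br[p] + br[j]) * (br[p] + br[j]))
              continue;
            if (obb_overlap(newc, newR, &h[3 * p], &c[3 * j], &rot[9 * j],
                            &h[3 * j])) {
              overlap = true;
              break;
            }
          }
        }
    if (overlap) continue;

    grid_remove(p);
    for (int k = 0; k < 3; ++k) c[3 * p + k] = newc[k];
    for (int k = 0; k < 9; ++k) rot[9 * p + k] = newR[k];
    update_aabb(p, &c[3 * p], &rot[9 * p]);
    grid_insert(p);
    n_accepted += 1.0;
  }

  NumericMatrix cen(P, 3), rt(P, 9);
  NumericVector incl(P);
  for (int p = 0; p < P; ++p) {
    for (int k = 0; k < 3; ++k) cen(p, k) = c[3 * p + k];
    for (int k = 0; k < 9; ++k) rt(p, k) = rot[9 * p + k];
    const double uz = std::fabs(rot[9 * p + 8]);
    incl[p] = std::acos(uz > 1.0 ? 1.0 : uz);
  }
  return List::create(_["centers"] = cen, _["rot"] = rt,
                      _["inclination"] = incl, _["n_accepted"] = n_accepted);
}

// ---------------------------------------------------------------------------
// Analysis kernels
// ---------------------------------------------------------------------------

// time-averaged MSD at the requested lags (overlapping-pair average)
// [[Rcpp::export]]
NumericVector cpp_msd_at_lags(NumericMatrix pos, IntegerVector lags) {
  const long N = pos.nrow();
  const int L = lags.size();
  NumericVector out(L);
  const double* x = &pos(0, 0);
  const double* y = &pos(0, 1);
  const double* z = &pos(0, 2);
  for (int l = 0; l < L; ++l) {
    const long n = lags[l];
    if (n < 1 || n >= N) stop("lag out of range 1..N-1");
    double s = 0.0;
    const long m = N - n;
    for (long j = 0; j < m; ++j) {
      const double dx = x[j + n] - x[j];
      const double dy = y[j + n] - y[j];
      const double dz = z[j + n] - z[j];
      s += dx * dx + dy * dy + dz * dz;
    }
    out[l] = s / (double)m;
  }
  return out;
}

// sum of consecutive segment lengths (effective path length, nm)
// [[Rcpp::export]]
double cpp_path_length(NumericMatrix pos) {
  const long N = pos.nrow();
  const double* x = &pos(0, 0);
  const double* y = &pos(0, 1);
  const double* z = &pos(0, 2);
  double s = 0.0;
  for (long j = 1; j < N; ++j) {
    const double dx = x[j] - x[j - 1];
    const double dy = y[j] - y[j - 1];
    const double dz = z[j] - z[j - 1];
    s += std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  return s;
}
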