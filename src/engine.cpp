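// Compiled numerics for the Brownian-dynamics arrival simulator:
//  - GJK support-function distance between convex polytopes (exact for
//    polytopes up to termination tolerance; witness points + supporting
//    vertex sets returned)
//  - static AABB binary tree over placed dimers (broad phase)
//  - the per-molecule trajectory loop (dynamic time step, move rejection
//    on collision, stereospecific arrival detection)
//  - free-diffusion / rotational-decorrelation / absorbing-sphere
//    reference simulations used by the property tests
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
// splitmix64 + xoshiro256** ; one independent stream per molecule derived
// from (master seed, replicate, molecule), so ensembles are order
// independent and mergeable.
static inline uint64_t sm64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
struct Rng {
  uint64_t s[4];
  bool has_spare; double spare;
  void seed(uint64_t x) {
    has_spare = false;
    for (int i = 0; i < 4; i++) s[i] = sm64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double gauss() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0; v = 2.0 * unif() - 1.0; s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double m = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * m; has_spare = true;
    return u * m;
  }
};
static inline uint64_t stream_seed(uint64_t master, uint64_t rep,
                                   uint64_t mol) {
  uint64_t x = master;
  uint64_t a = sm64(x);
  uint64_t y = a ^ (rep * 0xD1342543DE82EF95ULL + mol * 0x9E3779B97F4A7C15ULL
                    + 0x632BE59BD9B4E019ULL);
  return sm64(y);
}

// ---------------------------------------------------------- small algebra
struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { V3 r{x, y, z}; return r; }
static inline V3 operator+(V3 a, V3 b) { return v3(a.x+b.x, a.y+b.y, a.z+b.z); }
static inline V3 operator-(V3 a, V3 b) { return v3(a.x-b.x, a.y-b.y, a.z-b.z); }
static inline V3 operator*(double s, V3 a) { return v3(s*a.x, s*a.y, s*a.z); }
static inline double dot(V3 a, V3 b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 cross(V3 a, V3 b) {
  return v3(a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x);
}
static inline double norm2(V3 a) { return dot(a, a); }

struct Quat { double w, x, y, z; };
static inline Quat qmul(const Quat &a, const Quat &b) {
  Quat r;
  r.w = a.w*b.w - a.x*b.x - a.y*b.y - a.z*b.z;
  r.x = a.w*b.x + a.x*b.w + a.y*b.z - a.z*b.y;
  r.y = a.w*b.y - a.x*b.z + a.y*b.w + a.z*b.x;
  r.z = a.w*b.z + a.x*b.y - a.y*b.x + a.z*b.w;
  return r;
}
static inline void qnormalize(Quat &q) {
  double n = std::sqrt(q.w*q.w + q.x*q.x + q.y*q.y + q.z*q.z);
  q.w /= n; q.x /= n; q.y /= n; q.z /= n;
}
static inline void qtomat(const Quat &q, double R[9]) {
  double w=q.w, x=q.x, y=q.y, z=q.z;
  R[0]=1-2*(y*y+z*z); R[1]=2*(x*y-w*z);   R[2]=2*(x*z+w*y);
  R[3]=2*(x*y+w*z);   R[4]=1-2*(x*x+z*z); R[5]=2*(y*z-w*x);
  R[6]=2*(x*z-w*y);   R[7]=2*(y*z+w*x);   R[8]=1-2*(x*x+y*y);
}
static inline Quat qfromrotvec(V3 v) {
  double th = std::sqrt(norm2(v));
  Quat q;
  if (th < 1e-300) { q.w = 1; q.x = q.y = q.z = 0; return q; }
  double s = std::sin(th / 2) / th;
  q.w = std::cos(th / 2); q.x = s*v.x; q.y = s*v.y; q.z = s*v.z;
  return q;
}
static inline V3 rot(const double R[9], V3 p) {
  return v3(R[0]*p.x + R[1]*p.y + R[2]*p.z,
            R[3]*p.x + R[4]*p.y + R[5]*p.z,
            R[6]*p.x + R[7]*p.y + R[8]*p.z);
}
static inline V3 rotT(const double R[9], V3 p) {
  return v3(R[0]*p.x + R[3]*p.y + R[6]*p.z,
            R[1]*p.x + R[4]*p.y + R[7]*p.z,
            R[2]*p.x + R[5]*p.y + R[8]*p.z);
}

// -------------------------------------------------------------- GJK -----
struct ShapeRef {           // posed convex vertex cloud
  const double *v; int n;   // body vertices, n x 3 column-major from R
  double R[9]; V3 t;
  inline V3 vert(int i) const {
    return rot(R, v3(v[i], v[i + n], v[i + 2 * n])) + t;
  }
  inline int support(V3 d) const {
    V3 dl = rotT(R, d);
    int best = 0;
    double bv = v[0]*dl.x + v[n]*dl.y + v[2*n]*dl.z;
    for (int i = 1; i < n; i++) {
      double s = v[i]*dl.x + v[i+n]*dl.y + v[i+2*n]*dl.z;
      if (s > bv) { bv = s; best = i; }
    }
    return best;
  }
};

struct SimplexVert { V3 w, a, b; int ia, ib; };

// closest point to the origin on a simplex of 1..4 vertices; reduces the
// simplex to the supporting subset and writes barycentric weights.
// returns true when the origin is contained (overlap).
static bool simplex_closest(SimplexVert W[4], int &n, V3 &v, double lam[4]) {
  if (n == 1) { v = W[0].w; lam[0] = 1; return false; }
  if (n == 2) {
    V3 a = W[0].w, b = W[1].w, ab = b - a;
    double t = -dot(a, ab), d = norm2(ab);
    if (d <= 1e-300 || t <= 0) { n = 1; lam[0] = 1; v = a; return false; }
    if (t >= d) { W[0] = W[1]; n = 1; lam[0] = 1; v = W[0].w; return false; }
    t /= d; lam[0] = 1 - t; lam[1] = t; v = (1 - t) * a + t * b;
    return false;
  }
  if (n == 3) {
    V3 a = W[0].w, b = W[1].w, c = W[2].w;
    V3 ab = b - a, ac = c - a, ap = v3(0,0,0) - a;
    double d1 = dot(ab, ap), d2 = dot(ac, ap);
    if (d1 <= 0 && d2 <= 0) { n = 1; lam[0] = 1; v = a; return false; }
    V3 bp = v3(0,0,0) - b;
    double d3 = dot(ab, bp), d4 = dot(ac, bp);
    if (d3 >= 0 && d4 <= d3) { W[0] = W[1]; n = 1; lam[0] = 1; v = W[0].w;
      return false; }
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0 && d1 >= 0 && d3 <= 0 && d1 - d3 > 1e-300) {
      double t = d1 / (d1 - d3);
      n = 2; lam[0] = 1 - t; lam[1] = t; v = (1 - t) * a + t * b;
      return false;
    }
    V3 cp = v3(0,0,0) - c;
    double d5 = dot(ab, cp), d6 = dot(ac, cp);
    if (d6 >= 0 && d5 <= d6) { W[0] = W[2]; n = 1; lam[0] = 1; v = W[0].w;
      return false; }
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0 && d2 >= 0 && d6 <= 0 && d2 - d6 > 1e-300) {
      double t = d2 / (d2 - d6);
      W[1] = W[2]; n = 2; lam[0] = 1 - t; lam[1] = t;
      v = (1 - t) * a + t * W[1].w; return false;
    }
    double va = d3 * d6 - d5 * d4;
    if (va <= 0 && d4 - d3 >= 0 && d5 - d6 >= 0
        && (d4 - d3) + (d5 - d6) > 1e-300) {
      double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      W[0] = W[1]; W[1] = W[2]; n = 2; lam[0] = 1 - t; lam[1] = t;
      v = (1 - t) * W[0].w + t * W[1].w; return false;
    }
    double denom = va + vb + vc;
    if (std::fabs(denom) < 1e-300) { n = 1; lam[0] = 1; v = a; return false; }
    lam[0] = va / denom; lam[1] = vb / denom; lam[2] = vc / denom;
    v = lam[0] * a + lam[1] * b + lam[2] * c;
    return false;
  }
  // n == 4: certified containment test via barycentric coordinates of the
  // origin; anything short of a solid certificate falls back to the
  // minimum over the four triangular faces.
  {
    V3 a = W[0].w, b = W[1].w, c = W[2].w, d = W[3].w;
    double det = dot(d - a, cross(b - a, c - a));
    double scale = std::sqrt(std::max(std::max(norm2(b - a), norm2(c - a)),
                                      norm2(d - a)));
    // signed sub-volumes of the origin in the tetrahedron; containment is
    // claimed only when every sub-volume clears a scale-aware margin that
    // dominates floating-point noise (sliver tetrahedra never certify)
    {
      V3 o = v3(0, 0, 0);
      double la = dot(d - o, cross(b - o, c - o));
      double lb = dot(d - a, cross(o - a, c - a));
      double lc = dot(d - a, cross(b - a, o - a));
      double ld = dot(o - a, cross(b - a, c - a));
      double vth = 1e-9 * scale * scale * scale + 1e-30;
      if (det > 0) {
        if (la > vth && lb > vth && lc > vth && ld > vth) return true;
      } else {
        if (la < -vth && lb < -vth && lc < -vth && ld < -vth) return true;
      }
    }
    double bestd = 1e300; SimplexVert bw[4]; int bn = 1;
    double bl[4] = {1, 0, 0, 0}; V3 bv = W[0].w;
    int faces[4][3] = {{0,1,2},{0,1,3},{0,2,3},{1,2,3}};
    for (int f = 0; f < 4; f++) {
      SimplexVert T[4] = {W[faces[f][0]], W[faces[f][1]], W[faces[f][2]]};
      int tn = 3; double tl[4]; V3 tv;
      simplex_closest(T, tn, tv, tl);
      double dd = norm2(tv);
      if (dd < bestd) {
        bestd = dd; bn = tn; bv = tv;
        for (int i = 0; i < tn; i++) { bw[i] = T[i]; bl[i] = tl[i]; }
      }
    }
    n = bn; v = bv;
    for (int i = 0; i < bn; i++) { W[i] = bw[i]; lam[i] = bl[i]; }
    return false;
  }
}

static long long g_gjk_calls = 0, g_gjk_iters = 0, g_gjk_restarts = 0,
                 g_steps = 0, g_collchecks = 0, g_exact = 0;
// [[Rcpp::export]]
Rcpp::NumericVector cpp_perf_counters(bool reset) {
  Rcpp::NumericVector r = Rcpp::NumericVector::create(
    (double)g_gjk_calls, (double)g_gjk_iters, (double)g_gjk_restarts,
    (double)g_steps, (double)g_collchecks, (double)g_exact);
  if (reset) { g_gjk_calls = g_gjk_iters = g_gjk_restarts = g_steps
             = g_collchecks = g_exact = 0; }
  return r;
}

struct GjkOut {
  double dist;            // > 0 separation; <= 0 overlap
  V3 pa, pb;              // witness points (valid when dist > 0)
  int na, nb, idsA[4], idsB[4];
  bool hard;              // overlap certified by simplex containment
};

// distance between two posed convex polytopes; dir0 is an optional warm
// start direction (e.g. the witness separation from a previous query).
// Exits only on a certified duality gap; cycling exits (possible with a
// poor start direction and degenerate simplexes) trigger a restart from a
// different direction, and the final fallback reports the best certified
// lower bound, which is conservative for collision decisions.
static void gjk(const ShapeRef &A, const ShapeRef &B, V3 dir0, GjkOut &out) {
  out.hard = false;
  g_gjk_calls++;
  const double rel = 1e-10;
  double glb = -1e300;          // best certified lower bound on distance
  double best_vv = 1e300;
  SimplexVert bestW[4]; int best_n = 0; double best_lam[4];
  V3 starts[5] = {dir0, A.t - B.t, v3(1, 0, 0), v3(0, 1, 0), v3(0, 0, 1)};
  for (int attempt = 0; attempt < 5; attempt++) {
    V3 v = starts[attempt];
    if (norm2(v) < 1e-12) continue;
    SimplexVert W[4]; int n = 0; double lam[4];
    double vv_prev = 1e300;
    if (attempt > 0) g_gjk_restarts++;
    for (int iter = 0; iter < 64; iter++) {
      g_gjk_iters++;
      V3 d = v3(0,0,0) - v;
      int ia = A.support(d), ib = B.support(v3(0,0,0) - d);
      SimplexVert sw;
      sw.a = A.vert(ia); sw.b = B.vert(ib); sw.w = sw.a - sw.b;
      sw.ia = ia; sw.ib = ib;
      double vv = norm2(v);
      if (n > 0) {
        double vw = dot(v, sw.w);
        if (vw > 0) glb = std::max(glb, vw / std::sqrt(vv));
        if (vv - vw <= rel * vv + 1e-24) {
          // certified optimum
          out.dist = std::sqrt(vv);
          out.pa = v3(0,0,0); out.pb = v3(0,0,0);
          out.na = n; out.nb = n;
          for (int i = 0; i < n; i++) {
            out.pa = out.pa + lam[i] * W[i].a;
            out.pb = out.pb + lam[i] * W[i].b;
            out.idsA[i] = W[i].ia; out.idsB[i] = W[i].ib;
          }
          return;
        }
      }
      bool dup = false;
      for (int i = 0; i < n; i++)
        if (W[i].ia == sw.ia && W[i].ib == sw.ib) { dup = true; break; }
      if (dup) break;                       // cycling: restart
      W[n++] = sw;
      bool inside = simplex_closest(W, n, v, lam);
      double vvn = norm2(v);
      if (inside || vvn < 1e-24) { out.dist = -1.0; out.hard = inside; return; }
      if (vvn < best_vv) {
        best_vv = vvn; best_n = n;
        for (int i = 0; i < n; i++) { bestW[i] = W[i]; best_lam[i] = lam[i]; }
      }
      if (vvn >= vv_prev * (1.0 - 1e-12)) break;   // stalled: restart
      vv_prev = vvn;
    }
  }
  // uncertified after all restarts (vanishingly rare): report the
  // certified lower bound; non-positive means "treat as collision"
  if (glb > 0) {
    out.dist = glb;
    out.pa = v3(0,0,0); out.pb = v3(0,0,0);
    out.na = best_n; out.nb = best_n;
    for (int i = 0; i < best_n; i++) {
      out.pa = out.pa + best_lam[i] * bestW[i].a;
      out.pb = out.pb + best_lam[i] * bestW[i].b;
      out.idsA[i] = bestW[i].ia; out.idsB[i] = bestW[i].ib;
    }
  } else {
    out.dist = -1.0;
  }
}

// [[Rcpp::export]]
List cpp_convex_distance(NumericMatrix VA, NumericMatrix RA, NumericVector tA,
                         NumericMatrix VB, NumericMatrix RB, NumericVector tB,
                         NumericVector dir0) {
  ShapeRef A, B;
  A.v = VA.begin(); A.n = VA.nrow();
  B.v = VB.begin(); B.n = VB.nrow();
  for (int r = 0; r < 3; r++) for (int c = 0; c < 3; c++) {
    A.R[3 * r + c] = RA(r, c); B.R[3 * r + c] = RB(r, c);
  }
  A.t = v3(tA[0], tA[1], tA[2]); B.t = v3(tB[0], tB[1], tB[2]);
  GjkOut out;
  gjk(A, B, v3(dir0[0], dir0[1], dir0[2]), out);
  if (out.dist <= 0)
    return List::create(_["distance"] = -1.0,
                        _["point_a"] = NumericVector::create(NA_REAL, NA_REAL, NA_REAL),
                        _["point_b"] = NumericVector::create(NA_REAL, NA_REAL, NA_REAL),
                        _["support_a"] = IntegerVector(0),
                        _["support_b"] = IntegerVector(0));
  IntegerVector sa(out.na), sb(out.nb);
  for (int i = 0; i < out.na; i++) sa[i] = out.idsA[i] + 1;
  for (int i = 0; i < out.nb; i++) sb[i] = out.idsB[i] + 1;
  return List::create(
    _["distance"] = out.dist,
    _["point_a"] = NumericVector::create(out.pa.x, out.pa.y, out.pa.z),
    _["point_b"] = NumericVector::create(out.pb.x, out.pb.y, out.pb.z),
    _["support_a"] = sa, _["support_b"] = sb);
}

// ------------------------------------------------------------ AABB tree -
struct AabbTree {
  std::vector<double> lo, hi;        // 3 per node
  std::vector<int> left, right, leaf;  // leaf >= 0 holds the box id
  int build(const std::vector<double> &blo, const std::vector<double> &bhi,
            std::vector<int> &ids, int b, int e) {
    int node = (int)leaf.size();
    lo.insert(lo.end(), {1e300, 1e300, 1e300});
    hi.insert(hi.end(), {-1e300, -1e300, -1e300});
    left.push_back(-1); right.push_back(-1); leaf.push_back(-1);
    for (int i = b; i < e; i++)
      for (int k = 0; k < 3; k++) {
        lo[3*node+k] = std::min(lo[3*node+k], blo[3*ids[i]+k]);
        hi[3*node+k] = std::max(hi[3*node+k], bhi[3*ids[i]+k]);
      }
    if (e - b == 1) { leaf[node] = ids[b]; return node; }
    int ax = 0; double best = -1;
    for (int k = 0; k < 3; k++) {
      double ext = hi[3*node+k] - lo[3*node+k];
      if (ext > best) { best = ext; ax = k; }
    }
    int mid = (b + e) / 2;
    std::nth_element(ids.begin()+b, ids.begin()+mid, ids.begin()+e,
      [&](int i, int j) {
        return blo[3*i+ax] + bhi[3*i+ax] < blo[3*j+ax] + bhi[3*j+ax];
      });
    int l = build(blo, bhi, ids, b, mid);
    int r = build(blo, bhi, ids, mid, e);
    left[node] = l; right[node] = r;
    return node;
  }
  inline double box_dist2(int node, V3 p) const {
    double d2 = 0;
    double pc[3] = {p.x, p.y, p.z};
    for (int k = 0; k < 3; k++) {
      double d = std::max(std::max(lo[3*node+k] - pc[k],
                                   pc[k] - hi[3*node+k]), 0.0);
      d2 += d * d;
    }
    return d2;
  }
  void query_box(int node, const double qlo[3], const double qhi[3],
                 std::vector<int> &out) const {
    for (int k = 0; k < 3; k++)
      if (qlo[k] > hi[3*node+k] || qhi[k] < lo[3*node+k]) return;
    if (leaf[node] >= 0) { out.push_back(leaf[node]); return; }
    query_box(left[node], qlo, qhi, out);
    query_box(right[node], qlo, qhi, out);
  }
};

// [[Rcpp::export]]
List cpp_aabb_tree(NumericMatrix blo, NumericMatrix bhi) {
  int n = blo.nrow();
  std::vector<double> lo(3 * n), hi(3 * n);
  for (int i = 0; i < n; i++)
    for (int k = 0; k < 3; k++) { lo[3*i+k] = blo(i, k); hi[3*i+k] = bhi(i, k); }
  std::vector<int> ids(n);
  for (int i = 0; i < n; i++) ids[i] = i;
  AabbTree tr;
  tr.build(lo, hi, ids, 0, n);
  int m = (int)tr.leaf.size();
  NumericMatrix nlo(m, 3), nhi(m, 3);
  IntegerVector lft(m), rgt(m), lf(m);
  for (int i = 0; i < m; i++) {
    for (int k = 0; k < 3; k++) { nlo(i, k) = tr.lo[3*i+k]; nhi(i, k) = tr.hi[3*i+k]; }
    lft[i] = tr.left[i]; rgt[i] = tr.right[i]; lf[i] = tr.leaf[i];
  }
  return List::create(_["lo"] = nlo, _["hi"] = nhi, _["left"] = lft,
                      _["right"] = rgt, _["leaf"] = lf);
}

static AabbTree tree_from_list(const List &tl) {
  AabbTree tr;
  NumericMatrix nlo = tl["lo"], nhi = tl["hi"];
  IntegerVector lft = tl["left"], rgt = tl["right"], lf = tl["leaf"];
  int m = nlo.nrow();
  tr.lo.resize(3 * m); tr.hi.resize(3 * m);
  tr.left.resize(m); tr.right.resize(m); tr.leaf.resize(m);
  for (int i = 0; i < m; i++) {
    for (int k = 0; k < 3; k++) { tr.lo[3*i+k] = nlo(i, k); tr.hi[3*i+k] = nhi(i, k); }
    tr.left[i] = lft[i]; tr.right[i] = rgt[i]; tr.leaf[i] = lf[i];
  }
  return tr;
}

// [[Rcpp::export]]
IntegerVector cpp_aabb_query(List tree, NumericVector qlo, NumericVector qhi) {
  AabbTree tr = tree_from_list(tree);
  std::vector<int> out;
  double lo[3] = {qlo[0], qlo[1], qlo[2]}, hi[3] = {qhi[0], qhi[1], qhi[2]};
  tr.query_box(0, lo, hi, out);
  IntegerVector r(out.size());
  for (size_t i = 0; i < out.size(); i++) r[i] = out[i] + 1;
  return r;
}

// ----------------------------------------------------------- the scene --
struct Scene {
  const double *dv; int ndv;             // dimer body vertices
  std::vector<double> R;                 // 9 per dimer (row-major)
  std::vector<V3> t;
  int ndim;
  AabbTree tree;
  const double *bv; int nbv;             // binder body vertices
  double binder_rad;                     // max vertex radius (bounding sphere)
  double dimer_rad;                      // max dimer vertex radius
  // capped bounding cylinder of the whole lattice (axis = world z): a
  // cheap, exact lower bound on the separation used in the far field
  double cyl_rad, cyl_zlo, cyl_zhi;
  inline double cylinder_lb(V3 p) const {
    double rho = std::sqrt(p.x * p.x + p.y * p.y);
    double dr = std::max(rho - cyl_rad, 0.0);
    double dz = std::max(std::max(cyl_zlo - p.z, p.z - cyl_zhi), 0.0);
    return std::sqrt(dr * dr + dz * dz) - binder_rad > 0
      ? std::sqrt(dr * dr + dz * dz) - binder_rad : 0.0;
  }

  inline ShapeRef dimer(int i) const {
    ShapeRef s; s.v = dv; s.n = ndv;
    for (int k = 0; k < 9; k++) s.R[k] = R[9*i+k];
    s.t = t[i];
    return s;
  }
  // exact closest separation binder <-> lattice, best-first over the tree
  double min_distance(const ShapeRef &mol, int root, double best,
                      int *nearest) const {
    if (leafv(root) >= 0) {
      GjkOut o;
      gjk(mol, dimer(leafv(root)), v3(0,0,0), o);
      double d = o.dist <= 0 ? 0.0 : o.dist;
      if (d < best && nearest) *nearest = leafv(root);
      return std::min(best, d);
    }
    int l = tree.left[root], r = tree.right[root];
    double dl = std::sqrt(tree.box_dist2(l, mol.t)) - binder_rad;
    double dr = std::sqrt(tree.box_dist2(r, mol.t)) - binder_rad;
    if (dl > dr) { std::swap(l, r); std::swap(dl, dr); }
    if (dl < best) best = min_distance(mol, l, best, nearest);
    if (dr < best) best = min_distance(mol, r, best, nearest);
    return best;
  }
  inline int leafv(int node) const { return tree.leaf[node]; }
  double distance(const ShapeRef &mol, int *nearest = nullptr) const {
    return min_distance(mol, 0, 1e300, nearest);
  }
  // does the molecule overlap any dimer?
  bool collides(const ShapeRef &mol, std::vector<int> &buf) const {
    buf.clear();
    double qlo[3] = {mol.t.x - binder_rad, mol.t.y - binder_rad,
                     mol.t.z - binder_rad};
    double qhi[3] = {mol.t.x + binder_rad, mol.t.y + binder_rad,
                     mol.t.z + binder_rad};
    tree.query_box(0, qlo, qhi, buf);
    for (size_t i = 0; i < buf.size(); i++) {
      GjkOut o;
      gjk(mol, dimer(buf[i]), v3(0,0,0), o);
      if (o.dist <= 0) return true;
    }
    return false;
  }
};

static Scene scene_from_args(NumericMatrix dimerV, NumericMatrix dimerR,
                             NumericMatrix dimerT, NumericMatrix binderV) {
  Scene sc;
  sc.dv = dimerV.begin(); sc.ndv = dimerV.nrow();
  sc.ndim = dimerR.nrow();
  sc.R.resize(9 * sc.ndim); sc.t.resize(sc.ndim);
  for (int i = 0; i < sc.ndim; i++) {
    for (int k = 0; k < 9; k++) sc.R[9*i+k] = dimerR(i, k);
    sc.t[i] = v3(dimerT(i, 0), dimerT(i, 1), dimerT(i, 2));
  }
  sc.bv = binderV.begin(); sc.nbv = binderV.nrow();
  sc.binder_rad = 0;
  for (int i = 0; i < sc.nbv; i++) {
    double r2 = binderV(i,0)*binderV(i,0) + binderV(i,1)*binderV(i,1)
              + binderV(i,2)*binderV(i,2);
    sc.binder_rad = std::max(sc.binder_rad, std::sqrt(r2));
  }
  sc.dimer_rad = 0;
  for (int i = 0; i < sc.ndv; i++) {
    double r2 = dimerV(i,0)*dimerV(i,0) + dimerV(i,1)*dimerV(i,1)
              + dimerV(i,2)*dimerV(i,2);
    sc.dimer_rad = std::max(sc.dimer_rad, std::sqrt(r2));
  }
  // world AABBs of the dimers (vertices transformed per placement)
  int n = sc.ndim;
  std::vector<double> blo(3*n, 1e300), bhi(3*n, -1e300);
  sc.cyl_rad = 0; sc.cyl_zlo = 1e300; sc.cyl_zhi = -1e300;
  for (int i = 0; i < n; i++) {
    ShapeRef d = sc.dimer(i);
    for (int j = 0; j < sc.ndv; j++) {
      V3 p = d.vert(j);
      double pc[3] = {p.x, p.y, p.z};
      for (int k = 0; k < 3; k++) {
        blo[3*i+k] = std::min(blo[3*i+k], pc[k]);
        bhi[3*i+k] = std::max(bhi[3*i+k], pc[k]);
      }
      sc.cyl_rad = std::max(sc.cyl_rad, std::sqrt(p.x*p.x + p.y*p.y));
      sc.cyl_zlo = std::min(sc.cyl_zlo, p.z);
      sc.cyl_zhi = std::max(sc.cyl_zhi, p.z);
    }
  }
  std::vector<int> ids(n);
  for (int i = 0; i < n; i++) ids[i] = i;
  sc.tree.build(blo, bhi, ids, 0, n);
  return sc;
}

// dynamic step-size rule: step length = Dist/5 at >=100 nm, Dist/20 at
// <=1 nm, divisor linear in Dist between; near a binding site a fixed step
// of 0.05 nm typical displacement.
static inline double plan_dt(double dist, bool near_site, double Dc_nm,
                             double near_step_nm) {
  double dx;
  if (near_site) dx = near_step_nm;
  else {
    double divisor;
    if (dist >= 100.0) divisor = 5.0;
    else if (dist <= 1.0) divisor = 20.0;
    else divisor = 20.0 - 15.0 * (dist - 1.0) / 99.0;
    dx = dist / divisor;
    // step-length floor away from binding sites: resolves the collision
    // boundary layer without letting the step collapse to zero at walls
    if (dx < 2.0 * near_step_nm) dx = 2.0 * near_step_nm;
  }
  return dx * dx / (6.0 * Dc_nm);
}

struct SiteSet {
  int nsite;
  std::vector<int> k;            // anchors per site
  std::vector<int> aidx;         // nsite x 4, binder-anchor index or -1
  std::vector<V3> iface;         // nsite x 4 interface centres (padded)
  std::vector<V3> center, normal;
  std::vector<int> normal_rule;  // apply the orientation (not-upside-down) rule
  double patt_rad;               // max |iface - center| over all sites
};

// [[Rcpp::export]]
List cpp_run_ensemble(NumericMatrix dimerV, NumericMatrix dimerR,
                      NumericMatrix dimerT, NumericMatrix binderV,
                      NumericMatrix anchorsBody, NumericVector bindNormal,
                      IntegerVector siteK, IntegerMatrix siteAnchorIdx,
                      NumericMatrix siteIface, NumericMatrix siteCenter,
                      NumericMatrix siteNormal, IntegerVector siteNormalRule,
                      NumericVector centroid, List config) {
  Scene sc = scene_from_args(dimerV, dimerR, dimerT, binderV);
  SiteSet ss;
  ss.nsite = siteK.size();
  ss.k.resize(ss.nsite); ss.aidx.resize(4 * ss.nsite);
  ss.iface.resize(4 * ss.nsite);
  ss.center.resize(ss.nsite); ss.normal.resize(ss.nsite);
  ss.normal_rule.resize(ss.nsite);
  ss.patt_rad = 0;
  for (int s = 0; s < ss.nsite; s++) {
    ss.k[s] = siteK[s];
    ss.center[s] = v3(siteCenter(s,0), siteCenter(s,1), siteCenter(s,2));
    ss.normal[s] = v3(siteNormal(s,0), siteNormal(s,1), siteNormal(s,2));
    ss.normal_rule[s] = siteNormalRule[s];
    for (int j = 0; j < 4; j++) {
      ss.aidx[4*s+j] = siteAnchorIdx(s, j);   // 0-based or -1
      ss.iface[4*s+j] = v3(siteIface(s, 3*j), siteIface(s, 3*j+1),
                           siteIface(s, 3*j+2));
      if (ss.aidx[4*s+j] >= 0) {
        double d = std::sqrt(norm2(ss.iface[4*s+j] - ss.center[s]));
        ss.patt_rad = std::max(ss.patt_rad, d);
      }
    }
  }
  int nanch = anchorsBody.nrow();
  std::vector<V3> anch(nanch);
  for (int i = 0; i < nanch; i++)
    anch[i] = v3(anchorsBody(i,0), anchorsBody(i,1), anchorsBody(i,2));
  V3 bn_body = v3(bindNormal[0], bindNormal[1], bindNormal[2]);
  V3 iface_body = v3(0,0,0);
  for (int i = 0; i < nanch; i++) iface_body = iface_body + (1.0/nanch) * anch[i];
  V3 ctr = v3(centroid[0], centroid[1], centroid[2]);

  double start_radius   = as<double>(config["start_radius"]);
  double escape_radius  = as<double>(config["escape_radius"]);
  double bind_dist      = as<double>(config["binding_distance"]);
  double Dc_nm          = as<double>(config["dc_nm"]);
  double Drot           = as<double>(config["dc_rot"]);
  double near_step      = as<double>(config["near_step_nm"]);
  double max_steps      = as<double>(config["max_steps"]);
  int    retry_cap      = as<int>(config["retry_cap"]);
  uint64_t seed         = (uint64_t)as<double>(config["seed"]);
  int n_mol             = as<int>(config["n_molecules"]);
  IntegerVector reps    = config["replicates"];
  bool debug_check      = as<bool>(config["debug_check"]);

  double bd2 = bind_dist * bind_dist;
  double site_gate = ss.patt_rad + bind_dist;   // |ifc-center| gate radius
  double site_gate2 = (site_gate + 1.0) * (site_gate + 1.0);

  int total = n_mol * reps.size();
  IntegerVector out_rep(total), out_mol(total), out_site(total),
                out_status(total);
  NumericVector out_steps(total);
  double min_sep_seen = 1e300;

  std::vector<int> buf;
  int row = 0;
  for (int ri = 0; ri < reps.size(); ri++) {
    int rep = reps[ri];
    for (int mol = 0; mol < n_mol; mol++, row++) {
      Rng rng; rng.seed(stream_seed(seed, (uint64_t)rep, (uint64_t)mol));
      // start on the sphere, uniform orientation
      V3 u;
      do { u = v3(rng.gauss(), rng.gauss(), rng.gauss()); } while (norm2(u) < 1e-12);
      u = (1.0 / std::sqrt(norm2(u))) * u;
      V3 pos = ctr + start_radius * u;
      Quat q;
      { double g[4] = {rng.gauss(), rng.gauss(), rng.gauss(), rng.gauss()};
        double nn = std::sqrt(g[0]*g[0]+g[1]*g[1]+g[2]*g[2]+g[3]*g[3]);
        q.w = g[0]/nn; q.x = g[1]/nn; q.y = g[2]/nn; q.z = g[3]/nn; }
      ShapeRef mol_ref; mol_ref.v = sc.bv; mol_ref.n = sc.nbv;
      qtomat(q, mol_ref.R); mol_ref.t = pos;

      int status = 0;   // 0 free, 1 arrived, 2 escaped, 3 censored
      int site_hit = NA_INTEGER;
      double steps = 0;

      // near-field candidate cache and warm-start direction
      int since_exact = 0;
      std::vector<int> nearlist;
      std::vector<int> nearsites;
      V3 near_anchor = v3(1e9, 1e9, 1e9);
      V3 warm_dir = v3(0, 0, 0);
      const double NEAR_TH = 8.0;      // switch to exact narrow phase, nm
      const double LIST_MOVE = 3.0;    // rebuild the near list after this
      const double LIST_RAD  = NEAR_TH + LIST_MOVE + 1.0;

      // exact separation over the cached near list (pos must be within
      // LIST_MOVE of near_anchor); conservative +inf when list empty
      double dist_lb = 0, last_exact = -1;

      auto refresh_list = [&](V3 p) {
        nearlist.clear();
        double r = LIST_RAD + sc.binder_rad;
        double qlo[3] = {p.x - r, p.y - r, p.z - r};
        double qhi[3] = {p.x + r, p.y + r, p.z + r};
        sc.tree.query_box(0, qlo, qhi, nearlist);
        nearsites.clear();
        double r2s = (LIST_RAD + sc.binder_rad) * (LIST_RAD + sc.binder_rad);
        for (int s = 0; s < ss.nsite; s++)
          if (norm2(ss.center[s] - p) <= r2s) nearsites.push_back(s);
        near_anchor = p;
      };
      auto exact_sep = [&](const ShapeRef &m) -> double {
        g_exact++;
        if (std::sqrt(norm2(m.t - near_anchor)) > LIST_MOVE) refresh_list(m.t);
        double best = 1e300;
        for (size_t i = 0; i < nearlist.size(); i++) {
          int di = nearlist[i];
          double lb = std::sqrt(norm2(m.t - sc.t[di])) - sc.dimer_rad
                      - sc.binder_rad;
          if (lb >= best) continue;
          GjkOut o;
          gjk(m, sc.dimer(di), warm_dir, o);
          if (o.dist <= 0) return 0.0;
          if (o.dist < best) { best = o.dist; warm_dir = o.pa - o.pb; }
        }
        return best;
      };
      auto near_collides = [&](const ShapeRef &m) -> bool {
        g_collchecks++;
        if (std::sqrt(norm2(m.t - near_anchor)) > LIST_MOVE) refresh_list(m.t);
        for (size_t i = 0; i < nearlist.size(); i++) {
          int di = nearlist[i];
          double lb = std::sqrt(norm2(m.t - sc.t[di])) - sc.dimer_rad
                      - sc.binder_rad;
          if (lb > 0) continue;
          GjkOut o;
          gjk(m, sc.dimer(di), warm_dir, o);
          if (o.dist <= 0) return true;
        }
        return false;
      };

      {
        double d_an = sc.cylinder_lb(pos);
        dist_lb = d_an > NEAR_TH ? d_an : exact_sep(mol_ref);
        last_exact = dist_lb;
      }

      while (status == 0) {
        V3 rel = pos - ctr;
        if (std::sqrt(norm2(rel)) >= escape_radius * (1.0 - 1e-12))
          { status = 2; break; }
        double d_an = sc.cylinder_lb(pos);
        double dist;
        if (d_an > NEAR_TH) {
          dist = d_an; dist_lb = d_an; last_exact = -1;
        } else {
          // refresh the exact separation when the running lower bound has
          // degraded materially; while hugging the wall (bound below the
          // step floor regime) the plan no longer depends on the exact
          // value, so refresh only sparsely
          bool need = false;
          if (last_exact < 0) need = true;
          else if (dist_lb < 0.75 * last_exact) {
            if (dist_lb > 1.0) need = true;
            else if (++since_exact >= 4) need = true;
          }
          if (need) {
            dist_lb = exact_sep(mol_ref);
            last_exact = dist_lb;
            since_exact = 0;
          }
          dist = dist_lb;
        }
        // near-site flag from the binder interface centroid
        bool near_site = false;
        if (dist < 3.0) {
          if (std::sqrt(norm2(pos - near_anchor)) > LIST_MOVE)
            refresh_list(pos);
          V3 ifc = rot(mol_ref.R, iface_body) + pos;
          for (size_t si = 0; si < nearsites.size(); si++) {
            if (norm2(ifc - ss.center[nearsites[si]]) <= bd2) {
              near_site = true; break;
            }
          }
        }
        double dt = plan_dt(dist, near_site, Dc_nm, near_step);
        double sig_t = std::sqrt(2.0 * Dc_nm * dt);
        double sig_r = std::sqrt(2.0 * Drot * dt);
        // propose, reject on collision, halve the step after retry_cap tries
        int attempts = 0;
        V3 npos; Quat nq; ShapeRef nref = mol_ref;
        double moved;
        while (true) {
          V3 d3 = v3(sig_t * rng.gauss(), sig_t * rng.gauss(),
                     sig_t * rng.gauss());
          V3 rv = v3(sig_r * rng.gauss(), sig_r * rng.gauss(),
                     sig_r * rng.gauss());
          moved = std::sqrt(norm2(d3)) + std::sqrt(norm2(rv)) * sc.binder_rad;
          // a move strictly shorter than the current separation bound
          // cannot produce a contact: accept without a narrow-phase test
          if (moved < dist_lb) {
            nq = qmul(qfromrotvec(rv), q); qnormalize(nq);
            npos = pos + d3;
            qtomat(nq, nref.R); nref.t = npos;
            break;
          }
          nq = qmul(qfromrotvec(rv), q); qnormalize(nq);
          npos = pos + d3;
          qtomat(nq, nref.R); nref.t = npos;
          if (!near_collides(nref)) break;
          attempts++;
          if (attempts % retry_cap == 0) {
            sig_t *= 0.70710678118654752; sig_r *= 0.70710678118654752;
          }
          if (attempts > 100 * retry_cap)
            stop("attempt_move: no collision-free proposal found (geometry bug?)");
        }
        pos = npos; q = nq; mol_ref = nref;
        steps += 1; g_steps++;
        dist_lb = std::max(dist_lb - moved, 0.0);
        if (debug_check) {
          double dchk = sc.distance(mol_ref);
          if (dchk <= 0) {
            // distinguish a certified interpenetration from the benign
            // certification-ambiguous case of a molecule touching the
            // wall within floating-point resolution
            for (int di = 0; di < sc.ndim; di++) {
              GjkOut o2; gjk(mol_ref, sc.dimer(di), v3(0,0,0), o2);
              if (o2.dist <= 0 && o2.hard)
                stop("penetrating pose accepted (collision bug)");
            }
            dchk = 0.0;
          }
          min_sep_seen = std::min(min_sep_seen, dchk);
        }
        if (dist_lb < 3.0 && sc.cylinder_lb(pos) < 3.0) {
          // arrival: all k anchor pairs within the binding distance,
          // plus the orientation rule for single-anchor sites
          if (std::sqrt(norm2(pos - near_anchor)) > LIST_MOVE)
            refresh_list(pos);
          V3 ifc = rot(mol_ref.R, iface_body) + pos;
          V3 aw[4]; bool aw_done = false;
          for (size_t si = 0; si < nearsites.size() && status == 0; si++) {
            int s = nearsites[si];
            if (norm2(ifc - ss.center[s]) > site_gate2) continue;
            if (!aw_done) {
              for (int i = 0; i < nanch; i++)
                aw[i] = rot(mol_ref.R, anch[i]) + pos;
              aw_done = true;
            }
            bool ok = true;
            for (int j = 0; j < 4 && ok; j++) {
              int ai = ss.aidx[4*s+j];
              if (ai < 0) continue;
              if (norm2(aw[ai] - ss.iface[4*s+j]) > bd2) ok = false;
            }
            if (ok && ss.normal_rule[s]) {
              V3 wn = rot(mol_ref.R, bn_body);
              if (dot(wn, ss.normal[s]) >= 0) ok = false;
            }
            if (ok) { status = 1; site_hit = s + 1; }
          }
        }
        if (status == 0 && steps >= max_steps) status = 3;
      }
      out_rep[row] = rep; out_mol[row] = mol + 1;
      out_status[row] = status; out_site[row] = site_hit;
      out_steps[row] = steps;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["replicate"] = out_rep, _["molecule"] = out_mol,
                      _["status"] = out_status, _["site"] = out_site,
                      _["n_steps"] = out_steps,
                      _["min_separation"] = min_sep_seen);
}

// exact separation binder <-> whole lattice (used by R-level stepping)
// [[Rcpp::export]]
List cpp_scene_distance(NumericMatrix dimerV, NumericMatrix dimerR,
                        NumericMatrix dimerT, NumericMatrix binderV,
                        NumericMatrix bR, NumericVector bt) {
  Scene sc = scene_from_args(dimerV, dimerR, dimerT, binderV);
  ShapeRef mol; mol.v = sc.bv; mol.n = sc.nbv;
  for (int r = 0; r < 3; r++) for (int c = 0; c < 3; c++)
    mol.R[3*r+c] = bR(r, c);
  mol.t = v3(bt[0], bt[1], bt[2]);
  int nearest = -1;
  double d = sc.distance(mol, &nearest);
  bool coll = false;
  std::vector<int> buf;
  if (d <= 1e-12) coll = sc.collides(mol, buf);
  return List::create(_["distance"] = coll ? -1.0 : d,
                      _["nearest_dimer"] = nearest + 1);
}

// ---------------------------------------------------- reference dynamics -
// free translational diffusion: mean squared displacement per recorded step
// [[Rcpp::export]]
NumericVector cpp_free_msd(int n_mol, int n_steps, double dt, double Dc_nm,
                           double seed) {
  NumericVector msd(n_steps);
  double sig = std::sqrt(2.0 * Dc_nm * dt);
  for (int m = 0; m < n_mol; m++) {
    Rng rng; rng.seed(stream_seed((uint64_t)seed, 0, (uint64_t)m));
    V3 p = v3(0, 0, 0);
    for (int s = 0; s < n_steps; s++) {
      p = p + v3(sig * rng.gauss(), sig * rng.gauss(), sig * rng.gauss());
      msd[s] += norm2(p);
    }
  }
  for (int s = 0; s < n_steps; s++) msd[s] /= n_mol;
  return msd;
}

// rotational diffusion: autocorrelation <u(t).u(0)> of a body axis
// [[Rcpp::export]]
NumericVector cpp_rot_autocorr(int n_mol, int n_steps, double dt, double Drot,
                               double seed) {
  NumericVector ac(n_steps);
  double sig = std::sqrt(2.0 * Drot * dt);
  for (int m = 0; m < n_mol; m++) {
    Rng rng; rng.seed(stream_seed((uint64_t)seed, 1, (uint64_t)m));
    Quat q; q.w = 1; q.x = q.y = q.z = 0;
    double R[9];
    for (int s = 0; s < n_steps; s++) {
      V3 rv = v3(sig * rng.gauss(), sig * rng.gauss(), sig * rng.gauss());
      q = qmul(qfromrotvec(rv), q); qnormalize(q);
      qtomat(q, R);
      ac[s] += R[8];   // world z component of the body z axis
    }
  }
  for (int s = 0; s < n_steps; s++) ac[s] /= n_mol;
  return ac;
}

// diffusion to an absorbing sphere (radius a) inside an absorbing outer
// boundary (radius Rout), started at r0, with the engine's step-size rule;
// validates against the closed-form hitting probability
// [[Rcpp::export]]
IntegerVector cpp_sphere_hitting(int n_mol, double a, double r0, double Rout,
                                 double Dc_nm, double seed) {
  int hit = 0, esc = 0;
  for (int m = 0; m < n_mol; m++) {
    Rng rng; rng.seed(stream_seed((uint64_t)seed, 2, (uint64_t)m));
    V3 u;
    do { u = v3(rng.gauss(), rng.gauss(), rng.gauss()); } while (norm2(u) < 1e-12);
    u = (1.0 / std::sqrt(norm2(u))) * u;
    V3 p = r0 * u;
    for (;;) {
      double r = std::sqrt(norm2(p));
      if (r <= a) { hit++; break; }
      if (r >= Rout) { esc++; break; }
      double dist = r - a;
      double dt = plan_dt(dist, false, Dc_nm, 0.05);
      double sig = std::sqrt(2.0 * Dc_nm * dt);
      p = p + v3(sig * rng.gauss(), sig * rng.gauss(), sig * rng.gauss());
    }
  }
  return IntegerVector::create(hit, esc);
}

// micro-benchmark: repeated GJK on a posed pair (perf diagnostics)
// [[Rcpp::export]]
NumericVector cpp_bench_gjk(NumericMatrix VA, NumericMatrix RA,
                            NumericVector tA, NumericMatrix VB,
                            NumericMatrix RB, NumericVector tB, int m) {
  ShapeRef A, B;
  A.v = VA.begin(); A.n = VA.nrow();
  B.v = VB.begin(); B.n = VB.nrow();
  for (int r = 0; r < 3; r++) for (int c = 0; c < 3; c++) {
    A.R[3 * r + c] = RA(r, c); B.R[3 * r + c] = RB(r, c);
  }
  A.t = v3(tA[0], tA[1], tA[2]); B.t = v3(tB[0], tB[1], tB[2]);
  double acc = 0;
  long long it0 = g_gjk_iters;
  for (int i = 0; i < m; i++) {
    GjkOut o;
    V3 jitter = v3(1e-9 * (i % 7), 1e-9 * (i % 5), 1e-9 * (i % 3));
    ShapeRef B2 = B; B2.t = B.t + jitter;
    gjk(A, B2, v3(0,0,0), o);
    acc += o.dist;
  }
  return NumericVector::create(acc / m, (double)(g_gjk_iters - it0) / m);
}
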