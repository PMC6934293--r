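// Core numerical kernels: explicit central-difference dynamics of
// corotational Timoshenko beam chains with penalty contact, plus mesh
// geometry utilities (marching tetrahedra, winding number, ray parity,
// segment distances).
//
// Internal unit system: mm / mg / ms (derived force unit mN, derived
// stress unit kPa).  All arrays are passed from R already converted.

#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>
#include <utility>

using namespace Rcpp;

// ---------------------------------------------------------------- vectors

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline V3 operator+(V3 a, V3 b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(V3 a, V3 b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(double s, V3 a) { return V3(s * a.x, s * a.y, s * a.z); }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(V3 a, V3 b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(V3 a) { return std::sqrt(dot(a, a)); }

struct Q4 {
  double w, x, y, z;
  Q4() : w(1), x(0), y(0), z(0) {}
  Q4(double a, double b, double c, double d) : w(a), x(b), y(c), z(d) {}
};
static inline Q4 qmul(Q4 a, Q4 b) {
  return Q4(a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z,
            a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y,
            a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x,
            a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w);
}
static inline Q4 qconj(Q4 a) { return Q4(a.w, -a.x, -a.y, -a.z); }
static inline Q4 qnorm(Q4 a) {
  double n = std::sqrt(a.w * a.w + a.x * a.x + a.y * a.y + a.z * a.z);
  return Q4(a.w / n, a.x / n, a.y / n, a.z / n);
}
// rotate vector by quaternion (world_from_body)
static inline V3 qrot(Q4 q, V3 v) {
  V3 u(q.x, q.y, q.z);
  V3 t = 2.0 * cross(u, v);
  return v + q.w * t + cross(u, t);
}
static inline V3 qrotT(Q4 q, V3 v) { return qrot(qconj(q), v); }

// -------------------------------------------------- segment distances

// closest points between segments p1-p2 and q1-q2 (Eberly)
static double seg_seg_dist(V3 p1, V3 p2, V3 q1, V3 q2,
                           double& s_out, double& t_out) {
  V3 d1 = p2 - p1, d2 = q2 - q1, r = p1 - q1;
  double a = dot(d1, d1), e = dot(d2, d2), f = dot(d2, r);
  double s, t;
  const double EPS = 1e-14;
  if (a <= EPS && e <= EPS) { s = t = 0.0; }
  else if (a <= EPS) { s = 0.0; t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    double c = dot(d1, r);
    if (e <= EPS) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      double b = dot(d1, d2), denom = a * e - b * b;
      s = denom > EPS ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0) { t = 0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1) { t = 1; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  s_out = s; t_out = t;
  V3 cp = p1 + s * d1, cq = q1 + t * d2;
  return norm(cp - cq);
}

// minimum distance between polyline segments whose arc-length
// separation exceeds `window`
// [[Rcpp::export]]
double polyline_self_clearance(NumericMatrix pts, double window) {
  int n = pts.nrow();
  std::vector<V3> p(n);
  std::vector<double> arc(n, 0.0);
  for (int i = 0; i < n; ++i) p[i] = V3(pts(i, 0), pts(i, 1), pts(i, 2));
  for (int i = 1; i < n; ++i) arc[i] = arc[i - 1] + norm(p[i] - p[i - 1]);
  double best = R_PosInf, s, t;
  for (int i = 0; i + 1 < n; ++i)
    for (int j = i + 1; j + 1 < n; ++j) {
      if (arc[j] - arc[i + 1] < window) continue;
      double d = seg_seg_dist(p[i], p[i + 1], p[j], p[j + 1], s, t);
      if (d < best) best = d;
    }
  return best;
}

// point to segment distance
static inline double pt_seg_dist(V3 p, V3 a, V3 b) {
  V3 ab = b - a;
  double t = dot(p - a, ab) / std::max(1e-14, dot(ab, ab));
  t = std::min(1.0, std::max(0.0, t));
  return norm(p - (a + t * ab));
}

// [[Rcpp::export]]
NumericVector cpp_min_dist_to_segments(NumericMatrix pts, NumericMatrix segA,
                                       NumericMatrix segB) {
  int n = pts.nrow(), m = segA.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    V3 p(pts(i, 0), pts(i, 1), pts(i, 2));
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double d = pt_seg_dist(p, V3(segA(j, 0), segA(j, 1), segA(j, 2)),
                             V3(segB(j, 0), segB(j, 1), segB(j, 2)));
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// ------------------------------------------------ point-triangle distance

static V3 closest_on_triangle(V3 p, V3 a, V3 b, V3 c) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return a;
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return a + (d1 / (d1 - d3)) * ab;
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return a + (d2 / (d2 - d6)) * ac;
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return b + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (c - b);
  double denom = 1.0 / (va + vb + vc);
  return a + (vb * denom) * ab + (vc * denom) * ac;
}

// ------------------------------------------------ winding number / parity

// [[Rcpp::export]]
NumericVector cpp_winding_number(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix P) {
  int np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  for (int ip = 0; ip < np; ++ip) {
    V3 p(P(ip, 0), P(ip, 1), P(ip, 2));
    double total = 0.0;
    for (int it = 0; it < nf; ++it) {
      V3 a = V3(V(F(it, 0) - 1, 0), V(F(it, 0) - 1, 1), V(F(it, 0) - 1, 2)) - p;
      V3 b = V3(V(F(it, 1) - 1, 0), V(F(it, 1) - 1, 1), V(F(it, 1) - 1, 2)) - p;
      V3 c = V3(V(F(it, 2) - 1, 0), V(F(it, 2) - 1, 1), V(F(it, 2) - 1, 2)) - p;
      double la = norm(a), lb = norm(b), lc = norm(c);
      double num = dot(a, cross(b, c));
      double den = la * lb * lc + dot(a, b) * lc + dot(b, c) * la + dot(c, a) * lb;
      total += 2.0 * std::atan2(num, den);
    }
    out[ip] = total / (4.0 * M_PI);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_ray_parity(NumericMatrix V, IntegerMatrix F,
                             NumericMatrix P, NumericVector dir) {
  int np = P.nrow(), nf = F.nrow();
  V3 d(dir[0], dir[1], dir[2]);
  IntegerVector out(np);
  for (int ip = 0; ip < np; ++ip) {
    V3 o(P(ip, 0), P(ip, 1), P(ip, 2));
    int count = 0;
    for (int it = 0; it < nf; ++it) {
      V3 a(V(F(it, 0) - 1, 0), V(F(it, 0) - 1, 1), V(F(it, 0) - 1, 2));
      V3 b(V(F(it, 1) - 1, 0), V(F(it, 1) - 1, 1), V(F(it, 1) - 1, 2));
      V3 c(V(F(it, 2) - 1, 0), V(F(it, 2) - 1, 1), V(F(it, 2) - 1, 2));
      // Moller-Trumbore
      V3 e1 = b - a, e2 = c - a;
      V3 pv = cross(d, e2);
      double det = dot(e1, pv);
      if (std::fabs(det) < 1e-14) continue;
      double inv = 1.0 / det;
      V3 tv = o - a;
      double u = dot(tv, pv) * inv;
      if (u < 0 || u > 1) continue;
      V3 qv = cross(tv, e1);
      double v = dot(d, qv) * inv;
      if (v < 0 || u + v > 1) continue;
      double t = dot(e2, qv) * inv;
      if (t > 1e-12) ++count;
    }
    out[ip] = count;
  }
  return out;
}

// ------------------------------------------------ marching tetrahedra

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vals, IntegerVector n,
                       NumericVector xs, NumericVector ys, NumericVector zs) {
  int nx = n[0], ny = n[1], nz = n[2];
  std::vector<double> v(vals.begin(), vals.end());
  for (size_t i = 0; i < v.size(); ++i)
    if (std::fabs(v[i]) < 1e-12) v[i] = 1e-12;  // avoid on-grid zeros
  auto gid = [&](int i, int j, int k) { return i + nx * (j + (long)ny * k); };
  std::map<std::pair<long, long>, int> edge_vertex;
  std::vector<double> VX, VY, VZ;
  std::vector<int> TA, TB, TC;
  auto coord = [&](long g, double* c) {
    int i = g % nx; long r = g / nx;
    int j = r % ny; int k = (int)(r / ny);
    c[0] = xs[i]; c[1] = ys[j]; c[2] = zs[k];
  };
  auto edge_pt = [&](long ga, long gb) {
    if (ga > gb) std::swap(ga, gb);
    auto key = std::make_pair(ga, gb);
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double ca[3], cb[3];
    coord(ga, ca); coord(gb, cb);
    double t = v[ga] / (v[ga] - v[gb]);
    VX.push_back(ca[0] + t * (cb[0] - ca[0]));
    VY.push_back(ca[1] + t * (cb[1] - ca[1]));
    VZ.push_back(ca[2] + t * (cb[2] - ca[2]));
    int idx = (int)VX.size();
    edge_vertex[key] = idx;
    return idx;
  };
  // six tetrahedra per cube, all sharing the 0-6 diagonal
  const int tets[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                          {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        long corner[8] = {gid(i, j, k),         gid(i + 1, j, k),
                          gid(i + 1, j + 1, k), gid(i, j + 1, k),
                          gid(i, j, k + 1),     gid(i + 1, j, k + 1),
                          gid(i + 1, j + 1, k + 1), gid(i, j + 1, k + 1)};
        for (int tt = 0; tt < 6; ++tt) {
          long g[4];
          bool in[4];
          int nin = 0;
          for (int m = 0; m < 4; ++m) {
            g[m] = corner[tets[tt][m]];
            in[m] = v[g[m]] > 0;
            if (in[m]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            bool target = (nin == 1);
            int lone = 0;
            for (int m = 0; m < 4; ++m) if (in[m] == target) lone = m;
            int o[3], c = 0;
            for (int m = 0; m < 4; ++m) if (m != lone) o[c++] = m;
            int a = edge_pt(g[lone], g[o[0]]);
            int b = edge_pt(g[lone], g[o[1]]);
            int d = edge_pt(g[lone], g[o[2]]);
            TA.push_back(a); TB.push_back(b); TC.push_back(d);
          } else {
            int ins[2], outs[2], ci = 0, co = 0;
            for (int m = 0; m < 4; ++m) (in[m] ? ins[ci++] : outs[co++]) = m;
            int p00 = edge_pt(g[ins[0]], g[outs[0]]);
            int p01 = edge_pt(g[ins[0]], g[outs[1]]);
            int p10 = edge_pt(g[ins[1]], g[outs[0]]);
            int p11 = edge_pt(g[ins[1]], g[outs[1]]);
            TA.push_back(p00); TB.push_back(p01); TC.push_back(p11);
            TA.push_back(p00); TB.push_back(p11); TC.push_back(p10);
          }
        }
      }
  NumericMatrix Vm(VX.size(), 3);
  for (size_t m = 0; m < VX.size(); ++m) {
    Vm(m, 0) = VX[m]; Vm(m, 1) = VY[m]; Vm(m, 2) = VZ[m];
  }
  IntegerMatrix Fm(TA.size(), 3);
  for (size_t m = 0; m < TA.size(); ++m) {
    Fm(m, 0) = TA[m]; Fm(m, 1) = TB[m]; Fm(m, 2) = TC[m];
  }
  return List::create(_["vertices"] = Vm, _["triangles"] = Fm);
}

// ------------------------------------------------ beam internal forces

struct ElemProps {
  std::vector<double> L0, EA, GAs, EI, GJ;
  std::vector<V3> Gamma0, kappa0;
  std::vector<int> na, nb;  // 0-based end-node indices per element
  int ne;
};

static ElemProps read_elems(List elem) {
  ElemProps e;
  NumericVector L0 = elem["L0"], EA = elem["EA"], GAs = elem["GAs"],
               EI = elem["EI"], GJ = elem["GJ"];
  NumericMatrix G0 = elem["Gamma0"], K0 = elem["kappa0"];
  IntegerVector na = elem["nodeA"], nb = elem["nodeB"];
  e.ne = L0.size();
  for (int i = 0; i < e.ne; ++i) {
    e.na.push_back(na[i] - 1);
    e.nb.push_back(nb[i] - 1);
  }
  e.L0.assign(L0.begin(), L0.end());
  e.EA.assign(EA.begin(), EA.end());
  e.GAs.assign(GAs.begin(), GAs.end());
  e.EI.assign(EI.begin(), EI.end());
  e.GJ.assign(GJ.begin(), GJ.end());
  for (int i = 0; i < e.ne; ++i) {
    e.Gamma0.push_back(V3(G0(i, 0), G0(i, 1), G0(i, 2)));
    e.kappa0.push_back(V3(K0(i, 0), K0(i, 1), K0(i, 2)));
  }
  return e;
}

// element strain measures in the corotated (material) frame
static void elem_strains(const V3* x, const Q4* q, const ElemProps& ep, int e,
                         V3& Gamma, V3& kappa, Q4& qe) {
  int i = ep.na[e], j = ep.nb[e];
  Q4 qj = q[j];
  double dq = q[i].w * qj.w + q[i].x * qj.x + q[i].y * qj.y + q[i].z * qj.z;
  if (dq < 0) { qj = Q4(-qj.w, -qj.x, -qj.y, -qj.z); }
  qe = qnorm(Q4(q[i].w + qj.w, q[i].x + qj.x, q[i].y + qj.y, q[i].z + qj.z));
  V3 d = x[j] - x[i];
  Gamma = (1.0 / ep.L0[e]) * qrotT(qe, d);
  Q4 rel = qmul(qconj(q[i]), qj);
  if (rel.w < 0) rel = Q4(-rel.w, -rel.x, -rel.y, -rel.z);
  kappa = (2.0 / ep.L0[e]) * V3(rel.x, rel.y, rel.z);
}

// accumulate internal forces; elastic resultants go to F/T, viscous
// (stiffness-proportional damping) resultants to Fd/Td when given;
// returns elastic strain energy
static double internal_forces(const V3* x, const Q4* q, const ElemProps& ep,
                              V3* F, V3* T, V3* Fd, V3* Td,
                              std::vector<V3>* Gprev, std::vector<V3>* Kprev,
                              double beta, double dt) {
  double U = 0.0;
  for (int e = 0; e < ep.ne; ++e) {
    V3 Gamma, kappa; Q4 qe;
    elem_strains(x, q, ep, e, Gamma, kappa, qe);
    V3 dG = Gamma - ep.Gamma0[e];
    V3 dK = kappa - ep.kappa0[e];
    V3 n_m(ep.EA[e] * dG.x, ep.GAs[e] * dG.y, ep.GAs[e] * dG.z);
    V3 m_m(ep.GJ[e] * dK.x, ep.EI[e] * dK.y, ep.EI[e] * dK.z);
    U += 0.5 * ep.L0[e] * (dot(n_m, dG) + dot(m_m, dK));
    int i = ep.na[e], j = ep.nb[e];
    V3 d = x[j] - x[i];
    if (beta > 0 && Gprev && Fd) {
      V3 Gdot = (1.0 / dt) * (Gamma - (*Gprev)[e]);
      V3 Kdot = (1.0 / dt) * (kappa - (*Kprev)[e]);
      V3 nv(beta * ep.EA[e] * Gdot.x, beta * ep.GAs[e] * Gdot.y,
            beta * ep.GAs[e] * Gdot.z);
      V3 mv(beta * ep.GJ[e] * Kdot.x, beta * ep.EI[e] * Kdot.y,
            beta * ep.EI[e] * Kdot.z);
      V3 nv_sp = qrot(qe, nv);
      V3 mv_sp = qrot(qe, mv);
      V3 lev = 0.5 * cross(d, nv_sp);
      Fd[i] = Fd[i] + nv_sp; Fd[j] = Fd[j] - nv_sp;
      Td[i] = Td[i] + lev + mv_sp; Td[j] = Td[j] + lev - mv_sp;
    }
    if (Gprev) { (*Gprev)[e] = Gamma; (*Kprev)[e] = kappa; }
    V3 n_sp = qrot(qe, n_m);
    V3 m_sp = qrot(qe, m_m);
    V3 lever = 0.5 * cross(d, n_sp);
    F[i] = F[i] + n_sp;
    F[j] = F[j] - n_sp;
    T[i] = T[i] + lever + m_sp;
    T[j] = T[j] + lever - m_sp;
  }
  return U;
}

// [[Rcpp::export]]
List cpp_internal_forces(NumericMatrix x, NumericMatrix q, List elem) {
  int N = x.nrow();
  std::vector<V3> xs(N), F(N), T(N);
  std::vector<Q4> qs(N);
  for (int i = 0; i < N; ++i) {
    xs[i] = V3(x(i, 0), x(i, 1), x(i, 2));
    qs[i] = Q4(q(i, 0), q(i, 1), q(i, 2), q(i, 3));
  }
  ElemProps ep = read_elems(elem);
  double U = internal_forces(xs.data(), qs.data(), ep, F.data(), T.data(),
                             nullptr, nullptr, nullptr, nullptr, 0.0, 1.0);
  NumericMatrix Fo(N, 3), To(N, 3);
  for (int i = 0; i < N; ++i) {
    Fo(i, 0) = F[i].x; Fo(i, 1) = F[i].y; Fo(i, 2) = F[i].z;
    To(i, 0) = T[i].x; To(i, 1) = T[i].y; To(i, 2) = T[i].z;
  }
  return List::create(_["force"] = Fo, _["torque"] = To, _["energy"] = U);
}

// ------------------------------------------------ barriers

struct TubeBarrier {
  std::vector<V3> path;
  std::vector<double> s;
  double radius, mu, funnel_len, funnel_slope, s_max;
};

struct MeshBarrier {
  std::vector<V3> A, B, C, nrm, cen;
  std::vector<double> rbound;
  double mu, thickness;
  bool keep_inside;  // true: node stays r_c inside; false: node stays r_c
                     // on the +normal side (one-sided cover)
  // cheap sphere prunes: nodes closer than skip_in_r to pcen, or farther
  // than skip_out_r, cannot be in contact (negative = disabled)
  V3 pcen;
  double skip_in_r, skip_out_r;
};

// nearest point on a polyline; returns arc-length position and point
static double nearest_on_path(const std::vector<V3>& p,
                              const std::vector<double>& s, V3 x,
                              V3& cp, V3& tangent) {
  double best = R_PosInf, sbest = 0;
  V3 cbest = p[0], tbest = p[1] - p[0];
  for (size_t i = 0; i + 1 < p.size(); ++i) {
    V3 ab = p[i + 1] - p[i];
    double L2 = std::max(1e-14, dot(ab, ab));
    double t = std::min(1.0, std::max(0.0, dot(x - p[i], ab) / L2));
    V3 c = p[i] + t * ab;
    double d = norm(x - c);
    if (d < best) {
      best = d; cbest = c; tbest = ab;
      sbest = s[i] + t * (s[i + 1] - s[i]);
    }
  }
  cp = cbest;
  double tn = norm(tbest);
  tangent = tn > 1e-14 ? (1.0 / tn) * tbest : V3(1, 0, 0);
  return sbest;
}

// position on path at arc length sv (clamped; extrapolates past the ends
// along the end tangents)
static V3 path_at(const std::vector<V3>& p, const std::vector<double>& s,
                  double sv) {
  size_t n = p.size();
  if (sv <= s[0]) {
    V3 t = p[1] - p[0];
    return p[0] + ((sv - s[0]) / std::max(1e-14, norm(t))) * t;
  }
  if (sv >= s[n - 1]) {
    V3 t = p[n - 1] - p[n - 2];
    return p[n - 1] + ((sv - s[n - 1]) / std::max(1e-14, norm(t))) * t;
  }
  size_t lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    size_t mid = (lo + hi) / 2;
    if (s[mid] <= sv) lo = mid; else hi = mid;
  }
  double t = (sv - s[lo]) / std::max(1e-14, s[lo + 1] - s[lo]);
  return p[lo] + t * (p[lo + 1] - p[lo]);
}

static double smooth_step01(double xi) {
  if (xi <= 0) return 0.0;
  if (xi >= 1) return 1.0;
  return xi * xi * xi * (10.0 - 15.0 * xi + 6.0 * xi * xi);
}

// ------------------------------------------------ main simulation loop

// [[Rcpp::export]]
List cpp_run_sim(NumericMatrix x0, NumericMatrix q0, NumericMatrix v0,
                 NumericMatrix w0, List elem, NumericVector mass,
                 NumericVector inertia, List config, List bcs, List tubes,
                 List meshes, NumericMatrix ext_force,
                 IntegerVector fixed_nodes) {
  int N = x0.nrow();
  std::vector<V3> x(N), v(N), w(N), F(N), T(N), Fd(N), Td(N), vold(N), wold(N);
  std::vector<Q4> q(N);
  for (int i = 0; i < N; ++i) {
    x[i] = V3(x0(i, 0), x0(i, 1), x0(i, 2));
    v[i] = V3(v0(i, 0), v0(i, 1), v0(i, 2));
    w[i] = V3(w0(i, 0), w0(i, 1), w0(i, 2));
    q[i] = Q4(q0(i, 0), q0(i, 1), q0(i, 2), q0(i, 3));
  }
  ElemProps ep = read_elems(elem);
  std::vector<V3> Gprev(ep.ne), Kprev(ep.ne);
  for (int e = 0; e < ep.ne; ++e) {
    Q4 qe;
    elem_strains(x.data(), q.data(), ep, e, Gprev[e], Kprev[e], qe);
  }

  double dt = as<double>(config["dt"]);
  long nsteps = (long)as<double>(config["nsteps"]);
  double alpha = as<double>(config["alpha"]);
  double beta = as<double>(config["beta"]);
  double kn = as<double>(config["kn"]);
  double kt = as<double>(config["kt"]);
  double mu_self = as<double>(config["mu_self"]);
  double r_c = as<double>(config["r_contact"]);
  int checkpoint_every = as<int>(config["checkpoint_every"]);
  bool self_contact = as<bool>(config["self_contact"]);
  int self_skip = as<int>(config["self_skip"]);
  // A fresh state carries v at integer time t=0; the first update is then a
  // half kick so that stored velocities live at half steps thereafter.
  bool half_kick_first = as<bool>(config["half_kick_first"]);
  // viscous damping ratio of penalty contacts (stabilizes chatter)
  double zeta_c = as<double>(config["contact_damping"]);

  std::vector<bool> is_fixed(N, false);
  for (int k = 0; k < fixed_nodes.size(); ++k)
    is_fixed[fixed_nodes[k] - 1] = true;

  // boundary conditions
  struct BC {
    int node;
    std::vector<V3> path;
    std::vector<double> s;
    double s_from, s_to, t0, t1;
  };
  std::vector<BC> bc;
  for (int k = 0; k < bcs.size(); ++k) {
    List b = bcs[k];
    BC o;
    o.node = as<int>(b["node"]) - 1;
    NumericMatrix P = b["path"];
    NumericVector S = b["s"];
    for (int i = 0; i < P.nrow(); ++i)
      o.path.push_back(V3(P(i, 0), P(i, 1), P(i, 2)));
    o.s.assign(S.begin(), S.end());
    o.s_from = as<double>(b["s_from"]);
    o.s_to = as<double>(b["s_to"]);
    o.t0 = as<double>(b["t0"]);
    o.t1 = as<double>(b["t1"]);
    bc.push_back(o);
  }
  std::vector<bool> is_driven(N, false);
  for (auto& b : bc) is_driven[b.node] = true;

  // tube barriers
  std::vector<TubeBarrier> tb;
  for (int k = 0; k < tubes.size(); ++k) {
    List t = tubes[k];
    TubeBarrier o;
    NumericMatrix P = t["path"];
    NumericVector S = t["s"];
    for (int i = 0; i < P.nrow(); ++i)
      o.path.push_back(V3(P(i, 0), P(i, 1), P(i, 2)));
    o.s.assign(S.begin(), S.end());
    o.radius = as<double>(t["radius"]);
    o.mu = as<double>(t["mu"]);
    o.funnel_len = as<double>(t["funnel_len"]);
    o.funnel_slope = as<double>(t["funnel_slope"]);
    o.s_max = as<double>(t["s_max"]);
    tb.push_back(o);
  }
  // mesh barriers
  std::vector<MeshBarrier> mb;
  for (int k = 0; k < meshes.size(); ++k) {
    List m = meshes[k];
    MeshBarrier o;
    NumericMatrix V = m["vertices"];
    IntegerMatrix Fc = m["triangles"];
    for (int i = 0; i < Fc.nrow(); ++i) {
      V3 a(V(Fc(i, 0) - 1, 0), V(Fc(i, 0) - 1, 1), V(Fc(i, 0) - 1, 2));
      V3 b(V(Fc(i, 1) - 1, 0), V(Fc(i, 1) - 1, 1), V(Fc(i, 1) - 1, 2));
      V3 c(V(Fc(i, 2) - 1, 0), V(Fc(i, 2) - 1, 1), V(Fc(i, 2) - 1, 2));
      o.A.push_back(a); o.B.push_back(b); o.C.push_back(c);
      V3 nr = cross(b - a, c - a);
      o.nrm.push_back((1.0 / std::max(1e-14, norm(nr))) * nr);
      V3 cen = (1.0 / 3.0) * (a + b + c);
      o.cen.push_back(cen);
      double rb = std::max(norm(a - cen), std::max(norm(b - cen), norm(c - cen)));
      o.rbound.push_back(rb);
    }
    o.mu = as<double>(m["mu"]);
    o.thickness = as<double>(m["thickness"]);
    o.keep_inside = as<bool>(m["keep_inside"]);
    NumericVector pc = m["prune_center"];
    o.pcen = V3(pc[0], pc[1], pc[2]);
    o.skip_in_r = as<double>(m["skip_in_r"]);
    o.skip_out_r = as<double>(m["skip_out_r"]);
    mb.push_back(o);
  }

  // friction anchors: one per node per barrier (tubes then meshes)
  int nbar = (int)(tb.size() + mb.size());
  std::vector<char> anchor_on((size_t)N * std::max(1, nbar), 0);
  std::vector<V3> anchor((size_t)N * std::max(1, nbar));

  // self-contact broad phase: candidate segment pairs, refreshed
  // periodically with a margin covering the possible travel in between
  std::vector<std::pair<int, int>> sc_pairs;
  long sc_refresh = -1000000;
  const int SC_PERIOD = 16;
  double dissipated = 0.0, ext_work = 0.0, max_pen = 0.0;
  std::vector<double> led_t, led_ke, led_strain, led_contact, led_diss,
      led_work;
  bool store_positions = as<bool>(config["store_positions"]);
  List traj;
  std::string status = "ok";

  auto kinetic = [&]() {
    double ke = 0;
    for (int i = 0; i < N; ++i)
      ke += 0.5 * mass[i] * dot(v[i], v[i]) + 0.5 * inertia[i] * dot(w[i], w[i]);
    return ke;
  };

  double U = 0.0, Cpot = 0.0;
  long it = 0;
  for (it = 0; it < nsteps; ++it) {
    double t = it * dt;
    for (int i = 0; i < N; ++i) { F[i] = V3(); T[i] = V3(); Fd[i] = V3(); Td[i] = V3(); }
    // elastic internal forces to F/T, viscous (beta) damping to Fd/Td
    U = internal_forces(x.data(), q.data(), ep, F.data(), T.data(),
                        Fd.data(), Td.data(), &Gprev, &Kprev, beta, dt);
    // mass-proportional damping
    for (int i = 0; i < N; ++i) {
      Fd[i] = Fd[i] - (alpha * mass[i]) * v[i];
      Td[i] = Td[i] - (alpha * inertia[i]) * w[i];
    }

    // ---- contact ----
    Cpot = 0.0;
    // nodes inside a catheter tube are shielded from mesh barriers
    std::vector<char> in_tube(N, 0);
    // analytic tube confinement
    for (size_t kb = 0; kb < tb.size(); ++kb) {
      TubeBarrier& tu = tb[kb];
      size_t npth = tu.path.size();
      V3 t_in = tu.path[1] - tu.path[0];
      t_in = (1.0 / std::max(1e-14, norm(t_in))) * t_in;
      V3 t_out = tu.path[npth - 1] - tu.path[npth - 2];
      t_out = (1.0 / std::max(1e-14, norm(t_out))) * t_out;
      for (int i = 0; i < N; ++i) {
        V3 cp, tg;
        double sv = nearest_on_path(tu.path, tu.s, x[i], cp, tg);
        // extend the axis beyond both ends so funnel/exit regions use
        // radial (not point) distance
        double proj0 = dot(x[i] - tu.path[0], t_in);
        if (proj0 < 0) { sv = tu.s[0] + proj0; cp = tu.path[0] + proj0 * t_in; }
        double proj1 = dot(x[i] - tu.path[npth - 1], t_out);
        if (proj1 > 0) sv = tu.s[npth - 1] + proj1;
        if (sv > tu.s_max) continue;
        if (norm(x[i] - cp) < tu.radius + r_c && sv > tu.s[0]) in_tube[i] = 1;
        double R = tu.radius;
        bool in_funnel = false;
        if (sv < tu.s[0]) {
          double back = tu.s[0] - sv;
          if (back > tu.funnel_len) continue;
          R = tu.radius + tu.funnel_slope * back;
          in_funnel = true;
        }
        V3 rad = x[i] - cp;
        double dr = norm(rad);
        if (dr < 1e-12) continue;
        V3 nhat = (1.0 / dr) * rad;  // outward radial
        // tube region: thin physical wall at radius R (two-sided);
        // funnel region: one-sided converging cone that always confines,
        // pushing along the true cone normal (inward and backward) so the
        // wedge reaction is conservative
        double pen;
        V3 pushdir;
        if (in_funnel) {
          double cs = 1.0 / std::sqrt(1.0 + tu.funnel_slope * tu.funnel_slope);
          pen = (dr + r_c - R) * cs;
          V3 saxis = (sv < tu.s[0]) ? t_in : tg;
          pushdir = cs * ((-1.0) * nhat - tu.funnel_slope * saxis);
        } else if (dr <= R) {
          pen = dr + r_c - R;
          pushdir = (-1.0) * nhat;
        } else {
          pen = R + r_c - dr;
          pushdir = nhat;
        }
        if (pen <= 0) continue;
        double Nf = kn * pen;
        double vn = dot(v[i], pushdir);
        double fdmp = -2.0 * zeta_c * std::sqrt(kn * mass[i]) * std::min(vn, 0.0);
        F[i] = F[i] + Nf * pushdir;
        Fd[i] = Fd[i] + fdmp * pushdir;
        Cpot += 0.5 * kn * pen * pen;
        if (pen > max_pen) max_pen = pen;
        size_t ai = (size_t)i * nbar + kb;
        if (tu.mu > 0) {
          if (!anchor_on[ai]) { anchor[ai] = x[i]; anchor_on[ai] = 1; }
          V3 disp = x[i] - anchor[ai];
          V3 dtan = disp - dot(disp, nhat) * nhat;
          V3 ft = (-kt) * dtan;
          double cap = tu.mu * Nf, mag = norm(ft);
          if (mag > cap && mag > 1e-14) {
            ft = (cap / mag) * ft;
            anchor[ai] = x[i] + (1.0 / kt) * ft;
          }
          Fd[i] = Fd[i] + ft;
        } else {
          anchor_on[ai] = 0;
        }
      }
    }
    // rigid mesh barriers
    for (size_t kb = 0; kb < mb.size(); ++kb) {
      MeshBarrier& me = mb[kb];
      int nf = (int)me.A.size();
      for (int i = 0; i < N; ++i) {
        if (in_tube[i]) continue;
        double dpc = norm(x[i] - me.pcen);
        if (me.skip_in_r > 0 && dpc < me.skip_in_r) continue;
        if (me.skip_out_r > 0 && dpc > me.skip_out_r) continue;
        // nearest triangle with centroid pruning
        double bestd = R_PosInf;
        int bestt = -1;
        V3 bestp;
        for (int ti = 0; ti < nf; ++ti) {
          double dc = norm(x[i] - me.cen[ti]) - me.rbound[ti];
          if (dc > bestd) continue;
          V3 p = closest_on_triangle(x[i], me.A[ti], me.B[ti], me.C[ti]);
          double d = norm(x[i] - p);
          if (d < bestd) { bestd = d; bestt = ti; bestp = p; }
        }
        if (bestt < 0) continue;
        V3 nf3 = me.nrm[bestt];
        double signedd = dot(x[i] - bestp, nf3);  // >0 on +normal side
        double pen;
        V3 pushdir;
        if (me.keep_inside) {
          // stay at least r_c on the -normal side (inside the solid)
          pen = signedd + r_c;
          pushdir = (-1.0) * nf3;
          if (signedd > me.thickness) continue;
        } else {
          pen = r_c - signedd;
          pushdir = nf3;
          if (signedd < -me.thickness) continue;
        }
        if (pen <= 0) continue;
        double Nf = kn * pen;
        double vn = dot(v[i], pushdir);
        double fdmp = -2.0 * zeta_c * std::sqrt(kn * mass[i]) * std::min(vn, 0.0);
        F[i] = F[i] + Nf * pushdir;
        Fd[i] = Fd[i] + fdmp * pushdir;
        Cpot += 0.5 * kn * pen * pen;
        if (pen > max_pen) max_pen = pen;
        size_t ai = (size_t)i * nbar + tb.size() + kb;
        if (me.mu > 0) {
          V3 nhat = pushdir;
          if (!anchor_on[ai]) { anchor[ai] = x[i]; anchor_on[ai] = 1; }
          V3 disp = x[i] - anchor[ai];
          V3 dtan = disp - dot(disp, nhat) * nhat;
          V3 ft = (-kt) * dtan;
          double cap = me.mu * Nf, mag = norm(ft);
          if (mag > cap && mag > 1e-14) {
            ft = (cap / mag) * ft;
            anchor[ai] = x[i] + (1.0 / kt) * ft;
          }
          Fd[i] = Fd[i] + ft;
        }
      }
      // clear anchors for nodes that left contact
      for (int i = 0; i < N; ++i) {
        size_t ai = (size_t)i * nbar + tb.size() + kb;
        // cheap heuristic: anchor expires if spring stretched beyond 4 r_c
        if (anchor_on[ai] && norm(x[i] - anchor[ai]) > 4 * r_c)
          anchor_on[ai] = 0;
      }
    }
    // coil self contact (segment-segment, penalty at distance < 2 r_c)
    if (self_contact && ep.ne > 1) {
      if (it - sc_refresh >= SC_PERIOD) {
        // margin: fastest node can close the gap from both sides
        double vmax = 0.0;
        for (int i = 0; i < N; ++i) vmax = std::max(vmax, norm(v[i]));
        double margin = 2.0 * vmax * dt * SC_PERIOD + 0.1;
        sc_pairs.clear();
        for (int e1 = 0; e1 < ep.ne; ++e1)
          for (int e2 = e1 + 1; e2 < ep.ne; ++e2) {
            int a1 = ep.na[e1], a2 = ep.na[e2];
            if (std::abs(a1 - a2) <= self_skip) continue;
            double s1, s2;
            double d = seg_seg_dist(x[a1], x[ep.nb[e1]], x[a2],
                                    x[ep.nb[e2]], s1, s2);
            if (d < 2 * r_c + margin)
              sc_pairs.push_back(std::make_pair(e1, e2));
          }
        sc_refresh = it;
      }
      for (auto& pr : sc_pairs) {
          int e1 = pr.first, e2 = pr.second;
          int a1 = ep.na[e1], b1 = ep.nb[e1];
          int a2 = ep.na[e2], b2 = ep.nb[e2];
          double s1, s2;
          double d = seg_seg_dist(x[a1], x[b1], x[a2], x[b2], s1, s2);
          double pen = 2 * r_c - d;
          if (pen <= 0 || d < 1e-12) continue;
          V3 c1 = x[a1] + s1 * (x[b1] - x[a1]);
          V3 c2 = x[a2] + s2 * (x[b2] - x[a2]);
          V3 nhat = (1.0 / d) * (c1 - c2);
          double Nf = kn * pen;
          V3 fn = Nf * nhat;
          Cpot += 0.5 * kn * pen * pen;
          if (pen > max_pen) max_pen = pen;
          V3 v1 = (1 - s1) * v[a1] + s1 * v[b1];
          V3 v2 = (1 - s2) * v[a2] + s2 * v[b2];
          V3 vrel = v1 - v2;
          double vn = dot(vrel, nhat);
          double mred = 0.25 * (mass[a1] + mass[b1] + mass[a2] + mass[b2]);
          V3 fvis = (-2.0 * zeta_c * std::sqrt(kn * mred) * std::min(vn, 0.0)) * nhat;
          // friction: regularized Coulomb on relative tangential velocity
          V3 vt = vrel - vn * nhat;
          double vtn = norm(vt);
          V3 ftf;
          if (mu_self > 0 && vtn > 1e-12)
            ftf = (-mu_self * Nf * vtn / (vtn + 0.01) / vtn) * vt;
          V3 fdiss = fvis + ftf;
          F[a1] = F[a1] + (1 - s1) * fn;
          F[b1] = F[b1] + s1 * fn;
          F[a2] = F[a2] - (1 - s2) * fn;
          F[b2] = F[b2] - s2 * fn;
          Fd[a1] = Fd[a1] + (1 - s1) * fdiss;
          Fd[b1] = Fd[b1] + s1 * fdiss;
          Fd[a2] = Fd[a2] - (1 - s2) * fdiss;
          Fd[b2] = Fd[b2] - s2 * fdiss;
      }
    }

    // ---- integrate ----
    double tnew = t + dt;
    double kick = (it == 0 && half_kick_first) ? 0.5 * dt : dt;
    for (int i = 0; i < N; ++i) { vold[i] = v[i]; wold[i] = w[i]; }
    for (int i = 0; i < N; ++i) {
      V3 fx(ext_force(i, 0), ext_force(i, 1), ext_force(i, 2));
      if (is_fixed[i]) { v[i] = V3(); w[i] = V3(); continue; }
      if (is_driven[i]) continue;
      v[i] = v[i] + (kick / mass[i]) * (F[i] + Fd[i] + fx);
      w[i] = w[i] + (kick / inertia[i]) * (T[i] + Td[i]);
    }
    for (auto& b : bc) {
      double xi = (tnew - b.t0) / std::max(1e-14, b.t1 - b.t0);
      double sv = b.s_from + (b.s_to - b.s_from) * smooth_step01(xi);
      V3 xt = path_at(b.path, b.s, sv);
      V3 vnew = (1.0 / dt) * (xt - x[b.node]);
      V3 react = (mass[b.node] / dt) * (vnew - vold[b.node]) -
                 (F[b.node] + Fd[b.node]);
      ext_work += dot(react, (0.5 * dt) * (vnew + vold[b.node]));
      v[b.node] = vnew;
      w[b.node] = w[b.node] +
                  (dt / inertia[b.node]) * (T[b.node] + Td[b.node]);
    }
    // work of applied forces and dissipation, with midpoint velocities so
    // the discrete ledger closes
    for (int i = 0; i < N; ++i) {
      V3 vm = 0.5 * (v[i] + vold[i]);
      V3 wm = 0.5 * (w[i] + wold[i]);
      V3 fx(ext_force(i, 0), ext_force(i, 1), ext_force(i, 2));
      if (dot(fx, fx) > 0) ext_work += dt * dot(fx, vm);
      dissipated -= dt * (dot(Fd[i], vm) + dot(Td[i], wm));
      x[i] = x[i] + dt * v[i];
      double wn = norm(w[i]);
      if (wn > 1e-14) {
        double half = 0.5 * wn * dt;
        V3 u = (1.0 / wn) * w[i];
        Q4 dqr(std::cos(half), std::sin(half) * u.x, std::sin(half) * u.y,
               std::sin(half) * u.z);
        q[i] = qnorm(qmul(dqr, q[i]));
      }
    }

    if ((it & 0x3F) == 0) {
      bool bad = false;
      for (int i = 0; i < N && !bad; ++i)
        if (!std::isfinite(x[i].x) || !std::isfinite(x[i].y) ||
            !std::isfinite(x[i].z) || std::fabs(x[i].x) > 1e6)
          bad = true;
      if (bad) { status = "diverged"; break; }
    }
    if (checkpoint_every > 0 && (it + 1) % checkpoint_every == 0) {
      led_t.push_back(tnew);
      led_ke.push_back(kinetic());
      led_strain.push_back(U);
      led_contact.push_back(Cpot);
      led_diss.push_back(dissipated);
      led_work.push_back(ext_work);
      if (store_positions) {
        NumericMatrix snap(N, 3);
        for (int i = 0; i < N; ++i) {
          snap(i, 0) = x[i].x; snap(i, 1) = x[i].y; snap(i, 2) = x[i].z;
        }
        traj.push_back(snap);
      }
    }
  }

  NumericMatrix xo(N, 3), qo(N, 4), vo(N, 3), wo(N, 3);
  for (int i = 0; i < N; ++i) {
    xo(i, 0) = x[i].x; xo(i, 1) = x[i].y; xo(i, 2) = x[i].z;
    vo(i, 0) = v[i].x; vo(i, 1) = v[i].y; vo(i, 2) = v[i].z;
    wo(i, 0) = w[i].x; wo(i, 1) = w[i].y; wo(i, 2) = w[i].z;
    qo(i, 0) = q[i].w; qo(i, 1) = q[i].x; qo(i, 2) = q[i].y; qo(i, 3) = q[i].z;
  }
  return List::create(
      _["x"] = xo, _["q"] = qo, _["v"] = vo, _["w"] = wo,
      _["strain_energy"] = U, _["contact_energy"] = Cpot,
      _["kinetic_energy"] = kinetic(), _["dissipated"] = dissipated,
      _["ext_work"] = ext_work, _["max_penetration"] = max_pen,
      _["status"] = status, _["steps_done"] = (double)it,
      _["trajectory"] = traj,
      _["ledger"] = List::create(
          _["t"] = wrap(led_t), _["kinetic"] = wrap(led_ke),
          _["strain"] = wrap(led_strain), _["contact"] = wrap(led_contact),
          _["dissipated"] = wrap(led_diss), _["ext_work"] = wrap(led_work)));
}
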