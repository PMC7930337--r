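// 2D rod-and-spring body in a linear-drag (agar) environment, plus the
// coupled circuit -> muscle -> body simulation loop.
//
// The body is a chain of n_seg segments bounded by n_seg+1 rigid rods. Rod i
// has generalized coordinates (x, y, phi); its endpoints sit at
// c +/- w_i * d(phi) with d = (cos phi, sin phi). The dorsal endpoint is the
// +d side. Segments are braced by damped-spring lateral elements (dorsal and
// ventral cuticle) and two damped-spring diagonals (internal pressure).
// Muscles contract lateral elements. The medium exerts linear drag with a
// 40-fold anisotropy between motion along the midline and lateral slip.
//
// Dynamics are overdamped: C(x) v = F_internal(x, v) + F_muscle. The
// production integrator is a linearized backward-Euler step (elastic Jacobian
// treated implicitly, Baraff-Witkin style, with the compressive branch of the
// Jacobian clamped); damping is always implicit in v. The resulting linear
// system is block-tridiagonal (3x3 blocks) and solved by a block Thomas
// algorithm. An elastic-explicit reference integrator is kept for
// convergence testing.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Vec2 { double x, y; };
static inline Vec2 v2(double x, double y) { return {x, y}; }
static inline Vec2 operator-(Vec2 a, Vec2 b) { return {a.x - b.x, a.y - b.y}; }
static inline double dot(Vec2 a, Vec2 b) { return a.x * b.x + a.y * b.y; }

// 3x3 blocks stored row-major
typedef double Mat3[9];
typedef double Mat2[4];

static inline void m3_zero(Mat3 m) { for (int k = 0; k < 9; ++k) m[k] = 0; }

// m += Ja^T * M2 * Jb where J = [[1,0,ax],[0,1,ay]] (point Jacobian with
// moment arm a = dp/dphi), M2 a 2x2 row-major block, and sgn +/-1.
static inline void add_JtMJ(Mat3 m, const Mat2 M2, Vec2 aa, Vec2 ab,
                            double sgn) {
  // T = M2 * Jb : 2x3
  double T[6] = {M2[0], M2[1], M2[0] * ab.x + M2[1] * ab.y,
                 M2[2], M2[3], M2[2] * ab.x + M2[3] * ab.y};
  // Ja^T * T : rows of Ja^T are (1,0),(0,1),(aa.x,aa.y)
  for (int c = 0; c < 3; ++c) {
    m[0 * 3 + c] += sgn * T[c];
    m[1 * 3 + c] += sgn * T[3 + c];
    m[2 * 3 + c] += sgn * (aa.x * T[c] + aa.y * T[3 + c]);
  }
}

static inline bool m3_invert(const Mat3 m, Mat3 inv) {
  const double a = m[0], b = m[1], c = m[2], d = m[3], e = m[4], f = m[5],
               g = m[6], h = m[7], i = m[8];
  const double A = e * i - f * h, B = -(d * i - f * g), C = d * h - e * g;
  const double det = a * A + b * B + c * C;
  if (std::abs(det) < 1e-300) return false;
  const double id = 1.0 / det;
  inv[0] = A * id; inv[1] = -(b * i - c * h) * id; inv[2] = (b * f - c * e) * id;
  inv[3] = B * id; inv[4] = (a * i - c * g) * id;  inv[5] = -(a * f - c * d) * id;
  inv[6] = C * id; inv[7] = -(a * h - b * g) * id; inv[8] = (a * e - b * d) * id;
  return true;
}

static inline void m3_mul(const Mat3 a, const Mat3 b, Mat3 out) {
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c)
      out[r * 3 + c] = a[r * 3] * b[c] + a[r * 3 + 1] * b[3 + c] +
                       a[r * 3 + 2] * b[6 + c];
}

static inline void m3_mulvec(const Mat3 a, const double *v, double *out) {
  for (int r = 0; r < 3; ++r)
    out[r] = a[r * 3] * v[0] + a[r * 3 + 1] * v[1] + a[r * 3 + 2] * v[2];
}

struct Geom {
  int n_seg, n_rod;
  std::vector<double> w;                      // rod half-widths
  std::vector<double> l0_lat, l0_diag;        // rest lengths per segment
  std::vector<double> k_lat, c_lat, k_diag, c_diag;
  double Cpar, Cperp;
  std::vector<double> c_rot;
  // Hill-type muscle properties
  double Fmax, fl_width, fv_vmax, fv_hill, fv_cap;
};

Geom make_geom(int n_seg, NumericVector w, NumericVector l0_lat,
               NumericVector l0_diag, NumericVector k_lat, NumericVector c_lat,
               NumericVector k_diag, NumericVector c_diag, double Cpar,
               double Cperp, NumericVector c_rot, double Fmax, double fl_width,
               double fv_vmax, double fv_hill, double fv_cap) {
  Geom g;
  g.n_seg = n_seg;
  g.n_rod = n_seg + 1;
  g.w.assign(w.begin(), w.end());
  g.l0_lat.assign(l0_lat.begin(), l0_lat.end());
  g.l0_diag.assign(l0_diag.begin(), l0_diag.end());
  g.k_lat.assign(k_lat.begin(), k_lat.end());
  g.c_lat.assign(c_lat.begin(), c_lat.end());
  g.k_diag.assign(k_diag.begin(), k_diag.end());
  g.c_diag.assign(c_diag.begin(), c_diag.end());
  g.Cpar = Cpar;
  g.Cperp = Cperp;
  g.c_rot.assign(c_rot.begin(), c_rot.end());
  g.Fmax = Fmax;
  g.fl_width = fl_width;
  g.fv_vmax = fv_vmax;
  g.fv_hill = fv_hill;
  g.fv_cap = fv_cap;
  if ((int)g.w.size() != g.n_rod) stop("width profile must have n_seg+1 values");
  return g;
}

struct BodyState {
  std::vector<double> x, y, phi, vx, vy, vphi;
};

// force-length: parabolic around rest length, zero beyond +/- fl_width strain
static inline double f_length(double ratio, double width) {
  const double s = (ratio - 1.0) / width;
  const double v = 1.0 - s * s;
  return v > 0 ? v : 0.0;
}

// force-velocity on the shortening strain rate (Hill hyperbola on the
// shortening side, saturating mild enhancement when lengthening)
static inline double f_velocity(double shorten_rate, double vmax, double hill,
                                double cap) {
  if (shorten_rate >= 0) {
    const double s = shorten_rate >= vmax ? 1.0 : shorten_rate / vmax;
    return (1.0 - s) / (1.0 + hill * s);
  }
  const double s = -shorten_rate / vmax;
  const double fv = 1.0 + 0.5 * (s > 1.0 ? 1.0 : s);
  return fv > cap ? cap : fv;
}

// One overdamped step. driveD/driveV: per-segment muscle drives (sum of
// weighted activations) for the dorsal/ventral lateral elements. implicit =
// true uses the linearized backward-Euler elastic term. Returns false when a
// degenerate element or singular solve is met.
bool body_step_core(BodyState &st, const Geom &g, const double *driveD,
                    const double *driveV, double dt, bool implicit) {
  const int n = g.n_rod;
  std::vector<Mat3> Bd(n), Bu(g.n_seg), Bl(g.n_seg);
  std::vector<double> rhs(3 * n, 0.0);
  for (int i = 0; i < n; ++i) m3_zero(Bd[i]);
  for (int i = 0; i < g.n_seg; ++i) { m3_zero(Bu[i]); m3_zero(Bl[i]); }

  // drag blocks
  for (int i = 0; i < n; ++i) {
    const double cp = std::cos(st.phi[i]), sp = std::sin(st.phi[i]);
    // rod axis d (dorsoventral): lateral slip, high drag;
    // midline tangent t = d-perp: low drag
    Bd[i][0] = g.Cpar * sp * sp + g.Cperp * cp * cp;
    Bd[i][1] = Bd[i][3] = (g.Cperp - g.Cpar) * cp * sp;
    Bd[i][4] = g.Cpar * cp * cp + g.Cperp * sp * sp;
    Bd[i][8] = g.c_rot[i];
  }

  // elements: 4 per segment (lateral D, lateral V, 2 diagonals)
  for (int i = 0; i < g.n_seg; ++i) {
    const int j = i + 1;
    const double cpi = std::cos(st.phi[i]), spi = std::sin(st.phi[i]);
    const double cpj = std::cos(st.phi[j]), spj = std::sin(st.phi[j]);
    const Vec2 di = v2(cpi, spi), dj = v2(cpj, spj);
    const Vec2 ci = v2(st.x[i], st.y[i]), cj = v2(st.x[j], st.y[j]);

    const int sa[4] = {+1, -1, +1, -1};
    const int sb[4] = {+1, -1, -1, +1};
    for (int e = 0; e < 4; ++e) {
      const bool lat = e < 2;
      const double k = lat ? g.k_lat[i] : g.k_diag[i];
      const double c = lat ? g.c_lat[i] : g.c_diag[i];
      const double l0 = lat ? g.l0_lat[i] : g.l0_diag[i];

      const Vec2 pa = v2(ci.x + sa[e] * g.w[i] * di.x,
                         ci.y + sa[e] * g.w[i] * di.y);
      const Vec2 pb = v2(cj.x + sb[e] * g.w[j] * dj.x,
                         cj.y + sb[e] * g.w[j] * dj.y);
      const Vec2 u = pb - pa;
      const double l = std::sqrt(dot(u, u));
      if (l < 1e-9) return false;
      const Vec2 uh = v2(u.x / l, u.y / l);

      // moment arms dp/dphi
      const Vec2 aa = v2(-sa[e] * g.w[i] * spi, sa[e] * g.w[i] * cpi);
      const Vec2 ab = v2(-sb[e] * g.w[j] * spj, sb[e] * g.w[j] * cpj);

      double f_act = 0.0;
      if (lat) {
        const double drive = (e == 0) ? driveD[i] : driveV[i];
        if (drive != 0.0) {
          const Vec2 va = v2(st.vx[i] + st.vphi[i] * aa.x,
                             st.vy[i] + st.vphi[i] * aa.y);
          const Vec2 vb = v2(st.vx[j] + st.vphi[j] * ab.x,
                             st.vy[j] + st.vphi[j] * ab.y);
          const double dldt = dot(uh, vb - va);
          const double shorten = -dldt / l0;
          f_act = g.Fmax * drive * f_length(l / l0, g.fl_width) *
                  f_velocity(shorten, g.fv_vmax, g.fv_hill, g.fv_cap);
        }
      }

      // scalar element force: positive pulls endpoints together
      const double f = k * (l - l0) + f_act;
      const Vec2 Fa = v2(f * uh.x, f * uh.y);
      // rhs contributions (Ja^T Fa and Jb^T (-Fa))
      rhs[3 * i + 0] += Fa.x;
      rhs[3 * i + 1] += Fa.y;
      rhs[3 * i + 2] += aa.x * Fa.x + aa.y * Fa.y;
      rhs[3 * j + 0] -= Fa.x;
      rhs[3 * j + 1] -= Fa.y;
      rhs[3 * j + 2] -= ab.x * Fa.x + ab.y * Fa.y;

      // velocity-multiplying 2x2: damping + (optionally) dt * elastic Jacobian
      Mat2 M2;
      const double uu[4] = {uh.x * uh.x, uh.x * uh.y, uh.x * uh.y, uh.y * uh.y};
      double kpar = c, kperp = 0.0;
      if (implicit) {
        kpar += dt * k;
        const double tens = 1.0 - l0 / l;
        if (tens > 0) kperp += dt * k * tens;
      }
      M2[0] = kpar * uu[0] + kperp * (1.0 - uu[0]);
      M2[1] = (kpar - kperp) * uu[1];
      M2[2] = M2[1];
      M2[3] = kpar * uu[3] + kperp * (1.0 - uu[3]);

      add_JtMJ(Bd[i], M2, aa, aa, +1.0);
      add_JtMJ(Bd[j], M2, ab, ab, +1.0);
      add_JtMJ(Bu[i], M2, aa, ab, -1.0);  // block (i, j)
      add_JtMJ(Bl[i], M2, ab, aa, -1.0);  // block (j, i)
    }
  }

  // block-tridiagonal Thomas
  std::vector<Mat3> Dp(n);
  std::vector<double> rp(3 * n);
  for (int k = 0; k < 9; ++k) Dp[0][k] = Bd[0][k];
  for (int k = 0; k < 3; ++k) rp[k] = rhs[k];
  Mat3 inv, Wm, WB;
  for (int i = 1; i < n; ++i) {
    if (!m3_invert(Dp[i - 1], inv)) return false;
    m3_mul(Bl[i - 1], inv, Wm);
    m3_mul(Wm, Bu[i - 1], WB);
    for (int k = 0; k < 9; ++k) Dp[i][k] = Bd[i][k] - WB[k];
    double tmp[3];
    m3_mulvec(Wm, &rp[3 * (i - 1)], tmp);
    for (int k = 0; k < 3; ++k) rp[3 * i + k] = rhs[3 * i + k] - tmp[k];
  }
  std::vector<double> v(3 * n);
  if (!m3_invert(Dp[n - 1], inv)) return false;
  m3_mulvec(inv, &rp[3 * (n - 1)], &v[3 * (n - 1)]);
  for (int i = n - 2; i >= 0; --i) {
    double bv[3], tmp[3];
    m3_mulvec(Bu[i], &v[3 * (i + 1)], bv);
    for (int k = 0; k < 3; ++k) tmp[k] = rp[3 * i + k] - bv[k];
    if (!m3_invert(Dp[i], inv)) return false;
    m3_mulvec(inv, tmp, &v[3 * i]);
  }

  for (int i = 0; i < n; ++i) {
    st.vx[i] = v[3 * i];
    st.vy[i] = v[3 * i + 1];
    st.vphi[i] = v[3 * i + 2];
    st.x[i] += dt * st.vx[i];
    st.y[i] += dt * st.vy[i];
    st.phi[i] += dt * st.vphi[i];
  }
  return true;
}

}  // namespace

// Internal (elastic + damping + active muscle) generalized forces for a given
// state, damping evaluated against the supplied velocities. Returns an
// (n_rod x 3) matrix of (Fx, Fy, torque).
// [[Rcpp::export]]
NumericMatrix body_internal_forces_cpp(
    NumericVector x, NumericVector y, NumericVector phi, NumericVector vx,
    NumericVector vy, NumericVector vphi, int n_seg, NumericVector w,
    NumericVector l0_lat, NumericVector l0_diag, NumericVector k_lat,
    NumericVector c_lat, NumericVector k_diag, NumericVector c_diag,
    double Cpar, double Cperp, NumericVector c_rot, double Fmax,
    double fl_width, double fv_vmax, double fv_hill, double fv_cap,
    NumericVector driveD, NumericVector driveV) {
  Geom g = make_geom(n_seg, w, l0_lat, l0_diag, k_lat, c_lat, k_diag, c_diag,
                     Cpar, Cperp, c_rot, Fmax, fl_width, fv_vmax, fv_hill,
                     fv_cap);
  const int n = g.n_rod;
  NumericMatrix out(n, 3);
  for (int i = 0; i < g.n_seg; ++i) {
    const int j = i + 1;
    const double cpi = std::cos(phi[i]), spi = std::sin(phi[i]);
    const double cpj = std::cos(phi[j]), spj = std::sin(phi[j]);
    const int sa[4] = {+1, -1, +1, -1};
    const int sb[4] = {+1, -1, -1, +1};
    for (int e = 0; e < 4; ++e) {
      const bool lat = e < 2;
      const double k = lat ? g.k_lat[i] : g.k_diag[i];
      const double c = lat ? g.c_lat[i] : g.c_diag[i];
      const double l0 = lat ? g.l0_lat[i] : g.l0_diag[i];
      const Vec2 pa = v2(x[i] + sa[e] * g.w[i] * cpi, y[i] + sa[e] * g.w[i] * spi);
      const Vec2 pb = v2(x[j] + sb[e] * g.w[j] * cpj, y[j] + sb[e] * g.w[j] * spj);
      const Vec2 u = pb - pa;
      const double l = std::sqrt(dot(u, u));
      if (l < 1e-9) stop("degenerate element (zero length) in segment %d", i + 1);
      const Vec2 uh = v2(u.x / l, u.y / l);
      const Vec2 aa = v2(-sa[e] * g.w[i] * spi, sa[e] * g.w[i] * cpi);
      const Vec2 ab = v2(-sb[e] * g.w[j] * spj, sb[e] * g.w[j] * cpj);
      const Vec2 va = v2(vx[i] + vphi[i] * aa.x, vy[i] + vphi[i] * aa.y);
      const Vec2 vb = v2(vx[j] + vphi[j] * ab.x, vy[j] + vphi[j] * ab.y);
      const double dldt = dot(uh, vb - va);
      double f_act = 0.0;
      if (lat) {
        const double drive = (e == 0) ? driveD[i] : driveV[i];
        if (drive != 0.0)
          f_act = g.Fmax * drive * f_length(l / l0, g.fl_width) *
                  f_velocity(-dldt / l0, g.fv_vmax, g.fv_hill, g.fv_cap);
      }
      const double f = k * (l - l0) + c * dldt + f_act;
      out(i, 0) += f * uh.x;
      out(i, 1) += f * uh.y;
      out(i, 2) += aa.x * f * uh.x + aa.y * f * uh.y;
      out(j, 0) -= f * uh.x;
      out(j, 1) -= f * uh.y;
      out(j, 2) -= ab.x * f * uh.x + ab.y * f * uh.y;
    }
  }
  return out;
}

// Integrate the body alone under constant per-segment muscle drives.
// [[Rcpp::export]]
List body_run_cpp(NumericVector x0, NumericVector y0, NumericVector phi0,
                  NumericVector vx0, NumericVector vy0, NumericVector vphi0,
                  int n_seg, NumericVector w, NumericVector l0_lat,
                  NumericVector l0_diag, NumericVector k_lat,
                  NumericVector c_lat, NumericVector k_diag,
                  NumericVector c_diag, double Cpar, double Cperp,
                  NumericVector c_rot, double Fmax, double fl_width,
                  double fv_vmax, double fv_hill, double fv_cap,
                  NumericVector driveD, NumericVector driveV, double dt,
                  int n_steps, int record_stride, bool implicit) {
  Geom g = make_geom(n_seg, w, l0_lat, l0_diag, k_lat, c_lat, k_diag, c_diag,
                     Cpar, Cperp, c_rot, Fmax, fl_width, fv_vmax, fv_hill,
                     fv_cap);
  BodyState st;
  st.x.assign(x0.begin(), x0.end());
  st.y.assign(y0.begin(), y0.end());
  st.phi.assign(phi0.begin(), phi0.end());
  st.vx.assign(vx0.begin(), vx0.end());
  st.vy.assign(vy0.begin(), vy0.end());
  st.vphi.assign(vphi0.begin(), vphi0.end());

  const int n_rec = n_steps / record_stride;
  NumericMatrix X(n_rec, g.n_rod), Y(n_rec, g.n_rod), PHI(n_rec, g.n_rod);
  NumericVector trec(n_rec);
  int rec = 0;
  for (int step = 1; step <= n_steps; ++step) {
    if (!body_step_core(st, g, REAL(driveD), REAL(driveV), dt, implicit))
      stop("body integration failed at t = %g s (degenerate element or "
           "singular solve)", step * dt);
    if (step % record_stride == 0) {
      for (int i = 0; i < g.n_rod; ++i) {
        X(rec, i) = st.x[i];
        Y(rec, i) = st.y[i];
        PHI(rec, i) = st.phi[i];
      }
      trec[rec] = step * dt;
      ++rec;
    }
  }
  return List::create(
      _["time"] = trec, _["x"] = X, _["y"] = Y, _["phi"] = PHI,
      _["state"] = List::create(
          _["x"] = NumericVector(st.x.begin(), st.x.end()),
          _["y"] = NumericVector(st.y.begin(), st.y.end()),
          _["phi"] = NumericVector(st.phi.begin(), st.phi.end()),
          _["vx"] = NumericVector(st.vx.begin(), st.vx.end()),
          _["vy"] = NumericVector(st.vy.begin(), st.vy.end()),
          _["vphi"] = NumericVector(st.vphi.begin(), st.vphi.end())));
}

// Full neuromechanical loop. Per macro step (dt_neural): one circuit Euler
// update, one muscle leaky-integrator update, then `substeps` body steps at
// dt_neural/substeps with frozen activations.
// Mdrv: (n_neurons x 48) map from synaptic outputs to muscle drives
//   (columns 1..24 dorsal, 25..48 ventral), entries gamma_m * sign_i * q_i.
// WmD/WmV: (24 x n_seg) muscle-to-lateral-element weights per side.
// [[Rcpp::export]]
List embodied_run_cpp(NumericMatrix W, NumericMatrix G, NumericVector tau,
                      NumericVector theta, NumericVector V0,
                      LogicalVector silenced, NumericVector tonic,
                      NumericMatrix Mdrv, double tauM, NumericMatrix WmD,
                      NumericMatrix WmV, int n_seg, NumericVector w,
                      NumericVector l0_lat, NumericVector l0_diag,
                      NumericVector k_lat, NumericVector c_lat,
                      NumericVector k_diag, NumericVector c_diag, double Cpar,
                      double Cperp, NumericVector c_rot, double Fmax,
                      double fl_width, double fv_vmax, double fv_hill,
                      double fv_cap, NumericVector x0, NumericVector y0,
                      NumericVector phi0, double dt_neural, int substeps,
                      int n_macro, int record_stride) {
  const int n = tau.size();
  const int n_mus = Mdrv.ncol();  // 48 = 24 dorsal + 24 ventral
  const int n_side = n_mus / 2;
  Geom g = make_geom(n_seg, w, l0_lat, l0_diag, k_lat, c_lat, k_diag, c_diag,
                     Cpar, Cperp, c_rot, Fmax, fl_width, fv_vmax, fv_hill,
                     fv_cap);
  if (WmD.nrow() != n_side || WmV.nrow() != n_side)
    stop("muscle-element maps must have 24 rows");

  std::vector<double> V(n), S(n), dV(n), invtau(n);
  std::vector<char> off(n);
  for (int i = 0; i < n; ++i) {
    off[i] = silenced[i] ? 1 : 0;
    V[i] = off[i] ? 0.0 : V0[i];
    invtau[i] = 1.0 / tau[i];
  }
  std::vector<int> w_src, w_dst, g_src, g_dst;
  std::vector<double> w_val, g_val;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (W(j, i) != 0.0) { w_src.push_back(j); w_dst.push_back(i); w_val.push_back(W(j, i)); }
      if (G(j, i) != 0.0) { g_src.push_back(j); g_dst.push_back(i); g_val.push_back(G(j, i)); }
    }
  // sparse muscle->element triplets
  std::vector<int> mD_m, mD_e, mV_m, mV_e;
  std::vector<double> mD_w, mV_w;
  for (int m = 0; m < n_side; ++m)
    for (int e = 0; e < n_seg; ++e) {
      if (WmD(m, e) != 0.0) { mD_m.push_back(m); mD_e.push_back(e); mD_w.push_back(WmD(m, e)); }
      if (WmV(m, e) != 0.0) { mV_m.push_back(m); mV_e.push_back(e); mV_w.push_back(WmV(m, e)); }
    }

  std::vector<double> A(n_mus, 0.0), I(n_mus);
  std::vector<double> driveD(n_seg), driveV(n_seg);
  BodyState st;
  st.x.assign(x0.begin(), x0.end());
  st.y.assign(y0.begin(), y0.end());
  st.phi.assign(phi0.begin(), phi0.end());
  st.vx.assign(g.n_rod, 0.0);
  st.vy.assign(g.n_rod, 0.0);
  st.vphi.assign(g.n_rod, 0.0);

  const double dt_body = dt_neural / substeps;
  const int n_rec = n_macro / record_stride;
  NumericMatrix Srec(n_rec, n), Arec(n_rec, n_mus), X(n_rec, g.n_rod),
      Y(n_rec, g.n_rod);
  NumericVector trec(n_rec);
  int rec = 0;

  for (int step = 1; step <= n_macro; ++step) {
    // circuit
    for (int i = 0; i < n; ++i) S[i] = off[i] ? 0.0 : 1.0 / (1.0 + std::exp(-(V[i] + theta[i])));
    for (int i = 0; i < n; ++i) dV[i] = off[i] ? 0.0 : tonic[i];
    for (size_t e = 0; e < w_val.size(); ++e) dV[w_dst[e]] += w_val[e] * S[w_src[e]];
    for (size_t e = 0; e < g_val.size(); ++e) {
      const int j = g_src[e], i = g_dst[e];
      if (!off[j] && !off[i]) dV[i] += g_val[e] * (V[j] - V[i]);
    }
    for (int i = 0; i < n; ++i)
      if (!off[i]) V[i] += dt_neural * invtau[i] * (-V[i] + dV[i]);
    for (int i = 0; i < n; ++i) S[i] = off[i] ? 0.0 : 1.0 / (1.0 + std::exp(-(V[i] + theta[i])));

    // muscles
    for (int m = 0; m < n_mus; ++m) I[m] = 0.0;
    for (int i = 0; i < n; ++i) {
      if (S[i] == 0.0) continue;
      for (int m = 0; m < n_mus; ++m) I[m] += Mdrv(i, m) * S[i];
    }
    for (int m = 0; m < n_mus; ++m) A[m] += dt_neural / tauM * (I[m] - A[m]);

    // element drives
    std::fill(driveD.begin(), driveD.end(), 0.0);
    std::fill(driveV.begin(), driveV.end(), 0.0);
    for (size_t t = 0; t < mD_w.size(); ++t) driveD[mD_e[t]] += mD_w[t] * A[mD_m[t]];
    for (size_t t = 0; t < mV_w.size(); ++t) driveV[mV_e[t]] += mV_w[t] * A[n_side + mV_m[t]];

    // body substeps
    for (int s = 0; s < substeps; ++s)
      if (!body_step_core(st, g, driveD.data(), driveV.data(), dt_body, true))
        stop("body integration failed at t = %g s (degenerate element or "
             "singular solve)", step * dt_neural);

    if (step % record_stride == 0) {
      for (int i = 0; i < n; ++i) Srec(rec, i) = S[i];
      for (int m = 0; m < n_mus; ++m) Arec(rec, m) = A[m];
      for (int i = 0; i < g.n_rod; ++i) { X(rec, i) = st.x[i]; Y(rec, i) = st.y[i]; }
      trec[rec] = step * dt_neural;
      ++rec;
    }
  }
  return List::create(_["time"] = trec, _["S"] = Srec, _["A"] = Arec,
                      _["x"] = X, _["y"] = Y);
}
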