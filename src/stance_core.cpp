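// Core numerics for the two-link 3-D inverted-pendulum stance model:
//  - exact Kane / Newton-Euler inverse and forward dynamics (no finite
//    differences anywhere),
//  - centre-of-pressure from the ground-reaction wrench at the ankle,
//  - tactor-display device logic (tilt sensing, nearest-neighbour column,
//    stepwise row coding, first-order torque lag),
//  - the fixed-step RK4 closed-loop integrator with a delayed-state buffer.
//
// Conventions (shared with the R layer):
//  * internal frame: x forward, y LEFT, z up (right-handed); the user-facing
//    frame has y to the RIGHT, so internal y quantities are negated at the
//    interface.
//  * generalized coordinates q = (ankle_S, hip_S, ankle_C, hip_C) in rad;
//    S = sagittal pitch (positive forward), C = coronal roll (positive
//    rightward lean, i.e. rotation about internal +x).
//  * link orientations: legs R1 = Ry(aS) * Rx(aC); torso R2 = R1 * Ry(hS) * Rx(hC).
//  * generalized torques are conjugate to q: positive sagittal torque
//    accelerates the joint angle forward.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
};
static inline Vec3 v3(double x, double y, double z) { return {x, y, z}; }
static inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
static inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}

struct Mat3 {
  double m[3][3];
  Vec3 col(int j) const { return {m[0][j], m[1][j], m[2][j]}; }
  Vec3 mul(Vec3 v) const {
    return {m[0][0] * v.x + m[0][1] * v.y + m[0][2] * v.z,
            m[1][0] * v.x + m[1][1] * v.y + m[1][2] * v.z,
            m[2][0] * v.x + m[2][1] * v.y + m[2][2] * v.z};
  }
};
static Mat3 matmul(const Mat3 &a, const Mat3 &b) {
  Mat3 c;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      c.m[i][j] = a.m[i][0] * b.m[0][j] + a.m[i][1] * b.m[1][j] + a.m[i][2] * b.m[2][j];
  return c;
}
static Mat3 rotY(double t) {
  double c = std::cos(t), s = std::sin(t);
  return {{{c, 0, s}, {0, 1, 0}, {-s, 0, c}}};
}
static Mat3 rotX(double t) {
  double c = std::cos(t), s = std::sin(t);
  return {{{1, 0, 0}, {0, c, -s}, {0, s, c}}};
}
// world-frame I * v with I principal-diagonal in the body frame: R diag(I) R^T v
static inline Vec3 inertia_mul(const Mat3 &R, Vec3 Idiag, Vec3 v) {
  Vec3 vb = {R.m[0][0] * v.x + R.m[1][0] * v.y + R.m[2][0] * v.z,
             R.m[0][1] * v.x + R.m[1][1] * v.y + R.m[2][1] * v.z,
             R.m[0][2] * v.x + R.m[1][2] * v.y + R.m[2][2] * v.z};
  vb = {Idiag.x * vb.x, Idiag.y * vb.y, Idiag.z * vb.z};
  return R.mul(vb);
}

struct Params {
  double m1, m2, L1, d1, d2, g;
  Vec3 I1, I2; // principal inertias about COM, body frame (x,y,z)
};
static Params unpack(const NumericVector &p) {
  Params P;
  P.m1 = p[0]; P.m2 = p[1]; P.L1 = p[2]; P.d1 = p[3]; P.d2 = p[4];
  P.I1 = v3(p[5], p[6], p[7]);
  P.I2 = v3(p[8], p[9], p[10]);
  P.g = p[11];
  return P;
}

// Inverse dynamics: generalized torques required to realise qdd at (q, qd)
// with ankle-point acceleration aA (internal frame) and gravity g.
// Also returns (optionally) the reaction wrench at the ankle.
static void inverse_dyn(const double q[4], const double qd[4], const double qdd[4],
                        Vec3 aA, const Params &P, double useg,
                        double Q[4], Vec3 *Fr, Vec3 *Mr) {
  const Vec3 ex = v3(1, 0, 0), ey = v3(0, 1, 0), ez = v3(0, 0, 1);
  double aS = q[0], hS = q[1], aC = q[2], hC = q[3];
  double daS = qd[0], dhS = qd[1], daC = qd[2], dhC = qd[3];
  double ddaS = qdd[0], ddhS = qdd[1], ddaC = qdd[2], ddhC = qdd[3];

  Mat3 Ry1 = rotY(aS), Rx1 = rotX(aC);
  Mat3 R1 = matmul(Ry1, Rx1);
  Mat3 Ry2 = rotY(hS), Rx2 = rotX(hC);
  Mat3 R2 = matmul(R1, matmul(Ry2, Rx2));

  // joint axes
  Vec3 u1 = ey;                       // ankle pitch
  Vec3 u2 = Ry1.mul(ex);              // ankle roll
  Vec3 u3 = R1.mul(ey);               // hip pitch
  Vec3 u4 = matmul(R1, Ry2).mul(ex);  // hip roll

  Vec3 w1 = daS * u1 + daC * u2;
  Vec3 w2 = w1 + dhS * u3 + dhC * u4;

  // axis rates (each axis rotates with the frames upstream of it)
  Vec3 u2d = cross(daS * u1, u2);
  Vec3 u3d = cross(w1, u3);
  Vec3 u4d = cross(w1 + dhS * u3, u4);

  Vec3 w1d = ddaS * u1 + ddaC * u2 + daC * u2d;
  Vec3 w2d = w1d + ddhS * u3 + ddhC * u4 + dhS * u3d + dhC * u4d;

  Vec3 r1 = P.d1 * R1.col(2); // ankle -> legs COM
  Vec3 rL = P.L1 * R1.col(2); // ankle -> hip
  Vec3 r2 = P.d2 * R2.col(2); // hip -> torso COM

  Vec3 a1 = aA + cross(w1d, r1) + cross(w1, cross(w1, r1));
  Vec3 a2 = aA + cross(w1d, rL) + cross(w1, cross(w1, rL)) + cross(w2d, r2) +
            cross(w2, cross(w2, r2));

  Vec3 gvec = v3(0, 0, useg * P.g);
  Vec3 F1 = P.m1 * (a1 + gvec);
  Vec3 F2 = P.m2 * (a2 + gvec);
  Vec3 T1 = inertia_mul(R1, P.I1, w1d) + cross(w1, inertia_mul(R1, P.I1, w1));
  Vec3 T2 = inertia_mul(R2, P.I2, w2d) + cross(w2, inertia_mul(R2, P.I2, w2));

  // partial angular velocities / partial COM velocities, k = (aS, hS, aC, hC)
  Vec3 pw1[4] = {u1, v3(0, 0, 0), u2, v3(0, 0, 0)};
  Vec3 pw2[4] = {u1, u3, u2, u4};
  for (int k = 0; k < 4; ++k) {
    Vec3 pv1 = cross(pw1[k], r1);
    Vec3 pv2 = cross(pw1[k], rL) + cross(pw2[k], r2);
    Q[k] = dot(pv1, F1) + dot(pw1[k], T1) + dot(pv2, F2) + dot(pw2[k], T2);
  }
  if (Fr) *Fr = F1 + F2;
  if (Mr) *Mr = T1 + T2 + cross(r1, F1) + cross(rL + r2, F2);
}

// 4x4 linear solve, partial pivoting
static void solve4(double A[4][4], double b[4], double x[4]) {
  int piv[4] = {0, 1, 2, 3};
  for (int c = 0; c < 4; ++c) {
    int best = c;
    for (int r = c + 1; r < 4; ++r)
      if (std::fabs(A[piv[r]][c]) > std::fabs(A[piv[best]][c])) best = r;
    std::swap(piv[c], piv[best]);
    double p = A[piv[c]][c];
    if (p == 0.0) stop("singular mass matrix");
    for (int r = c + 1; r < 4; ++r) {
      double f = A[piv[r]][c] / p;
      for (int cc = c; cc < 4; ++cc) A[piv[r]][cc] -= f * A[piv[c]][cc];
      b[piv[r]] -= f * b[piv[c]];
    }
  }
  for (int c = 3; c >= 0; --c) {
    double s = b[piv[c]];
    for (int cc = c + 1; cc < 4; ++cc) s -= A[piv[c]][cc] * x[cc];
    x[c] = s / A[piv[c]][c];
  }
}

// Forward dynamics: qdd from applied generalized torques tau, platform accel.
static void forward_dyn(const double q[4], const double qd[4], const double tau[4],
                        Vec3 aA, const Params &P, double qdd[4]) {
  double M[4][4], bias[4], col[4], z4[4] = {0, 0, 0, 0}, e[4];
  // mass matrix columns: ID with unit qdd, no velocity/gravity/base terms
  for (int j = 0; j < 4; ++j) {
    for (int k = 0; k < 4; ++k) e[k] = (k == j) ? 1.0 : 0.0;
    inverse_dyn(q, z4, e, v3(0, 0, 0), P, 0.0, col, nullptr, nullptr);
    for (int k = 0; k < 4; ++k) M[k][j] = col[k];
  }
  inverse_dyn(q, qd, z4, aA, P, 1.0, bias, nullptr, nullptr);
  double rhs[4];
  for (int k = 0; k < 4; ++k) rhs[k] = tau[k] - bias[k];
  solve4(M, rhs, qdd);
}

// [[Rcpp::export(name = ".cpp_inverse_dynamics")]]
NumericVector cpp_inverse_dynamics(NumericVector state, NumericVector qdd,
                                   NumericVector platform_accel, NumericVector params) {
  Params P = unpack(params);
  double q[4], qd[4], qa[4], Q[4];
  for (int i = 0; i < 4; ++i) { q[i] = state[i]; qd[i] = state[4 + i]; qa[i] = qdd[i]; }
  Vec3 aA = v3(platform_accel[0], platform_accel[1], 0);
  inverse_dyn(q, qd, qa, aA, P, 1.0, Q, nullptr, nullptr);
  return NumericVector::create(Q[0], Q[1], Q[2], Q[3]);
}

// [[Rcpp::export(name = ".cpp_forward_dynamics")]]
NumericVector cpp_forward_dynamics(NumericVector state, NumericVector tau,
                                   NumericVector platform_accel, NumericVector params) {
  Params P = unpack(params);
  double q[4], qd[4], tq[4], qdd[4];
  for (int i = 0; i < 4; ++i) { q[i] = state[i]; qd[i] = state[4 + i]; tq[i] = tau[i]; }
  Vec3 aA = v3(platform_accel[0], platform_accel[1], 0);
  forward_dyn(q, qd, tq, aA, P, qdd);
  return NumericVector::create(qdd[0], qdd[1], qdd[2], qdd[3]);
}

// [[Rcpp::export(name = ".cpp_mass_matrix")]]
NumericMatrix cpp_mass_matrix(NumericVector state, NumericVector params) {
  Params P = unpack(params);
  double q[4], z4[4] = {0, 0, 0, 0}, e[4], col[4];
  for (int i = 0; i < 4; ++i) q[i] = state[i];
  NumericMatrix M(4, 4);
  for (int j = 0; j < 4; ++j) {
    for (int k = 0; k < 4; ++k) e[k] = (k == j) ? 1.0 : 0.0;
    inverse_dyn(q, z4, e, v3(0, 0, 0), P, 0.0, col, nullptr, nullptr);
    for (int k = 0; k < 4; ++k) M(k, j) = col[k];
  }
  return M;
}

// COP (internal frame, relative to the ankle point) and vertical reaction.
// Solves the forward dynamics at the instant, then evaluates the reaction
// wrench at the ankle from the resulting accelerations.
// [[Rcpp::export(name = ".cpp_cop")]]
NumericVector cpp_cop(NumericVector state, NumericVector tau,
                      NumericVector platform_accel, NumericVector params) {
  Params P = unpack(params);
  double q[4], qd[4], tq[4], qdd[4], Q[4];
  for (int i = 0; i < 4; ++i) { q[i] = state[i]; qd[i] = state[4 + i]; tq[i] = tau[i]; }
  Vec3 aA = v3(platform_accel[0], platform_accel[1], 0);
  forward_dyn(q, qd, tq, aA, P, qdd);
  Vec3 Fr, Mr;
  inverse_dyn(q, qd, qdd, aA, P, 1.0, Q, &Fr, &Mr);
  double Fz = Fr.z;
  double copx = (Fz > 0) ? -Mr.y / Fz : NA_REAL;
  double copy = (Fz > 0) ? Mr.x / Fz : NA_REAL;
  return NumericVector::create(copx, copy, Fz);
}

// ---------------------------------------------------------------------------
// Device logic
// ---------------------------------------------------------------------------

// cos/sin of an azimuth given in degrees, exact at multiples of 90 so that
// symmetric (single-plane) motions stay single-plane to machine precision.
static void cos_sin_deg(double az, double *c, double *s) {
  double a = az - 360.0 * std::floor(az / 360.0);
  if (a >= 360.0) a = 0.0;
  if (a == 0.0)      { *c = 1;  *s = 0;  return; }
  if (a == 90.0)     { *c = 0;  *s = 1;  return; }
  if (a == 180.0)    { *c = -1; *s = 0;  return; }
  if (a == 270.0)    { *c = 0;  *s = -1; return; }
  *c = std::cos(a * M_PI / 180.0);
  *s = std::sin(a * M_PI / 180.0);
}

// torso tilt (deg): phi, phidot, azimuth (deg clockwise from navel),
// magnitude m = phi + 0.5 * phidot
static void tilt_from_state(const double q[4], const double qd[4], double out[4]) {
  const double r2d = 180.0 / M_PI;
  double pS = (q[0] + q[1]) * r2d, pC = (q[2] + q[3]) * r2d;
  double dS = (qd[0] + qd[1]) * r2d, dC = (qd[2] + qd[3]) * r2d;
  double phi = std::sqrt(pS * pS + pC * pC);
  double phidot = (phi > 0) ? (pS * dS + pC * dC) / phi : 0.0;
  double az = 0.0;
  if (phi > 0) {
    az = std::atan2(pC, pS) * r2d;
    if (az < 0) az += 360.0;
  }
  out[0] = phi; out[1] = phidot; out[2] = az; out[3] = phi + 0.5 * phidot;
}

static double circ_dist(double a, double b) {
  double d = a - b;
  d -= 360.0 * std::floor(d / 360.0); // in [0, 360)
  return (d > 180.0) ? 360.0 - d : d;
}

// nearest-neighbour column + stepwise row; ties go to the lower azimuth.
// cols sorted ascending by the caller. Returns row in out[0] (0 = off) and
// the displayed column azimuth in out[1] (NA when off).
static void select_act(double m, double az, const std::vector<double> &cols,
                       int nrows, double deadzone, const std::vector<double> &thr,
                       double out[2]) {
  out[0] = 0; out[1] = NA_REAL;
  if (cols.empty() || m < deadzone) return;
  int r = 0;
  for (int i = 0; i < (int)thr.size() && i < nrows; ++i)
    if (m >= thr[i]) r = i + 1;
  if (r == 0) return;
  int best = 0;
  double bd = circ_dist(az, cols[0]);
  for (int i = 1; i < (int)cols.size(); ++i) {
    double d = circ_dist(az, cols[i]);
    if (d < bd - 1e-12) { bd = d; best = i; } // tie -> keep lower azimuth
  }
  out[0] = r; out[1] = cols[best];
}

// ---------------------------------------------------------------------------
// Closed-loop simulation
// ---------------------------------------------------------------------------

// Controller torque from a (plane-wise) delayed state vector.
static void pc_torque(const double st[8], const NumericMatrix &KS,
                      const NumericMatrix &KC, double tpc[4]) {
  // plane state x = (alpha_a, alpha_h, dalpha_a, dalpha_h)
  double xS[4] = {st[0], st[1], st[4], st[5]};
  double xC[4] = {st[2], st[3], st[6], st[7]};
  tpc[0] = -(KS(0, 0) * xS[0] + KS(0, 1) * xS[1] + KS(0, 2) * xS[2] + KS(0, 3) * xS[3]);
  tpc[1] = -(KS(1, 0) * xS[0] + KS(1, 1) * xS[1] + KS(1, 2) * xS[2] + KS(1, 3) * xS[3]);
  tpc[2] = -(KC(0, 0) * xC[0] + KC(0, 1) * xC[1] + KC(0, 2) * xC[2] + KC(0, 3) * xC[3]);
  tpc[3] = -(KC(1, 0) * xC[0] + KC(1, 1) * xC[1] + KC(1, 2) * xC[2] + KC(1, 3) * xC[3]);
}

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(NumericVector state0, NumericVector params, double dt, int nsteps,
                  NumericMatrix accel_grid,  // (nsteps+1) x 2, internal frame
                  NumericMatrix accel_half,  // nsteps x 2, at t + dt/2
                  NumericMatrix KS, NumericMatrix KC, int td_steps,
                  bool fb_on, double tauF,
                  NumericMatrix kS, NumericMatrix kC, // 3 x 2 (rows r, cols ankle/hip)
                  NumericVector columns, int nrows, double deadzone,
                  NumericVector thresholds, double fall_limit,
                  int cop_stride = 1,
                  Nullable<NumericMatrix> ext_torque = R_NilValue) {
  // optional exogenous joint-torque injection ((n+1) x 4, generalized
  // convention), added to the applied torques at every stage; used for
  // system-identification experiments
  NumericMatrix ext;
  bool has_ext = ext_torque.isNotNull();
  if (has_ext) ext = NumericMatrix(ext_torque);
  Params P = unpack(params);
  int n = nsteps;
  std::vector<double> cols(columns.begin(), columns.end());
  std::vector<double> thr(thresholds.begin(), thresholds.end());

  // history of states on the grid (row i = state at t_i)
  NumericMatrix hist(n + 1, 8);
  for (int j = 0; j < 8; ++j) hist(0, j) = state0[j];

  NumericMatrix TPC(n + 1, 4), TF(n + 1, 4), COP(n + 1, 2);
  NumericVector rowv(n + 1), colv(n + 1), tiltphi(n + 1), tiltaz(n + 1);
  // device lag state, DEVICE sign convention (positive = corrective)
  double tfdev[4] = {0, 0, 0, 0};
  int fell = -1;

  double st[8];
  for (int j = 0; j < 8; ++j) st[j] = state0[j];

  for (int i = 0; i <= n; ++i) {
    // delayed states for the controller (clamped: pre-history = initial state)
    double del0[8], del1[8];
    int i0 = i - td_steps, i1 = i + 1 - td_steps;
    if (i0 < 0) i0 = 0;
    if (i1 < 0) i1 = 0;
    if (i1 > n) i1 = n; // only reachable at i = n with td = 0 (no step taken)
    for (int j = 0; j < 8; ++j) { del0[j] = hist(i0, j); del1[j] = hist(i1, j); }

    double tpc0[4], tpc1[4];
    pc_torque(del0, KS, KC, tpc0);

    // device update from the current state
    double q[4] = {st[0], st[1], st[2], st[3]};
    double qd[4] = {st[4], st[5], st[6], st[7]};
    double tl[4];
    tilt_from_state(q, qd, tl);
    double act[2] = {0, NA_REAL};
    double Kdev[4] = {0, 0, 0, 0}; // targets: S ankle, S hip, C ankle, C hip
    if (fb_on) {
      select_act(tl[3], tl[2], cols, nrows, deadzone, thr, act);
      int r = (int)act[0];
      if (r > 0) {
        double c, s;
        cos_sin_deg(act[1], &c, &s);
        Kdev[0] = kS(r - 1, 0) * c;
        Kdev[1] = kS(r - 1, 1) * c;
        Kdev[2] = kC(r - 1, 0) * s;
        Kdev[3] = kC(r - 1, 1) * s;
      }
    }
    tiltphi[i] = tl[0]; tiltaz[i] = tl[2];
    rowv[i] = act[0]; colv[i] = act[1];

    // record channels at t_i (applied biofeedback torque = -device torque,
    // plus any exogenous injection)
    double tfa0[4];
    for (int j = 0; j < 4; ++j) {
      tfa0[j] = -tfdev[j] + (has_ext ? ext(i, j) : 0.0);
      TPC(i, j) = tpc0[j];
      TF(i, j) = tfa0[j];
    }
    if (i % cop_stride == 0) {
      double tau[4];
      for (int j = 0; j < 4; ++j) tau[j] = tpc0[j] + tfa0[j];
      double qdd[4], Q[4];
      Vec3 aA = v3(accel_grid(i, 0), accel_grid(i, 1), 0);
      forward_dyn(q, qd, tau, aA, P, qdd);
      Vec3 Fr, Mr;
      inverse_dyn(q, qd, qdd, aA, P, 1.0, Q, &Fr, &Mr);
      COP(i, 0) = -Mr.y / Fr.z;
      COP(i, 1) = Mr.x / Fr.z;
    } else {
      COP(i, 0) = NA_REAL;
      COP(i, 1) = NA_REAL;
    }

    if (i == n) break;

    // lag factors across the step (exact exponential stepping)
    double eh = std::exp(-0.5 * dt / tauF), ef = eh * eh;
    double tf_h[4], tf_f[4]; // device torque at t + dt/2, t + dt
    for (int j = 0; j < 4; ++j) {
      tf_h[j] = Kdev[j] + (tfdev[j] - Kdev[j]) * eh;
      tf_f[j] = Kdev[j] + (tfdev[j] - Kdev[j]) * ef;
    }

    bool td0 = (td_steps == 0);
    if (!td0) pc_torque(del1, KS, KC, tpc1);

    // stage torques (controller part held per stage; midpoint = average)
    auto stage_tau = [&](int stage, const double stq[8], double tau[4]) {
      double tpc[4];
      if (td0) {
        pc_torque(stq, KS, KC, tpc);
      } else if (stage == 0) {
        for (int j = 0; j < 4; ++j) tpc[j] = tpc0[j];
      } else if (stage == 3) {
        for (int j = 0; j < 4; ++j) tpc[j] = tpc1[j];
      } else {
        for (int j = 0; j < 4; ++j) tpc[j] = 0.5 * (tpc0[j] + tpc1[j]);
      }
      const double *tf = (stage == 0) ? tfdev : (stage == 3 ? tf_f : tf_h);
      for (int j = 0; j < 4; ++j) tau[j] = tpc[j] - tf[j];
      if (has_ext) {
        double w1 = (stage == 0) ? 1.0 : (stage == 3 ? 0.0 : 0.5);
        for (int j = 0; j < 4; ++j)
          tau[j] += w1 * ext(i, j) + (1.0 - w1) * ext(i + 1, j);
      }
    };

    auto deriv = [&](const double x[8], int stage, Vec3 aA, double dx[8]) {
      double tau[4], qq[4], qqd[4], qdd[4];
      for (int j = 0; j < 4; ++j) { qq[j] = x[j]; qqd[j] = x[4 + j]; }
      stage_tau(stage, x, tau);
      forward_dyn(qq, qqd, tau, aA, P, qdd);
      for (int j = 0; j < 4; ++j) { dx[j] = qqd[j]; dx[4 + j] = qdd[j]; }
    };

    // the platform acceleration is piecewise constant with phase switches
    // on the grid, so the half-step sample is the exact in-step value for
    // every stage (end-point samples would straddle a switch)
    Vec3 ah = v3(accel_half(i, 0), accel_half(i, 1), 0);
    double k1[8], k2[8], k3[8], k4[8], xs[8];
    deriv(st, 0, ah, k1);
    for (int j = 0; j < 8; ++j) xs[j] = st[j] + 0.5 * dt * k1[j];
    deriv(xs, 1, ah, k2);
    for (int j = 0; j < 8; ++j) xs[j] = st[j] + 0.5 * dt * k2[j];
    deriv(xs, 2, ah, k3);
    for (int j = 0; j < 8; ++j) xs[j] = st[j] + dt * k3[j];
    deriv(xs, 3, ah, k4);
    for (int j = 0; j < 8; ++j)
      st[j] += dt / 6.0 * (k1[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);

    for (int j = 0; j < 4; ++j) tfdev[j] = tf_f[j];
    for (int j = 0; j < 8; ++j) hist(i + 1, j) = st[j];

    if (std::fabs(st[0]) > fall_limit || std::fabs(st[1]) > fall_limit ||
        std::fabs(st[2]) > fall_limit || std::fabs(st[3]) > fall_limit ||
        !std::isfinite(st[0]) || !std::isfinite(st[1]) ||
        !std::isfinite(st[2]) || !std::isfinite(st[3])) {
      fell = i + 1;
      break;
    }
  }

  return List::create(_["states"] = hist, _["tpc"] = TPC, _["tf"] = TF,
                      _["cop"] = COP, _["row"] = rowv, _["column"] = colv,
                      _["tilt_phi"] = tiltphi, _["tilt_az"] = tiltaz,
                      _["fell_at"] = fell);
}

// [[Rcpp::export(name = ".cpp_sense_tilt")]]
NumericVector cpp_sense_tilt(NumericVector state) {
  double q[4], qd[4], out[4];
  for (int i = 0; i < 4; ++i) { q[i] = state[i]; qd[i] = state[4 + i]; }
  tilt_from_state(q, qd, out);
  return NumericVector::create(_["phi"] = out[0], _["phidot"] = out[1],
                               _["azimuth"] = out[2], _["magnitude"] = out[3]);
}

// [[Rcpp::export(name = ".cpp_select_activation")]]
NumericVector cpp_select_activation(double magnitude, double azimuth,
                                    NumericVector columns, int nrows,
                                    double deadzone, NumericVector thresholds) {
  std::vector<double> cols(columns.begin(), columns.end());
  std::vector<double> thr(thresholds.begin(), thresholds.end());
  double out[2];
  select_act(magnitude, azimuth, cols, nrows, deadzone, thr, out);
  return NumericVector::create(_["row"] = out[0], _["column"] = out[1]);
}

// [[Rcpp::export(name = ".cpp_cos_sin_deg")]]
NumericVector cpp_cos_sin_deg(double azimuth) {
  double c, s;
  cos_sin_deg(azimuth, &c, &s);
  return NumericVector::create(c, s);
}
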