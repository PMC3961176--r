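// Fixed-step classical Runge-Kutta (RK4) cores for the three-node motif
// models and the two-variable CREB1/CREB2 model.  The integrator is the
// reference solution path: dt defaults to 0.05 min (3 s) at the R level and
// the stimulus is evaluated at the sub-stage times t, t+dt/2, t+dt so that
// pulse edges aligned to the grid are handled without ambiguity.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---- stimulus protocol -----------------------------------------------------
// Encoded as c(baseline, amplitude, onset, pulse_duration, n_pulses, gap)
// where gap is the interval from pulse offset to the next onset.  A pulse is
// active on the half-open window [start, start + duration).
struct Proto {
  double base, amp, onset, dur, gap;
  int n;
};

static inline Proto unpack_proto(const NumericVector& p) {
  Proto pr;
  pr.base  = p[0];
  pr.amp   = p[1];
  pr.onset = p[2];
  pr.dur   = p[3];
  pr.n     = (int)p[4];
  pr.gap   = p[5];
  return pr;
}

static inline double proto_val(const Proto& p, double t) {
  if (p.n <= 0 || p.dur <= 0.0) return p.base;
  double rel = t - p.onset;
  if (rel < 0.0) return p.base;
  double period = p.dur + p.gap;
  if (period <= 0.0) return p.base;
  int i = (int)std::floor(rel / period);
  if (i >= p.n) return p.base;
  return (rel - i * period < p.dur) ? p.amp : p.base;
}

// [[Rcpp::export(name = ".protocol_value_cpp")]]
NumericVector protocol_value_cpp(NumericVector proto, NumericVector t) {
  Proto p = unpack_proto(proto);
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = proto_val(p, t[i]);
  return out;
}

// ---- three-node motif models ----------------------------------------------
// Canonical parameter order (fixed, shared with the R level):
//  0 k_sA  1 k_basal_A  2 k_dA  3 K_A
//  4 k_sB  5 k_basal_B  6 k_dB  7 K_B
//  8 k_basal_T  9 k_ST  10 K_TA  11 K_TB  12 k_dT  13 K_T
// Regulated-rate overrides replace k_dA and/or k_dB by hyperbolic forms in a
// regulator X: decreasing k*K/(K+X), increasing k*X/(K+X).
struct TN {
  double ksA, kbA, kdA, KA, ksB, kbB, kdB, KB, kbT, kST, KTA, KTB, kdT, KT;
  int variant;              // 0 = M (product of saturable effects), 1 = A (sum)
  int ovA_code, ovA_reg;    // code: 0 none, 1 decreasing, 2 increasing
  double ovA_k, ovA_K;      // reg: 0 = A, 1 = B, 2 = T
  int ovB_code, ovB_reg;
  double ovB_k, ovB_K;
};

static inline double reg_rate(int code, double k, double K, double X) {
  return (code == 1) ? k * K / (K + X) : k * X / (K + X);
}

static inline void tn_rhs(const TN& m, const double* y,
                          double SA, double SB, double* dy) {
  double A = y[0], B = y[1], T = y[2];
  double kdA = m.ovA_code
    ? reg_rate(m.ovA_code, m.ovA_k, m.ovA_K,
               m.ovA_reg == 0 ? A : (m.ovA_reg == 1 ? B : T))
    : m.kdA;
  double kdB = m.ovB_code
    ? reg_rate(m.ovB_code, m.ovB_k, m.ovB_K,
               m.ovB_reg == 0 ? A : (m.ovB_reg == 1 ? B : T))
    : m.kdB;
  dy[0] = m.kbA + m.ksA * SA - kdA * A / (m.KA + A);
  dy[1] = m.kbB + m.ksB * SB - kdB * B / (m.KB + B);
  double fA = A / (m.KTA + A);
  double fB = B / (m.KTB + B);
  double act = (m.variant == 0) ? fA * fB : fA + fB;
  dy[2] = m.kbT + m.kST * act - m.kdT * T / (m.KT + T);
}

static TN unpack_tn(const NumericVector& params, int variant,
                    const IntegerVector& ovA, const NumericVector& ovAk,
                    const IntegerVector& ovB, const NumericVector& ovBk) {
  TN m;
  m.ksA = params[0];  m.kbA = params[1];  m.kdA = params[2];  m.KA = params[3];
  m.ksB = params[4];  m.kbB = params[5];  m.kdB = params[6];  m.KB = params[7];
  m.kbT = params[8];  m.kST = params[9];  m.KTA = params[10]; m.KTB = params[11];
  m.kdT = params[12]; m.KT  = params[13];
  m.variant  = variant;
  m.ovA_code = ovA[0]; m.ovA_reg = ovA[1];
  m.ovA_k = ovAk[0];   m.ovA_K = ovAk[1];
  m.ovB_code = ovB[0]; m.ovB_reg = ovB[1];
  m.ovB_k = ovBk[0];   m.ovB_K = ovBk[1];
  return m;
}

static const char* tn_names[3] = {"A", "B", "T"};

static inline void check_finite(const double* y, int dim, double t,
                                const char** names) {
  for (int j = 0; j < dim; ++j) {
    if (!R_finite(y[j]))
      stop("non-finite value of state variable '%s' at t = %g min",
           names[j], t);
  }
}

// [[Rcpp::export(name = ".sim_three_node_cpp")]]
List sim_three_node_cpp(NumericVector params, int variant,
                        IntegerVector ovA, NumericVector ovAk,
                        IntegerVector ovB, NumericVector ovBk,
                        NumericVector proto, double b_delay,
                        NumericVector y0, double t_end, double dt,
                        bool store) {
  TN m = unpack_tn(params, variant, ovA, ovAk, ovB, ovBk);
  Proto p = unpack_proto(proto);
  int nstep = (int)std::lround(t_end / dt);
  if (nstep < 1) stop("t_end must allow at least one step of size dt");

  double y[3] = {y0[0], y0[1], y0[2]};
  double k1[3], k2[3], k3[3], k4[3], ytmp[3];

  NumericMatrix states;
  NumericVector times;
  if (store) {
    states = NumericMatrix(nstep + 1, 3);
    times = NumericVector(nstep + 1);
  }
  double peak = y[2], peak_time = 0.0;
  int peak_index = 0;
  if (store) {
    for (int j = 0; j < 3; ++j) states(0, j) = y[j];
    times[0] = 0.0;
  }

  for (int i = 0; i < nstep; ++i) {
    double t = i * dt;
    double th = t + 0.5 * dt, tf = t + dt;
    double SA0 = proto_val(p, t),  SB0 = proto_val(p, t - b_delay);
    double SAh = proto_val(p, th), SBh = proto_val(p, th - b_delay);
    double SAf = proto_val(p, tf), SBf = proto_val(p, tf - b_delay);

    tn_rhs(m, y, SA0, SB0, k1);
    for (int j = 0; j < 3; ++j) ytmp[j] = y[j] + 0.5 * dt * k1[j];
    tn_rhs(m, ytmp, SAh, SBh, k2);
    for (int j = 0; j < 3; ++j) ytmp[j] = y[j] + 0.5 * dt * k2[j];
    tn_rhs(m, ytmp, SAh, SBh, k3);
    for (int j = 0; j < 3; ++j) ytmp[j] = y[j] + dt * k3[j];
    tn_rhs(m, ytmp, SAf, SBf, k4);
    for (int j = 0; j < 3; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    check_finite(y, 3, tf, tn_names);

    if (store) {
      for (int j = 0; j < 3; ++j) states(i + 1, j) = y[j];
      times[i + 1] = tf;
    }
    if (y[2] > peak) { peak = y[2]; peak_time = tf; peak_index = i + 1; }
  }

  double SAe = proto_val(p, t_end), SBe = proto_val(p, t_end - b_delay);
  tn_rhs(m, y, SAe, SBe, k1);
  NumericVector fin(3), dfin(3);
  for (int j = 0; j < 3; ++j) { fin[j] = y[j]; dfin[j] = k1[j]; }

  List out = List::create(
    _["peak"] = peak, _["peak_time"] = peak_time,
    _["peak_index"] = peak_index, _["n_samples"] = nstep + 1,
    _["final_state"] = fin, _["final_deriv"] = dfin);
  if (store) {
    out["times"] = times;
    out["states"] = states;
  }
  return out;
}

// Relax toward the basal fixed point under a constant stimulus; stops when
// the max absolute derivative falls below tol (per minute).
// [[Rcpp::export(name = ".settle_three_node_cpp")]]
List settle_three_node_cpp(NumericVector params, int variant,
                           IntegerVector ovA, NumericVector ovAk,
                           IntegerVector ovB, NumericVector ovBk,
                           double S, NumericVector y0,
                           double dt, double tol, double t_max) {
  TN m = unpack_tn(params, variant, ovA, ovAk, ovB, ovBk);
  int nstep = (int)std::lround(t_max / dt);
  double y[3] = {y0[0], y0[1], y0[2]};
  double k1[3], k2[3], k3[3], k4[3], ytmp[3];
  double res = R_PosInf;
  double t = 0.0;
  bool conv = false;
  for (int i = 0; i < nstep; ++i) {
    tn_rhs(m, y, S, S, k1);
    res = std::max(std::fabs(k1[0]), std::max(std::fabs(k1[1]), std::fabs(k1[2])));
    if (res < tol) { conv = true; break; }
    for (int j = 0; j < 3; ++j) ytmp[j] = y[j] + 0.5 * dt * k1[j];
    tn_rhs(m, ytmp, S, S, k2);
    for (int j = 0; j < 3; ++j) ytmp[j] = y[j] + 0.5 * dt * k2[j];
    tn_rhs(m, ytmp, S, S, k3);
    for (int j = 0; j < 3; ++j) ytmp[j] = y[j] + dt * k3[j];
    tn_rhs(m, ytmp, S, S, k4);
    for (int j = 0; j < 3; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    t += dt;
    check_finite(y, 3, t, tn_names);
  }
  return List::create(
    _["state"] = NumericVector::create(y[0], y[1], y[2]),
    _["residual"] = res, _["t"] = t, _["converged"] = conv);
}

// ---- CREB1/CREB2 model -----------------------------------------------------
// Parameter order: 0 V_x, 1 V_y, 2 K_x, 3 K_y, 4 k_dx, 5 k_dy,
//                  6 r_bas_x, 7 r_bas_y.  The protocol drives the effective
// V_x; CREB1 (x) activates and CREB2 (z) competitively represses both genes
// through a shared CRE occupancy factor.  Both factors bind as dimers, so
// the occupancy is quadratic in the protein levels (Kx, Ky are dimer-DNA
// dissociation constants in squared-concentration units); the quadratic
// self-activation is what makes the switch bistable.
struct CREB {
  double Vx, Vy, Kx, Ky, kdx, kdy, rbx, rby;
};

static inline void creb_rhs_c(const CREB& m, double Vxe,
                              const double* y, double* dy) {
  double x = y[0], z = y[1];
  double occ = (x * x / m.Kx) / (1.0 + x * x / m.Kx + z * z / m.Ky);
  dy[0] = m.rbx + Vxe * occ - m.kdx * x;
  dy[1] = m.rby + m.Vy * occ - m.kdy * z;
}

static CREB unpack_creb(const NumericVector& params) {
  CREB m;
  m.Vx = params[0]; m.Vy = params[1]; m.Kx = params[2]; m.Ky = params[3];
  m.kdx = params[4]; m.kdy = params[5]; m.rbx = params[6]; m.rby = params[7];
  return m;
}

static const char* creb_names[2] = {"CREB1", "CREB2"};

// [[Rcpp::export(name = ".sim_creb_cpp")]]
List sim_creb_cpp(NumericVector params, NumericVector proto,
                  NumericVector y0, double t_end, double dt, bool store) {
  CREB m = unpack_creb(params);
  Proto p = unpack_proto(proto);
  int nstep = (int)std::lround(t_end / dt);
  if (nstep < 1) stop("t_end must allow at least one step of size dt");
  double y[2] = {y0[0], y0[1]};
  double k1[2], k2[2], k3[2], k4[2], ytmp[2];

  NumericMatrix states;
  NumericVector times;
  if (store) {
    states = NumericMatrix(nstep + 1, 2);
    times = NumericVector(nstep + 1);
    states(0, 0) = y[0]; states(0, 1) = y[1]; times[0] = 0.0;
  }

  for (int i = 0; i < nstep; ++i) {
    double t = i * dt;
    double V0 = proto_val(p, t);
    double Vh = proto_val(p, t + 0.5 * dt);
    double Vf = proto_val(p, t + dt);
    creb_rhs_c(m, V0, y, k1);
    for (int j = 0; j < 2; ++j) ytmp[j] = y[j] + 0.5 * dt * k1[j];
    creb_rhs_c(m, Vh, ytmp, k2);
    for (int j = 0; j < 2; ++j) ytmp[j] = y[j] + 0.5 * dt * k2[j];
    creb_rhs_c(m, Vh, ytmp, k3);
    for (int j = 0; j < 2; ++j) ytmp[j] = y[j] + dt * k3[j];
    creb_rhs_c(m, Vf, ytmp, k4);
    for (int j = 0; j < 2; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    check_finite(y, 2, t + dt, creb_names);
    if (store) {
      states(i + 1, 0) = y[0]; states(i + 1, 1) = y[1];
      times[i + 1] = t + dt;
    }
  }

  creb_rhs_c(m, proto_val(p, t_end), y, k1);
  List out = List::create(
    _["final_state"] = NumericVector::create(y[0], y[1]),
    _["final_deriv"] = NumericVector::create(k1[0], k1[1]),
    _["n_samples"] = nstep + 1);
  if (store) {
    out["times"] = times;
    out["states"] = states;
  }
  return out;
}

// [[Rcpp::export(name = ".settle_creb_cpp")]]
List settle_creb_cpp(NumericVector params, double Vx_eff, NumericVector y0,
                     double dt, double tol, double t_max) {
  CREB m = unpack_creb(params);
  int nstep = (int)std::lround(t_max / dt);
  double y[2] = {y0[0], y0[1]};
  double k1[2], k2[2], k3[2], k4[2], ytmp[2];
  double res = R_PosInf, t = 0.0;
  bool conv = false;
  for (int i = 0; i < nstep; ++i) {
    creb_rhs_c(m, Vx_eff, y, k1);
    res = std::max(std::fabs(k1[0]), std::fabs(k1[1]));
    if (res < tol) { conv = true; break; }
    for (int j = 0; j < 2; ++j) ytmp[j] = y[j] + 0.5 * dt * k1[j];
    creb_rhs_c(m, Vx_eff, ytmp, k2);
    for (int j = 0; j < 2; ++j) ytmp[j] = y[j] + 0.5 * dt * k2[j];
    creb_rhs_c(m, Vx_eff, ytmp, k3);
    for (int j = 0; j < 2; ++j) ytmp[j] = y[j] + dt * k3[j];
    creb_rhs_c(m, Vx_eff, ytmp, k4);
    for (int j = 0; j < 2; ++j)
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    t += dt;
    check_finite(y, 2, t, creb_names);
  }
  return List::create(
    _["state"] = NumericVector::create(y[0], y[1]),
    _["residual"] = res, _["t"] = t, _["converged"] = conv);
}

// ---- generic RK4 for R-level right-hand sides ------------------------------
// Used by integrate_rk4() when handed an arbitrary R function; slower than
// the dedicated cores above but exact same stepping rule.
// [[Rcpp::export(name = ".rk4_generic_cpp")]]
List rk4_generic_cpp(Function rhs, NumericVector y0, double t_end, double dt) {
  int dim = y0.size();
  int nstep = (int)std::lround(t_end / dt);
  if (nstep < 1) stop("t_end must allow at least one step of size dt");
  NumericMatrix states(nstep + 1, dim);
  NumericVector times(nstep + 1);
  NumericVector y = clone(y0);
  for (int j = 0; j < dim; ++j) states(0, j) = y[j];
  times[0] = 0.0;
  for (int i = 0; i < nstep; ++i) {
    double t = i * dt;
    NumericVector k1 = rhs(t, y);
    NumericVector k2 = rhs(t + 0.5 * dt, y + 0.5 * dt * k1);
    NumericVector k3 = rhs(t + 0.5 * dt, y + 0.5 * dt * k2);
    NumericVector k4 = rhs(t + dt, y + dt * k3);
    for (int j = 0; j < dim; ++j) {
      y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (!R_finite(y[j]))
        stop("non-finite value of state variable %d at t = %g min",
             j + 1, t + dt);
      states(i + 1, j) = y[j];
    }
    times[i + 1] = t + dt;
  }
  return List::create(_["times"] = times, _["states"] = states);
}
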