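// Core fixed-step integrator for the insect-leg neuro-mechanical model.
//
// Units: time ms, voltage mV, conductance uS, capacitance nF (uS*mV = nA),
// angles deg, stiffness mN/mm^2, length mm, force mN, torque mN*mm.
//
// Muscle index order (shared everywhere): 0 protractor, 1 retractor,
// 2 levator, 3 depressor, 4 extensor, 5 flexor. Pools: fast = m, slow = m+6.
// CPG neurons: 0..5 = C1 (retractor), C2 (protractor), C3 (levator),
// C4 (depressor), C5 (extensor), C6 (flexor). Systems: 0 PR, 1 LD, 2 EF.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

// ---------------------------------------------------------------- CPG cell

struct CpgPars {
  double C, gnap, gl, Ena, El, Esyn, Edrive;
  double mhalf, mk, hhalf, hk, tau_hbar, tau_half, tau_k;
  double syn_half, syn_k;
};

static CpgPars cpg_pars_from(const NumericVector& p) {
  CpgPars q;
  q.C = p["C"]; q.gnap = p["gnap"]; q.gl = p["gl"];
  q.Ena = p["Ena"]; q.El = p["El"]; q.Esyn = p["Esyn"]; q.Edrive = p["Edrive"];
  q.mhalf = p["mhalf"]; q.mk = p["mk"]; q.hhalf = p["hhalf"]; q.hk = p["hk"];
  q.tau_hbar = p["tau_hbar"]; q.tau_half = p["tau_half"]; q.tau_k = p["tau_k"];
  q.syn_half = p["syn_half"]; q.syn_k = p["syn_k"];
  return q;
}

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline double syn_gate(const CpgPars& q, double Vpre) {
  return sigm((Vpre - q.syn_half) / q.syn_k);
}

// Derivatives of one CPG neuron given partner voltage and total drive g.
static inline void cpg_deriv(const CpgPars& q, double V, double h, double Vpartner,
                             double g_drive, double g_inh, double& dV, double& dh) {
  double minf = sigm((V - q.mhalf) / q.mk);
  double hinf = 1.0 - sigm((V - q.hhalf) / q.hk);
  double tauh = q.tau_hbar / std::cosh((V - q.tau_half) / q.tau_k);
  double I = -q.gnap * minf * h * (V - q.Ena)
             - q.gl * (V - q.El)
             - g_drive * (V - q.Edrive)
             - g_inh * syn_gate(q, Vpartner) * (V - q.Esyn);
  dV = I / q.C;
  dh = (hinf - h) / tauh;
}

// One RK4 step of a mutually inhibitory pair. g_extra_* are transient
// (sensory-pulse) drive conductances; stored drives stay untouched.
static void cpg_pair_rk4(const CpgPars& q, double* st /* Va,ha,Vb,hb */,
                         double gda, double gdb, double ginh,
                         double gxa, double gxb, double dt) {
  double k[4][4], y[4];
  const double gA = gda + gxa, gB = gdb + gxb;
  for (int stage = 0; stage < 4; ++stage) {
    double f = (stage == 0) ? 0.0 : (stage == 3 ? dt : dt / 2.0);
    for (int i = 0; i < 4; ++i)
      y[i] = st[i] + (stage == 0 ? 0.0 : f * k[stage - 1][i]);
    cpg_deriv(q, y[0], y[1], y[2], gA, ginh, k[stage][0], k[stage][1]);
    cpg_deriv(q, y[2], y[3], y[0], gB, ginh, k[stage][2], k[stage][3]);
  }
  for (int i = 0; i < 4; ++i)
    st[i] += dt / 6.0 * (k[0][i] + 2.0 * k[1][i] + 2.0 * k[2][i] + k[3][i]);
}

// [[Rcpp::export]]
NumericVector cpp_cpg_step(NumericVector pars, NumericVector state,
                           double g_drive_a, double g_drive_b, double g_inh,
                           double g_extra_a, double g_extra_b, double dt) {
  CpgPars q = cpg_pars_from(pars);
  double st[4] = { state[0], state[1], state[2], state[3] };
  cpg_pair_rk4(q, st, g_drive_a, g_drive_b, g_inh, g_extra_a, g_extra_b, dt);
  for (int i = 0; i < 4; ++i)
    if (!std::isfinite(st[i]))
      stop("CPG integration failure: non-finite state in neuron %s",
           (i < 2) ? "a" : "b");
  return NumericVector::create(st[0], st[1], st[2], st[3]);
}

// Free-run (or externally pulsed) trajectory of one half-centre pair.
// g_extra_a/b may be length 1 (constant) or length n (per step).
// [[Rcpp::export]]
NumericMatrix cpp_cpg_run(NumericVector pars, NumericVector state,
                          double g_drive_a, double g_drive_b, double g_inh,
                          NumericVector g_extra_a, NumericVector g_extra_b,
                          double dt, int n) {
  CpgPars q = cpg_pars_from(pars);
  double st[4] = { state[0], state[1], state[2], state[3] };
  NumericMatrix out(n + 1, 4);
  for (int j = 0; j < 4; ++j) out(0, j) = st[j];
  const bool va = g_extra_a.size() > 1, vb = g_extra_b.size() > 1;
  for (int i = 0; i < n; ++i) {
    double gxa = va ? g_extra_a[i] : g_extra_a[0];
    double gxb = vb ? g_extra_b[i] : g_extra_b[0];
    cpg_pair_rk4(q, st, g_drive_a, g_drive_b, g_inh, gxa, gxb, dt);
    for (int j = 0; j < 4; ++j) {
      if (!std::isfinite(st[j]))
        stop("CPG integration failure: non-finite state in neuron %s at t = %f ms",
             (j < 2) ? "a" : "b", (i + 1) * dt);
      out(i + 1, j) = st[j];
    }
  }
  colnames(out) = CharacterVector::create("V_a", "h_a", "V_b", "h_b");
  return out;
}

// ---------------------------------------------------------------- LIF MN

struct MnPars {
  double C, gl, El, Eex, Ein, thr, reset, refr;
};

static MnPars mn_pars_from(const NumericVector& p) {
  MnPars q;
  q.C = p["C"]; q.gl = p["gl"]; q.El = p["El"]; q.Eex = p["Eex"];
  q.Ein = p["Ein"]; q.thr = p["thr"]; q.reset = p["reset"]; q.refr = p["refr"];
  return q;
}

static inline double mn_deriv(const MnPars& q, double V, double g_ex, double g_in) {
  return (-q.gl * (V - q.El) - g_ex * (V - q.Eex) - g_in * (V - q.Ein)) / q.C;
}

static inline void mn_rk4(const MnPars& q, double& V, double g_ex, double g_in, double dt) {
  double k1 = mn_deriv(q, V, g_ex, g_in);
  double k2 = mn_deriv(q, V + dt / 2.0 * k1, g_ex, g_in);
  double k3 = mn_deriv(q, V + dt / 2.0 * k2, g_ex, g_in);
  double k4 = mn_deriv(q, V + dt * k3, g_ex, g_in);
  V += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
}

// Integrate one MN pool against a per-step relay-output trace.
// relay in [0,1] scales the inhibitory conductance g_inh_mn.
// [[Rcpp::export]]
List cpp_mn_run(NumericVector pars, double V0, NumericVector relay,
                double g_common, double g_inh_mn, double dt) {
  MnPars q = mn_pars_from(pars);
  int n = relay.size();
  NumericVector V(n + 1);
  std::vector<double> spikes;
  V[0] = V0;
  double v = V0, refr_until = -1.0;
  for (int i = 0; i < n; ++i) {
    double t1 = (i + 1) * dt;
    if (t1 <= refr_until) {
      v = q.reset;
    } else {
      mn_rk4(q, v, g_common, g_inh_mn * relay[i], dt);
      if (!std::isfinite(v))
        stop("motoneuron integration failure: non-finite V at t = %f ms", t1);
      if (v >= q.thr) {
        spikes.push_back(t1);
        v = q.reset;
        refr_until = t1 + q.refr;
      }
    }
    V[i + 1] = v;
  }
  return List::create(_["V"] = V, _["spikes"] = NumericVector(spikes.begin(), spikes.end()));
}

// ---------------------------------------------------------------- muscle algebra
// These small pure functions are the single source of truth: the engine below
// calls them, and the R wrappers export them unchanged.

// [[Rcpp::export]]
double cpp_muscle_stretch(double angle, double slope, double anchor, double dir) {
  double rel = (dir > 0) ? (anchor - angle) : (angle - anchor);
  double s = slope * rel;
  return s > 0.0 ? s : 0.0;
}

// [[Rcpp::export]]
double cpp_residual_stiffness(bool fibre_fast, bool ci_active, bool phase_stance,
                              double k_res_stat, double f_stance) {
  if (fibre_fast) return 0.0;
  if (!ci_active) return k_res_stat;          // stop epoch: full residual
  return phase_stance ? f_stance * k_res_stat : 0.0;
}

// [[Rcpp::export]]
double cpp_total_stiffness(double k_max, double A, double k_res_actual) {
  return k_max * A + k_res_actual;
}

// [[Rcpp::export]]
double cpp_muscle_force(double k_total, double r, double r_c, double stretch) {
  return (r / r_c) * k_total * stretch;
}

// Closed-form recruitment pair for a commanded stationary angle: the stronger
// side is de-recruited so the residual-stiffness balance holds at the target.
// Returns (r1, r2) as fractions of r_c (one of them = 1).
// [[Rcpp::export]]
NumericVector cpp_recruit_pair(double k1, double st1, double k2, double st2) {
  double t1 = k1 * st1, t2 = k2 * st2;
  if (t1 <= 0.0 || t2 <= 0.0)
    stop("recruitment infeasible: a muscle is slack at the target angle");
  if (t1 > t2) return NumericVector::create(t2 / t1, 1.0);
  if (t2 > t1) return NumericVector::create(1.0, t1 / t2);
  return NumericVector::create(1.0, 1.0);
}

// Exact update of first-order activation over one step.
// [[Rcpp::export]]
double cpp_activation_update(double A, bool in_window, double k_act, double k_r, double dt) {
  if (in_window) return 1.0 + (A - 1.0) * std::exp(-k_act * dt);
  return A * std::exp(-k_r * dt);
}

// ---------------------------------------------------------------- full engine

struct Pars {
  // cpg
  CpgPars cpg;
  double tau_scale[3];
  double gda[3], gdb[3], ginh[3];
  double V_thr, trig_C1, trig_C3, trig_C6, pulse_g, pulse_width;
  // mn
  MnPars mn;
  double g_common[12], g_inh_mn, fast_reduced_factor, slow_boost_factor, ap_window;
  // muscle
  double act_st[12], act_sw[12], k_r[12], k_max[12], k_res_stat[12];
  double r[12], r_c[12];
  double slope[6], anchor[6], l_min[6], arm[6], dir[6];
  // joints
  double I[3], b[3], lo[3], hi[3];
  // rules
  double beta_crit_pr, beta_crit_ef, hyst, beta_gc;
  double eps_beta, eps_angle, eps_vel;
  double alpha_crit, f_stance;
  int levdep_slow_tonic, slow_stop_mode;   // slow_stop_mode 1: cut at stop
  double alpha_s, gamma_s;
};

static void read_vec(const List& L, const char* nm, double* dst, int n) {
  NumericVector v = L[nm];
  if (v.size() != n) stop("parameter '%s' must have length %d", nm, n);
  for (int i = 0; i < n; ++i) dst[i] = v[i];
}

static Pars pars_from_list(const List& L) {
  Pars P;
  P.cpg = cpg_pars_from(as<NumericVector>(L["cpg"]));
  read_vec(L, "tau_scale", P.tau_scale, 3);
  read_vec(L, "g_drive_a", P.gda, 3);
  read_vec(L, "g_drive_b", P.gdb, 3);
  read_vec(L, "g_inh_mutual", P.ginh, 3);
  P.V_thr = L["V_thr"]; P.trig_C1 = L["trig_C1"]; P.trig_C3 = L["trig_C3"];
  P.trig_C6 = L["trig_C6"];
  P.pulse_g = L["pulse_g"]; P.pulse_width = L["pulse_width"];
  P.mn = mn_pars_from(as<NumericVector>(L["mn"]));
  read_vec(L, "g_common", P.g_common, 12);
  P.g_inh_mn = L["g_inh_mn"];
  P.fast_reduced_factor = L["fast_reduced_factor"];
  P.slow_boost_factor = L["slow_boost_factor"];
  P.ap_window = L["ap_window"];
  read_vec(L, "act_rate_stance", P.act_st, 12);
  read_vec(L, "act_rate_swing", P.act_sw, 12);
  read_vec(L, "relax_rate", P.k_r, 12);
  read_vec(L, "k_max", P.k_max, 12);
  read_vec(L, "k_res_stat", P.k_res_stat, 12);
  read_vec(L, "recruitment", P.r, 12);
  read_vec(L, "recruitment_ref", P.r_c, 12);
  read_vec(L, "slope", P.slope, 6);
  read_vec(L, "anchor", P.anchor, 6);
  read_vec(L, "l_min", P.l_min, 6);
  read_vec(L, "arm", P.arm, 6);
  read_vec(L, "dir", P.dir, 6);
  read_vec(L, "inertia", P.I, 3);
  read_vec(L, "damping", P.b, 3);
  read_vec(L, "angle_lo", P.lo, 3);
  read_vec(L, "angle_hi", P.hi, 3);
  P.beta_crit_pr = L["beta_crit_pr"]; P.beta_crit_ef = L["beta_crit_ef"];
  P.hyst = L["hysteresis"]; P.beta_gc = L["beta_gc"];
  P.eps_beta = L["eps_beta"]; P.eps_angle = L["eps_angle"]; P.eps_vel = L["eps_vel"];
  P.alpha_crit = L["alpha_crit"]; P.f_stance = L["f_stance"];
  P.levdep_slow_tonic = as<int>(L["levdep_slow_tonic"]);
  P.slow_stop_mode = as<int>(L["slow_stop_mode"]);
  P.alpha_s = L["alpha_s"]; P.gamma_s = L["gamma_s"];
  return P;
}

// joint of each muscle type
static const int JOINT_OF[6] = { 0, 0, 1, 1, 2, 2 };
// stance-active classification neuron per system (C1, C4, C6 -> idx 0, 3, 5)
static const int STANCE_NEURON[3] = { 0, 3, 5 };
// system of each muscle type (PR, PR, LD, LD, EF, EF)
static const int SYS_OF[6] = { 0, 0, 1, 1, 2, 2 };
// relay source: pool of muscle m is inhibited when its antagonist's CPG
// neuron is active. pro<-C1, ret<-C2, lev<-C4, dep<-C3, ext<-C6, flex<-C5
static const int RELAY_SRC[6] = { 0, 1, 3, 2, 5, 4 };

struct Event { double t; int code; double value; };

// gate levels (fast pools: normal -> armed at the stop switch -> reduced
// when the ongoing swing-phase burst completes; slow pools: normal ->
// enhanced (disinhibited) -> off)
enum { G_NORMAL = 0, G_REDUCED = 1, G_ENHANCED = 1, G_OFF = 2, G_ARMED = 2 };

// event codes (kept in step with R's .event_labels)
enum {
  EV_STOP_CMD = 1, EV_START_CMD = 2, EV_FAST_PR_REDUCED = 3, EV_FAST_EF_REDUCED = 4,
  EV_SLOW_PR_ENHANCED = 5, EV_SLOW_EF_ENHANCED = 6, EV_LD_OFF_LATCH = 7,
  EV_SLOW_PR_OFF = 8, EV_SLOW_EF_OFF = 9, EV_PR_ENABLED = 10, EV_EF_ENABLED = 11,
  EV_LD_ENABLED = 12, EV_BETA_PR_UP = 13, EV_BETA_PR_DOWN = 14,
  EV_BETA_EF_UP = 15, EV_BETA_EF_DOWN = 16, EV_MODE_SELECTED = 17
};

// [[Rcpp::export]]
List cpp_simulate(List pars, NumericMatrix schedule, NumericVector init_angles,
                  NumericVector cpg_init, double dt, double duration, int stride,
                  bool start_at_rest) {
  Pars P = pars_from_list(pars);
  const int nstep = (int) std::ceil(duration / dt + 1e-9);
  const int nsamp = nstep / stride + 1;

  // ---- continuous state
  double Vc[6], hc[6];                      // CPG
  for (int i = 0; i < 6; ++i) { Vc[i] = cpg_init[2 * i]; hc[i] = cpg_init[2 * i + 1]; }
  double Vmn[12];
  for (int i = 0; i < 12; ++i) Vmn[i] = P.mn.El;
  double th[3], om[3] = { 0, 0, 0 };
  for (int j = 0; j < 3; ++j) th[j] = init_angles[j];

  // ---- discrete state
  double A[12] = { 0 };
  double refr_until[12], window_until[12];
  for (int i = 0; i < 12; ++i) { refr_until[i] = -1.0; window_until[i] = -1.0; }
  double r_act[12];
  for (int i = 0; i < 12; ++i) r_act[i] = P.r[i];

  bool stop_active = false, start_active = false;
  int fast_pr = G_NORMAL, fast_ef = G_NORMAL;   // 0 normal, 1 reduced
  int slow_pr = G_NORMAL, slow_ef = G_NORMAL;   // 0 normal, 1 enhanced, 2 off
  int ld_gate = G_NORMAL;                       // 0 normal, 1 off (with latch)
  bool fast_pr_latched = false, fast_ef_latched = false;
  bool latch = false;
  bool ci_active = true;
  int start_mode = -1, start_stage = 0;
  bool prev_above_trig1 = false, prev_above_trig3 = false, prev_above_trig6 = false;
  bool start_c3_pulsed = false;

  if (start_at_rest) {
    stop_active = true; ci_active = false;
    fast_pr = G_REDUCED; fast_ef = G_REDUCED;
    slow_pr = G_OFF; slow_ef = G_OFF;
    ld_gate = G_OFF; latch = true;
    fast_pr_latched = fast_ef_latched = true;
    th[1] = P.beta_gc; om[1] = 0.0;
  }

  // beta threshold hysteresis state: 1 above, 0 below
  int pos_pr = (th[1] > P.beta_crit_pr) ? 1 : 0;
  int pos_ef = (th[1] > P.beta_crit_ef) ? 1 : 0;
  double pulse_until[6] = { -1, -1, -1, -1, -1, -1 };

  int sched_i = 0;
  const int nsched = schedule.nrow();
  bool prev_stance[3];
  for (int s = 0; s < 3; ++s) prev_stance[s] = Vc[STANCE_NEURON[s]] >= P.V_thr;

  std::vector<Event> events;
  std::vector< std::vector<double> > spikes(12);
  const int NC = 86;
  NumericMatrix trace(nsamp, NC);
  int spk_count[12] = { 0 };

  // sanity: drives constant by construction; log them every sample anyway so
  // the autonomy invariant is checkable on the trace itself.

  int samp = 0;
  for (int step = 0; step <= nstep; ++step) {
    const double t = step * dt;

    // ---------- sensors: beta threshold crossings (with hysteresis) ----------
    double beta = th[1];
    if (pos_pr == 0 && beta > P.beta_crit_pr + P.hyst) {
      pos_pr = 1;
      pulse_until[1] = t + P.pulse_width;          // excite C2 -> protraction
      events.push_back({ t, EV_BETA_PR_UP, beta });
    } else if (pos_pr == 1 && beta < P.beta_crit_pr - P.hyst) {
      pos_pr = 0;
      pulse_until[0] = t + P.pulse_width;          // excite C1 -> retraction
      events.push_back({ t, EV_BETA_PR_DOWN, beta });
    }
    if (pos_ef == 0 && beta > P.beta_crit_ef + P.hyst) {
      pos_ef = 1;
      pulse_until[4] = t + P.pulse_width;          // excite C5 -> extension
      events.push_back({ t, EV_BETA_EF_UP, beta });
    } else if (pos_ef == 1 && beta < P.beta_crit_ef - P.hyst) {
      pos_ef = 0;
      pulse_until[5] = t + P.pulse_width;          // excite C6 -> flexion
      events.push_back({ t, EV_BETA_EF_DOWN, beta });
    }

    // ---------- central commands (take effect at first step >= time) ----------
    while (sched_i < nsched && schedule(sched_i, 0) <= t + 1e-9) {
      int code = (int) schedule(sched_i, 1);
      double a_s = schedule(sched_i, 2);
      if (code == 1) {                             // stop
        stop_active = true; start_active = false;
        ci_active = false;                         // stop command inhibits CI directly
        if (R_finite(a_s)) P.alpha_s = a_s;
        // recruitment of the slow PR pair for the commanded stationary angle
        {
          double st1 = cpp_muscle_stretch(P.alpha_s, P.slope[0], P.anchor[0], P.dir[0]);
          double st2 = cpp_muscle_stretch(P.alpha_s, P.slope[1], P.anchor[1], P.dir[1]);
          NumericVector rr = cpp_recruit_pair(P.k_res_stat[6], st1, P.k_res_stat[7], st2);
          r_act[6] = rr[0] * P.r_c[6]; r_act[7] = rr[1] * P.r_c[7];
          double sg1 = cpp_muscle_stretch(P.gamma_s, P.slope[4], P.anchor[4], P.dir[4]);
          double sg2 = cpp_muscle_stretch(P.gamma_s, P.slope[5], P.anchor[5], P.dir[5]);
          NumericVector rg = cpp_recruit_pair(P.k_res_stat[10], sg1, P.k_res_stat[11], sg2);
          r_act[10] = rg[0] * P.r_c[10]; r_act[11] = rg[1] * P.r_c[11];
        }
        fast_pr_latched = fast_ef_latched = false;
        if (P.slow_stop_mode == 1) {
          // ablation variant: slow PR/EF pools silenced at the stop command
          slow_pr = G_OFF; slow_ef = G_OFF;
        } else {
          // slow-MN boost via enhanced central inhibition of their INs
          if (slow_pr == G_NORMAL) { slow_pr = G_ENHANCED; events.push_back({ t, EV_SLOW_PR_ENHANCED, 0 }); }
          if (slow_ef == G_NORMAL) { slow_ef = G_ENHANCED; events.push_back({ t, EV_SLOW_EF_ENHANCED, 0 }); }
        }
        events.push_back({ t, EV_STOP_CMD, P.alpha_s });
      } else {                                     // start
        start_active = true; stop_active = false;
        ci_active = true;                          // start reactivates CI immediately
        start_mode = (P.alpha_s < P.alpha_crit) ? 0 : 1;  // 0 swing-first, 1 stance-first
        start_stage = 0;
        start_c3_pulsed = false;
        prev_above_trig1 = Vc[0] >= P.trig_C1;
        prev_above_trig3 = Vc[2] >= P.trig_C3;
        prev_above_trig6 = Vc[5] >= P.trig_C6;
        events.push_back({ t, EV_START_CMD, (double) start_mode });
        events.push_back({ t, EV_MODE_SELECTED, (double) start_mode });
      }
      ++sched_i;
    }

    // ---------- phase flags ----------
    bool stance[3];
    for (int s = 0; s < 3; ++s) stance[s] = Vc[STANCE_NEURON[s]] >= P.V_thr;

    // ---------- coordination rules ----------
    if (stop_active) {
      // fast gates: the once-only switch arms while the relevant angle is in
      // its decreasing (protraction / extension) phase; the pools fall silent
      // when that swing-phase burst completes (end of the last protraction)
      if (!fast_pr_latched && om[0] < 0.0) {
        fast_pr = G_ARMED; fast_pr_latched = true;
        events.push_back({ t, EV_FAST_PR_REDUCED, om[0] });
      }
      if (!fast_ef_latched && om[2] < 0.0) {
        fast_ef = G_ARMED; fast_ef_latched = true;
        events.push_back({ t, EV_FAST_EF_REDUCED, om[2] });
      }
      if (fast_pr == G_ARMED && stance[0] && !prev_stance[0]) fast_pr = G_REDUCED;
      if (fast_ef == G_ARMED && stance[2] && !prev_stance[2]) fast_ef = G_REDUCED;
      // levator-depressor block + permanent ground contact
      if (ld_gate == G_NORMAL && fast_pr == G_REDUCED && fast_ef == G_REDUCED &&
          om[1] <= 0.0 && std::fabs(th[1] - P.beta_gc) <= P.eps_beta) {
        ld_gate = G_OFF; latch = true;
        th[1] = P.beta_gc; om[1] = 0.0;
        events.push_back({ t, EV_LD_OFF_LATCH, th[1] });
      }
      // slow gates: off when the angle has converged and velocity is near zero
      if (slow_pr == G_ENHANCED && latch &&
          std::fabs(th[0] - P.alpha_s) <= P.eps_angle &&
          std::fabs(om[0]) <= P.eps_vel) {
        slow_pr = G_OFF;
        events.push_back({ t, EV_SLOW_PR_OFF, th[0] });
      }
      if (slow_ef == G_ENHANCED && latch &&
          std::fabs(th[2] - P.gamma_s) <= P.eps_angle &&
          std::fabs(om[2]) <= P.eps_vel) {
        slow_ef = G_OFF;
        events.push_back({ t, EV_SLOW_EF_OFF, th[2] });
      }
    }
    if (start_active) {
      bool above1 = Vc[0] >= P.trig_C1, above3 = Vc[2] >= P.trig_C3, above6 = Vc[5] >= P.trig_C6;
      if (start_mode == 0) {
        // swing-first: everything released when C3 reaches its depolarization level
        if (!prev_above_trig3 && above3) {
          fast_pr = fast_ef = G_NORMAL;
          slow_pr = slow_ef = G_NORMAL;
          ld_gate = G_NORMAL; latch = false;
          events.push_back({ t, EV_PR_ENABLED, 0 });
          events.push_back({ t, EV_EF_ENABLED, 0 });
          events.push_back({ t, EV_LD_ENABLED, 0 });
          start_active = false;
        }
      } else {
        // stance-first cascade: PR at the C1 crossing, then EF (flexion) given
        // PR active, then LD once retraction and flexion are done (CPG phases)
        if (start_stage == 0 && !prev_above_trig1 && above1) {
          fast_pr = G_NORMAL; slow_pr = G_NORMAL;
          start_stage = 1;
          // standing load signal: the grounded leg re-entrains the LD CPG
          // into its depression phase while the retraction runs
          pulse_until[3] = t + P.pulse_width;
          events.push_back({ t, EV_PR_ENABLED, 0 });
        }
        if (start_stage == 1 && above6) {
          fast_ef = G_NORMAL; slow_ef = G_NORMAL;
          start_stage = 2;
          events.push_back({ t, EV_EF_ENABLED, 0 });
        }
        if (start_stage == 2 && Vc[0] < P.V_thr && Vc[5] < P.V_thr &&
            !start_c3_pulsed && !above3) {
          // retraction and flexion complete: the position signal initiates
          // the levation phase of the LD CPG
          pulse_until[2] = t + P.pulse_width;
          start_c3_pulsed = true;
        }
        if (start_stage == 2 && Vc[0] < P.V_thr && Vc[5] < P.V_thr && above3) {
          ld_gate = G_NORMAL; latch = false;
          start_stage = 3;
          events.push_back({ t, EV_LD_ENABLED, 0 });
          start_active = false;
        }
      }
      prev_above_trig1 = above1; prev_above_trig3 = above3; prev_above_trig6 = above6;
    }

    for (int s = 0; s < 3; ++s) prev_stance[s] = stance[s];

    // ---------- residual stiffness and forces ----------
    double kres[12], ktot[12], force[12];
    for (int p = 0; p < 12; ++p) {
      int m = p % 6;
      kres[p] = cpp_residual_stiffness(p < 6, ci_active, stance[SYS_OF[m]],
                                       P.k_res_stat[p], P.f_stance);
      double st = cpp_muscle_stretch(th[JOINT_OF[m]], P.slope[m], P.anchor[m], P.dir[m]);
      ktot[p] = cpp_total_stiffness(P.k_max[p], A[p], kres[p]);
      force[p] = cpp_muscle_force(ktot[p], r_act[p], P.r_c[p], st);
    }

    // ---------- relay outputs (graded, per pool) ----------
    double relay[12];     // inhibition in [0,1] delivered to each pool
    double gfac[12];      // multiplicative factor on the common drive
    for (int p = 0; p < 12; ++p) {
      int m = p % 6, s = SYS_OF[m];
      double cpg_inh = syn_gate(P.cpg, Vc[RELAY_SRC[m]]);
      double out = cpg_inh;
      double fac = 1.0;
      bool is_fast = p < 6;
      if (s == 0) {                       // PR
        if (is_fast) { if (fast_pr == G_REDUCED) fac = P.fast_reduced_factor; }
        else {
          if (slow_pr == G_ENHANCED) { out = 0.0; fac = P.slow_boost_factor; }
          else if (slow_pr == G_OFF) out = 1.0;
        }
      } else if (s == 2) {                // EF
        if (is_fast) { if (fast_ef == G_REDUCED) fac = P.fast_reduced_factor; }
        else {
          if (slow_ef == G_ENHANCED) { out = 0.0; fac = P.slow_boost_factor; }
          else if (slow_ef == G_OFF) out = 1.0;
        }
      } else {                            // LD: slow pool rhythmic like the fast
        if (ld_gate == G_OFF) out = 1.0;
        if (!is_fast && P.levdep_slow_tonic && ld_gate == G_NORMAL) out = 0.0;
      }
      relay[p] = out;
      gfac[p] = fac;
    }

    if (step == nstep) {
      // final sample only (no step beyond the horizon)
    }

    // ---------- sample ----------
    if (step % stride == 0) {
      int c = 0;
      trace(samp, c++) = t;
      for (int j = 0; j < 3; ++j) trace(samp, c++) = th[j];
      for (int j = 0; j < 3; ++j) trace(samp, c++) = om[j];
      for (int i = 0; i < 6; ++i) trace(samp, c++) = Vc[i];
      for (int p = 0; p < 12; ++p) trace(samp, c++) = A[p];
      for (int p = 6; p < 12; ++p) trace(samp, c++) = kres[p];
      for (int p = 0; p < 12; ++p) trace(samp, c++) = ktot[p];
      for (int p = 0; p < 12; ++p) trace(samp, c++) = force[p];
      for (int p = 0; p < 12; ++p) { trace(samp, c++) = spk_count[p]; spk_count[p] = 0; }
      for (int s = 0; s < 3; ++s) trace(samp, c++) = stance[s] ? 1.0 : 0.0;
      trace(samp, c++) = fast_pr; trace(samp, c++) = fast_ef;
      trace(samp, c++) = slow_pr; trace(samp, c++) = slow_ef;
      trace(samp, c++) = ld_gate;
      trace(samp, c++) = latch ? 1.0 : 0.0;
      trace(samp, c++) = (latch || std::fabs(th[1] - P.beta_gc) <= P.eps_beta) ? 1.0 : 0.0;
      trace(samp, c++) = ci_active ? 1.0 : 0.0;
      trace(samp, c++) = stop_active ? 1.0 : 0.0;
      trace(samp, c++) = start_active ? 1.0 : 0.0;
      for (int s = 0; s < 3; ++s) { trace(samp, c++) = P.gda[s]; trace(samp, c++) = P.gdb[s]; }
      ++samp;
    }
    if (step == nstep) break;

    // ---------- integrate one step ----------
    // CPG block (live coupling within the 3 pairs)
    for (int s = 0; s < 3; ++s) {
      int ia = 2 * s, ib = 2 * s + 1;
      double st4[4] = { Vc[ia], hc[ia], Vc[ib], hc[ib] };
      double gxa = (t < pulse_until[ia]) ? P.pulse_g : 0.0;
      double gxb = (t < pulse_until[ib]) ? P.pulse_g : 0.0;
      CpgPars q = P.cpg;
      q.tau_hbar *= P.tau_scale[s];
      cpg_pair_rk4(q, st4, P.gda[s], P.gdb[s], P.ginh[s], gxa, gxb, dt);
      Vc[ia] = st4[0]; hc[ia] = st4[1]; Vc[ib] = st4[2]; hc[ib] = st4[3];
      for (int j = 0; j < 4; ++j)
        if (!std::isfinite(st4[j]))
          stop("integration failure: non-finite CPG state (system %d) at t = %f ms", s + 1, t);
    }
    // MN pools
    const double t1 = t + dt;
    for (int p = 0; p < 12; ++p) {
      if (t1 <= refr_until[p]) { Vmn[p] = P.mn.reset; continue; }
      mn_rk4(P.mn, Vmn[p], P.g_common[p] * gfac[p], P.g_inh_mn * relay[p], dt);
      if (!std::isfinite(Vmn[p]))
        stop("integration failure: non-finite MN state (pool %d) at t = %f ms", p + 1, t);
      if (Vmn[p] >= P.mn.thr) {
        spikes[p].push_back(t1);
        ++spk_count[p];
        Vmn[p] = P.mn.reset;
        refr_until[p] = t1 + P.mn.refr;
        window_until[p] = t1 + P.ap_window;
      }
    }
    // muscle activation (exact first-order update, step-frozen window status)
    for (int p = 0; p < 12; ++p) {
      int m = p % 6;
      bool in_w = t < window_until[p];
      double k_act = stance[SYS_OF[m]] ? P.act_st[p] : P.act_sw[p];
      A[p] = cpp_activation_update(A[p], in_w, k_act, P.k_r[p], dt);
    }
    // joints (RK4 on angle+velocity; forces recomputed at substep angles with
    // step-frozen activations and stiffness branches)
    for (int j = 0; j < 3; ++j) {
      if (j == 1 && latch) { th[1] = P.beta_gc; om[1] = 0.0; continue; }
      double y0 = th[j], y1 = om[j];
      double ka[4], kb[4];
      for (int stg = 0; stg < 4; ++stg) {
        double f = (stg == 0) ? 0.0 : (stg == 3 ? dt : dt / 2.0);
        double a = y0 + f * (stg == 0 ? 0.0 : ka[stg - 1]);
        double w = y1 + f * (stg == 0 ? 0.0 : kb[stg - 1]);
        double tau = 0.0;
        for (int m = 0; m < 6; ++m) {
          if (JOINT_OF[m] != j) continue;
          double st = cpp_muscle_stretch(a, P.slope[m], P.anchor[m], P.dir[m]);
          double F = cpp_muscle_force(ktot[m], r_act[m], P.r_c[m], st)
                   + cpp_muscle_force(ktot[m + 6], r_act[m + 6], P.r_c[m + 6], st);
          tau += P.dir[m] * P.arm[m] * F;
        }
        ka[stg] = w;
        kb[stg] = (tau - P.b[j] * w) / P.I[j];
      }
      th[j] = y0 + dt / 6.0 * (ka[0] + 2 * ka[1] + 2 * ka[2] + ka[3]);
      om[j] = y1 + dt / 6.0 * (kb[0] + 2 * kb[1] + 2 * kb[2] + kb[3]);
      if (!std::isfinite(th[j]) || !std::isfinite(om[j]))
        stop("integration failure: non-finite joint state (joint %d) at t = %f ms", j + 1, t);
      if (th[j] < P.lo[j]) { th[j] = P.lo[j]; if (om[j] < 0) om[j] = 0; }
      if (th[j] > P.hi[j]) { th[j] = P.hi[j]; if (om[j] > 0) om[j] = 0; }
    }
  }

  NumericMatrix ev((int) events.size(), 3);
  for (size_t i = 0; i < events.size(); ++i) {
    ev(i, 0) = events[i].t; ev(i, 1) = events[i].code; ev(i, 2) = events[i].value;
  }
  List spk(12);
  for (int p = 0; p < 12; ++p)
    spk[p] = NumericVector(spikes[p].begin(), spikes[p].end());
  return List::create(_["trace"] = trace, _["events"] = ev, _["spikes"] = spk);
}
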