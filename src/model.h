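#ifndef ATRIASIM_MODEL_H
#define ATRIASIM_MODEL_H

#include <Rcpp.h>
#include <cmath>
#include <vector>

// Units throughout: mV, ms, pA, nS, pF, mM. Volumes in litres.
// Membrane equation: dV/dt = -(I_ion + I_gap)/Cm + i_stim  (i_stim in pA/pF,
// depolarizing positive); the tissue solver adds the diffusion term.

namespace atriasim {

constexpr double RTF  = 26.73;    // RT/F at 310 K, mV
constexpr double FDAY = 96487.0;  // C/mol

// ---------------------------------------------------------------------------
// Human atrial myocyte (Nygren-family formulation with AF-type remodelling
// and an SK / Ca-activated K current). 19 state variables.
// ---------------------------------------------------------------------------

enum MyoStateIdx {
  M_V = 0,
  M_m, M_h1, M_h2,          // INa gates
  M_d, M_f1, M_f2,          // ICaL gates
  M_r, M_s,                 // Ito gates
  M_rsus, M_ssus,           // IKur gates
  M_n,                      // IKs gate
  M_pa,                     // IKr gate
  M_arel, M_irel,           // RyR activation / inactivation
  M_Nai, M_Ki, M_Cai, M_CaSR,
  MYO_NSTATE
};
constexpr int MYO_NGATE = 12;     // voltage-gated (Rush-Larsen, LUT-able)

struct MyoParams {
  double Cm;
  double g_Na, g_CaL, g_t, g_Kur, g_Ks, g_Kr, g_K1, g_SK;
  double I_NaK_max, k_NaK_K, k_NaK_Na;
  double k_NaCa, gamma_NaCa, d_NaCa;
  double I_CaP_max, k_CaP;
  double g_bNa, g_bCa;
  double Na_o, K_o, Ca_o;
  double E_CaL_app, k_Ca_inact;
  double EC50_SK;
  double Vol_i, Vol_sr;           // litres
  double buf_i, buf_sr;           // instantaneous buffering factors
  double V_max_up, K_up, g_rel, k_SR_leak;
  double K_rel_inact, tau_rel_act, tau_rel_inact;
  double D;                       // tissue diffusion, cm^2/ms (profile-scaled)
  double pow_Ko4457, pow_kNaKNa15;  // derived, set on construction
};

inline MyoParams myo_params_from_list(const Rcpp::List& p) {
  MyoParams q;
  q.Cm = p["Cm"];
  q.g_Na = p["g_Na"]; q.g_CaL = p["g_CaL"]; q.g_t = p["g_t"];
  q.g_Kur = p["g_Kur"]; q.g_Ks = p["g_Ks"]; q.g_Kr = p["g_Kr"];
  q.g_K1 = p["g_K1"]; q.g_SK = p["g_SK"];
  q.I_NaK_max = p["I_NaK_max"]; q.k_NaK_K = p["k_NaK_K"]; q.k_NaK_Na = p["k_NaK_Na"];
  q.k_NaCa = p["k_NaCa"]; q.gamma_NaCa = p["gamma_NaCa"]; q.d_NaCa = p["d_NaCa"];
  q.I_CaP_max = p["I_CaP_max"]; q.k_CaP = p["k_CaP"];
  q.g_bNa = p["g_bNa"]; q.g_bCa = p["g_bCa"];
  q.Na_o = p["Na_o"]; q.K_o = p["K_o"]; q.Ca_o = p["Ca_o"];
  q.E_CaL_app = p["E_CaL_app"]; q.k_Ca_inact = p["k_Ca_inact"];
  q.EC50_SK = p["EC50_SK"];
  q.Vol_i = p["Vol_i"]; q.Vol_sr = p["Vol_sr"];
  q.buf_i = p["buf_i"]; q.buf_sr = p["buf_sr"];
  q.V_max_up = p["V_max_up"]; q.K_up = p["K_up"]; q.g_rel = p["g_rel"];
  q.k_SR_leak = p["k_SR_leak"]; q.K_rel_inact = p["K_rel_inact"];
  q.tau_rel_act = p["tau_rel_act"]; q.tau_rel_inact = p["tau_rel_inact"];
  q.D = p["D"];
  q.pow_Ko4457 = std::pow(q.K_o, 0.4457);
  q.pow_kNaKNa15 = std::pow(q.k_NaK_Na, 1.5);
  return q;
}

// Steady states and time constants for the 12 voltage-dependent myocyte gates,
// order: m, h1, h2, d, f1, f2, r, s, rsus, ssus, n, pa.
inline void myo_gate_rates(double V, double* winf, double* tau) {
  double e;
  // INa activation / fast + slow inactivation
  winf[0] = 1.0 / (1.0 + std::exp(-(V + 27.12) / 8.21));
  e = (V + 25.57) / 28.8;
  tau[0] = 0.042 * std::exp(-e * e) + 0.024;
  winf[1] = winf[2] = 1.0 / (1.0 + std::exp((V + 63.6) / 5.3));
  tau[1] = 30.0 / (1.0 + std::exp((V + 35.1) / 3.2)) + 0.3;
  tau[2] = 120.0 / (1.0 + std::exp((V + 35.1) / 3.2)) + 3.0;
  // ICaL
  winf[3] = 1.0 / (1.0 + std::exp(-(V + 9.0) / 5.8));
  e = (V + 35.0) / 30.0;
  tau[3] = 2.7 * std::exp(-e * e) + 2.0;
  winf[4] = winf[5] = 1.0 / (1.0 + std::exp((V + 27.4) / 7.1));
  e = (V + 40.0) / 14.4;
  tau[4] = 161.0 * std::exp(-e * e) + 10.0;
  e = (V + 40.0) / 14.2;
  tau[5] = 1332.3 * std::exp(-e * e) + 62.6;
  // Ito
  winf[6] = 1.0 / (1.0 + std::exp(-(V - 1.0) / 11.0));
  e = V / 30.0;
  tau[6] = 3.5 * std::exp(-e * e) + 1.5;
  winf[7] = 1.0 / (1.0 + std::exp((V + 40.5) / 11.5));
  e = (V + 52.45) / 14.97;
  tau[7] = 481.2 * std::exp(-e * e) + 14.14;
  // IKur (sustained outward)
  winf[8] = 1.0 / (1.0 + std::exp(-(V + 4.3) / 8.0));
  tau[8] = 9.0 / (1.0 + std::exp((V + 5.0) / 12.0)) + 0.5;
  winf[9] = 0.4 / (1.0 + std::exp((V + 20.0) / 10.0)) + 0.6;
  tau[9] = 47.0 / (1.0 + std::exp((V + 60.0) / 10.0)) + 300.0;
  // IKs
  winf[10] = 1.0 / (1.0 + std::exp(-(V - 19.9) / 12.7));
  e = (V - 20.0) / 20.0;
  tau[10] = 700.0 + 400.0 * std::exp(-e * e);
  // IKr activation
  winf[11] = 1.0 / (1.0 + std::exp(-(V + 15.0) / 6.0));
  e = (V + 20.1376) / 22.1996;
  tau[11] = 31.18 + 217.18 * std::exp(-e * e);
}

// Voltage-only factors entering the current equations (LUT-able).
struct MyoVF {
  double pi_kr;     // IKr instantaneous inactivation
  double k1_mult;   // IK1 rectification multiplier 1/(1+exp(...))
  double naca_e1;   // exp(gamma V / RTF)
  double naca_e2;   // exp((gamma-1) V / RTF)
  double nak_vf;    // (V+150)/(V+200)
};

// E_K is needed for the inward-rectifier factor; pass the current value.
inline MyoVF myo_vf_exact(double V, const MyoParams& p, double E_K) {
  MyoVF f;
  f.pi_kr = 1.0 / (1.0 + std::exp((V + 55.0) / 24.0));
  f.k1_mult = 1.0 / (1.0 + std::exp(1.5 * (V - E_K + 3.6) / RTF));
  f.naca_e1 = std::exp(p.gamma_NaCa * V / RTF);
  f.naca_e2 = std::exp((p.gamma_NaCa - 1.0) * V / RTF);
  f.nak_vf = (V + 150.0) / (V + 200.0);
  return f;
}

struct MyoCurrents {
  double I_ion;       // total transmembrane ionic current, pA (excl. gap/stim)
  double I_Na_tot;    // Na-carried sum for [Na+]i bookkeeping
  double I_K_tot;     // K-carried sum for [K+]i bookkeeping
  double I_Ca_mem;    // membrane Ca flux sum (ICaL + IbCa + ICaP - 2 INaCa)
};

// Advance one myocyte by dt. `gw_inf`/`gw_efac` are the per-gate steady state
// and exp(-dt/tau) (Rush-Larsen); callers supply them either exactly or from a
// lookup table. i_gap_* in pA (positive = leaving the myocyte).
constexpr int MYO_NCURR = 13;  // INa ICaL It IKur IKs IKr IK1 ISK INaK INaCa ICaP IbNa IbCa

// Nernst potentials and the two release-gate decay factors exp(-dt/tau) are
// supplied by the caller (they vary slowly / are constant per run).
inline MyoCurrents myo_step(double* s, const MyoParams& p, double dt,
                            double i_stim_pApF, double i_gap_Na, double i_gap_K,
                            const double* gw_inf, const double* gw_efac,
                            const MyoVF& vf,
                            double E_Na, double E_K, double E_Ca,
                            double e_rel_act, double e_rel_inact,
                            double* comps = nullptr) {
  const double V = s[M_V];
  const double Nai = s[M_Nai], Ki = s[M_Ki], Cai = s[M_Cai], CaSR = s[M_CaSR];

  const double I_Na = p.g_Na * s[M_m] * s[M_m] * s[M_m] *
                      (0.9 * s[M_h1] + 0.1 * s[M_h2]) * (V - E_Na);
  const double f_ca = 1.0 / (1.0 + Cai / p.k_Ca_inact);
  const double I_CaL = p.g_CaL * s[M_d] * (0.7 * s[M_f1] + 0.3 * s[M_f2]) *
                       f_ca * (V - p.E_CaL_app);
  const double I_t   = p.g_t * s[M_r] * s[M_s] * (V - E_K);
  const double I_Kur = p.g_Kur * s[M_rsus] * s[M_ssus] * (V - E_K);
  const double I_Ks  = p.g_Ks * s[M_n] * (V - E_K);
  const double I_Kr  = p.g_Kr * s[M_pa] * vf.pi_kr * (V - E_K);
  const double I_K1  = p.g_K1 * p.pow_Ko4457 * (V - E_K) * vf.k1_mult;
  const double ca2 = Cai * Cai;
  const double I_SK  = p.g_SK * ca2 / (ca2 + p.EC50_SK * p.EC50_SK) * (V - E_K);
  const double na15 = Nai * std::sqrt(Nai);
  const double I_NaK = p.I_NaK_max * p.K_o / (p.K_o + p.k_NaK_K) *
                       na15 / (na15 + p.pow_kNaKNa15) * vf.nak_vf;
  const double nai3 = Nai * Nai * Nai, nao3 = p.Na_o * p.Na_o * p.Na_o;
  const double I_NaCa = p.k_NaCa *
      (nai3 * p.Ca_o * vf.naca_e1 - nao3 * Cai * vf.naca_e2) /
      (1.0 + p.d_NaCa * (nao3 * Cai + nai3 * p.Ca_o));
  const double I_CaP = p.I_CaP_max * Cai / (Cai + p.k_CaP);
  const double I_bNa = p.g_bNa * (V - E_Na);
  const double I_bCa = p.g_bCa * (V - E_Ca);

  if (comps) {
    comps[0] = I_Na; comps[1] = I_CaL; comps[2] = I_t; comps[3] = I_Kur;
    comps[4] = I_Ks; comps[5] = I_Kr; comps[6] = I_K1; comps[7] = I_SK;
    comps[8] = I_NaK; comps[9] = I_NaCa; comps[10] = I_CaP;
    comps[11] = I_bNa; comps[12] = I_bCa;
  }
  MyoCurrents out;
  out.I_Na_tot = I_Na + I_bNa + 3.0 * I_NaK + 3.0 * I_NaCa;
  out.I_K_tot  = I_t + I_Kur + I_Ks + I_Kr + I_K1 + I_SK - 2.0 * I_NaK;
  out.I_Ca_mem = I_CaL + I_bCa + I_CaP - 2.0 * I_NaCa;
  // species sums net to the correct total charge: 3-2 = 1 x I_NaK, 3-2 = 1 x I_NaCa
  out.I_ion = out.I_Na_tot + out.I_K_tot + out.I_Ca_mem;

  // SR calcium handling (two lumped compartments). Release is triggered by
  // depolarization (L-type-like activation gate) and inactivated by high
  // cytosolic Ca2+; a small constant leak balances SERCA uptake at rest.
  const double J_up  = p.V_max_up * ca2 / (ca2 + p.K_up * p.K_up);
  const double J_rel = (p.g_rel * s[M_arel] * s[M_irel] + p.k_SR_leak) *
                       (CaSR - Cai);

  // release gate dynamics (Rush-Larsen with frozen rates); the activation
  // steady state equals the ICaL d-gate steady state (gw_inf[3])
  {
    double a_inf = gw_inf[3];
    double y = Cai / p.K_rel_inact;
    double y2 = y * y;
    double i_inf = 1.0 / (1.0 + y2 * y2);
    s[M_arel] = a_inf + (s[M_arel] - a_inf) * e_rel_act;
    s[M_irel] = i_inf + (s[M_irel] - i_inf) * e_rel_inact;
  }

  // Voltage-gated channels: Rush-Larsen
  double* g = s + M_m;
  for (int k = 0; k < MYO_NGATE; ++k)
    g[k] = gw_inf[k] + (g[k] - gw_inf[k]) * gw_efac[k];

  const double conv = 1.0e-12 / (FDAY * p.Vol_i);  // pA -> mM/ms in cytosol
  s[M_Nai] += dt * (-conv * (out.I_Na_tot + i_gap_Na));
  s[M_Ki]  += dt * (-conv * (out.I_K_tot + i_gap_K) + conv * i_stim_pApF * p.Cm);
  s[M_Cai] += dt * p.buf_i * (-0.5 * conv * out.I_Ca_mem + J_rel - J_up);
  s[M_CaSR] += dt * p.buf_sr * (J_up - J_rel) * (p.Vol_i / p.Vol_sr);

  s[M_V] += dt * (-(out.I_ion + i_gap_Na + i_gap_K) / p.Cm + i_stim_pApF);
  return out;
}

// Exact (non-tabulated) single-cell step: rates, Nernst and factors computed
// fresh from the current state.
inline MyoCurrents myo_step_exact(double* s, const MyoParams& p, double dt,
                                  double i_stim_pApF, double i_gap_Na,
                                  double i_gap_K, double* comps = nullptr) {
  double winf[MYO_NGATE], tau[MYO_NGATE], efac[MYO_NGATE];
  myo_gate_rates(s[M_V], winf, tau);
  if (dt > 0.0)
    for (int k = 0; k < MYO_NGATE; ++k) efac[k] = std::exp(-dt / tau[k]);
  else
    for (int k = 0; k < MYO_NGATE; ++k) efac[k] = 1.0;
  const double E_Na = RTF * std::log(p.Na_o / s[M_Nai]);
  const double E_K  = RTF * std::log(p.K_o / s[M_Ki]);
  const double E_Ca = 0.5 * RTF * std::log(p.Ca_o / s[M_Cai]);
  MyoVF vf = myo_vf_exact(s[M_V], p, E_K);
  double era = dt > 0.0 ? std::exp(-dt / p.tau_rel_act) : 1.0;
  double eri = dt > 0.0 ? std::exp(-dt / p.tau_rel_inact) : 1.0;
  return myo_step(s, p, dt, i_stim_pApF, i_gap_Na, i_gap_K, winf, efac, vf,
                  E_Na, E_K, E_Ca, era, eri, comps);
}

inline void myo_init_state(double* s, const MyoParams& p, double V0,
                           double Nai0, double Ki0, double Cai0, double CaSR0) {
  double winf[MYO_NGATE], tau[MYO_NGATE];
  myo_gate_rates(V0, winf, tau);
  s[M_V] = V0;
  for (int k = 0; k < MYO_NGATE; ++k) s[M_m + k] = winf[k];
  {
    s[M_arel] = 1.0 / (1.0 + std::exp(-(V0 + 9.0) / 5.8));
    double y = Cai0 / p.K_rel_inact, y2 = y * y;
    s[M_irel] = 1.0 / (1.0 + y2 * y2);
  }
  s[M_Nai] = Nai0; s[M_Ki] = Ki0; s[M_Cai] = Cai0; s[M_CaSR] = CaSR0;
}

// ---------------------------------------------------------------------------
// Active atrial fibroblast (MacCannell/Maleckar four-current formulation).
// States: V, r (IKv activation), sgate (IKv inactivation). Fixed [Na+]i, [K+]i.
// ---------------------------------------------------------------------------

enum FibStateIdx { F_V = 0, F_r, F_s, FIB_NSTATE };
constexpr int FIB_NGATE = 2;

struct FibParams {
  double Cm;
  double g_Kv, g_K1, I_NaK_max, g_bNa;
  double k_NaK_K, k_NaK_Na;
  double Na_i, K_i, Na_o, K_o;
};

inline FibParams fib_params_from_list(const Rcpp::List& p) {
  FibParams q;
  q.Cm = p["Cm"]; q.g_Kv = p["g_Kv"]; q.g_K1 = p["g_K1"];
  q.I_NaK_max = p["I_NaK_max"]; q.g_bNa = p["g_bNa"];
  q.k_NaK_K = p["k_NaK_K"]; q.k_NaK_Na = p["k_NaK_Na"];
  q.Na_i = p["Na_i"]; q.K_i = p["K_i"]; q.Na_o = p["Na_o"]; q.K_o = p["K_o"];
  return q;
}

inline void fib_gate_rates(double V, double* winf, double* tau) {
  double e;
  winf[0] = 1.0 / (1.0 + std::exp(-(V + 20.0) / 11.0));
  e = (V + 20.0) / 25.9;
  tau[0] = 20.3 + 138.0 * std::exp(-e * e);
  winf[1] = 1.0 / (1.0 + std::exp((V + 23.0) / 2.7));
  e = (V + 23.0) / 22.7;
  tau[1] = 1574.0 + 5268.0 * std::exp(-e * e);
}

// i_gap_in: total gap current entering the fibroblast (pA, depolarizing > 0).
inline double fib_step(double* s, const FibParams& p, double dt, double i_gap_in,
                       const double* gw_inf, const double* gw_efac) {
  const double V = s[F_V];
  const double E_K  = RTF * std::log(p.K_o / p.K_i);
  const double E_Na = RTF * std::log(p.Na_o / p.Na_i);

  const double I_Kv = p.g_Kv * s[F_r] * s[F_s] * (V - E_K);
  const double I_K1 = p.g_K1 * (V - E_K) /
                      (2.0 + std::exp(1.62 * (V - E_K) / RTF));
  const double na15 = std::pow(p.Na_i, 1.5);
  const double I_NaK = p.I_NaK_max * p.K_o / (p.K_o + p.k_NaK_K) *
                       na15 / (na15 + std::pow(p.k_NaK_Na, 1.5)) *
                       (V + 150.0) / (V + 200.0);
  const double I_bNa = p.g_bNa * (V - E_Na);
  const double I_ion = I_Kv + I_K1 + I_NaK + I_bNa;

  s[F_r] = gw_inf[0] + (s[F_r] - gw_inf[0]) * gw_efac[0];
  s[F_s] = gw_inf[1] + (s[F_s] - gw_inf[1]) * gw_efac[1];
  s[F_V] += dt * (-(I_ion) + i_gap_in) / p.Cm;
  return I_ion;
}

inline void fib_init_state(double* s, double V0) {
  double winf[FIB_NGATE], tau[FIB_NGATE];
  fib_gate_rates(V0, winf, tau);
  s[F_V] = V0; s[F_r] = winf[0]; s[F_s] = winf[1];
}

// ---------------------------------------------------------------------------
// Lookup tables over membrane voltage for the tissue solver.
// ---------------------------------------------------------------------------

// Interleaved per-voltage layout for cache locality: one contiguous block of
// MYO_ROW doubles per grid voltage (gate inf/efac pairs, then the 5 current
// factors); fibroblast tables likewise.
struct GateLUT {
  static constexpr int MYO_ROW = 2 * MYO_NGATE + 5;
  static constexpr int FIB_ROW = 2 * FIB_NGATE;
  double vmin, vmax, inv_dv;
  int n;
  std::vector<double> myo_tab;   // n * MYO_ROW
  std::vector<double> fib_tab;   // n * FIB_ROW
  double e_rel_act, e_rel_inact;

  void build(const MyoParams& mp, double dt, double E_K_ref,
             double v0 = -150.0, double v1 = 150.0, double dv = 0.05) {
    vmin = v0; vmax = v1;
    n = static_cast<int>((v1 - v0) / dv) + 2;
    inv_dv = 1.0 / dv;
    myo_tab.resize(static_cast<size_t>(n) * MYO_ROW);
    fib_tab.resize(static_cast<size_t>(n) * FIB_ROW);
    e_rel_act = std::exp(-dt / mp.tau_rel_act);
    e_rel_inact = std::exp(-dt / mp.tau_rel_inact);
    double winf[MYO_NGATE], tau[MYO_NGATE];
    double fwinf[FIB_NGATE], ftau[FIB_NGATE];
    for (int i = 0; i < n; ++i) {
      double V = v0 + i * dv;
      double* row = &myo_tab[static_cast<size_t>(i) * MYO_ROW];
      myo_gate_rates(V, winf, tau);
      for (int k = 0; k < MYO_NGATE; ++k) {
        row[2 * k] = winf[k];
        row[2 * k + 1] = std::exp(-dt / tau[k]);
      }
      row[2 * MYO_NGATE + 0] = 1.0 / (1.0 + std::exp((V + 55.0) / 24.0));
      row[2 * MYO_NGATE + 1] =
          1.0 / (1.0 + std::exp(1.5 * (V - E_K_ref + 3.6) / RTF));
      row[2 * MYO_NGATE + 2] = std::exp(mp.gamma_NaCa * V / RTF);
      row[2 * MYO_NGATE + 3] = std::exp((mp.gamma_NaCa - 1.0) * V / RTF);
      row[2 * MYO_NGATE + 4] = (V + 150.0) / (V + 200.0);
      double* frow = &fib_tab[static_cast<size_t>(i) * FIB_ROW];
      fib_gate_rates(V, fwinf, ftau);
      for (int k = 0; k < FIB_NGATE; ++k) {
        frow[2 * k] = fwinf[k];
        frow[2 * k + 1] = std::exp(-dt / ftau[k]);
      }
    }
  }

  // interpolate a full myocyte row into winf/efac arrays + current factors
  inline void myo_row(double V, double* winf, double* efac, MyoVF& vf) const {
    double x = (V - vmin) * inv_dv;
    if (!(x > 0.0)) x = 0.0;           // also catches NaN from a blown-up state
    if (x > n - 2) x = n - 2;
    int i = static_cast<int>(x);
    double w = x - i, u = 1.0 - w;
    const double* a = &myo_tab[static_cast<size_t>(i) * MYO_ROW];
    const double* b = a + MYO_ROW;
    for (int k = 0; k < MYO_NGATE; ++k) {
      winf[k] = a[2 * k] * u + b[2 * k] * w;
      efac[k] = a[2 * k + 1] * u + b[2 * k + 1] * w;
    }
    vf.pi_kr   = a[2 * MYO_NGATE + 0] * u + b[2 * MYO_NGATE + 0] * w;
    vf.k1_mult = a[2 * MYO_NGATE + 1] * u + b[2 * MYO_NGATE + 1] * w;
    vf.naca_e1 = a[2 * MYO_NGATE + 2] * u + b[2 * MYO_NGATE + 2] * w;
    vf.naca_e2 = a[2 * MYO_NGATE + 3] * u + b[2 * MYO_NGATE + 3] * w;
    vf.nak_vf  = a[2 * MYO_NGATE + 4] * u + b[2 * MYO_NGATE + 4] * w;
  }
  inline void fib_row(double V, double* winf, double* efac) const {
    double x = (V - vmin) * inv_dv;
    if (!(x > 0.0)) x = 0.0;           // also catches NaN from a blown-up state
    if (x > n - 2) x = n - 2;
    int i = static_cast<int>(x);
    double w = x - i, u = 1.0 - w;
    const double* a = &fib_tab[static_cast<size_t>(i) * FIB_ROW];
    const double* b = a + FIB_ROW;
    for (int k = 0; k < FIB_NGATE; ++k) {
      winf[k] = a[2 * k] * u + b[2 * k] * w;
      efac[k] = a[2 * k + 1] * u + b[2 * k + 1] * w;
    }
  }
};

}  // namespace atriasim

#endif
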