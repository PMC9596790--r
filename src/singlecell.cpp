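#include "model.h"
using namespace Rcpp;
using namespace atriasim;

// Shared stimulus helper: S1 train starting at t = 0.
static inline double stim_at(double t, int n_pulses, double period,
                             double dur, double amp) {
  if (t < 0.0 || n_pulses <= 0) return 0.0;
  int k = static_cast<int>(std::floor(t / period));
  double tp = t - k * period;
  return (k < n_pulses && tp < dur) ? amp : 0.0;
}

static void check_finite_state(const double* s, int n, double t) {
  for (int k = 0; k < n; ++k)
    if (!std::isfinite(s[k]))
      stop("simulation failure: non-finite state variable " + std::to_string(k + 1) + " at t = " + std::to_string(t) + " ms");
}

// [[Rcpp::export]]
NumericVector myo_initial_state_cpp(List params, double V0, double Nai0,
                                    double Ki0, double Cai0, double CaSR0) {
  MyoParams p = myo_params_from_list(params);
  NumericVector s(MYO_NSTATE);
  myo_init_state(REAL(s), p, V0, Nai0, Ki0, Cai0, CaSR0);
  s.attr("names") = CharacterVector::create(
      "V", "m", "h1", "h2", "d", "f1", "f2", "r", "s", "rsus", "ssus", "n",
      "pa", "arel", "irel", "Nai", "Ki", "Cai", "CaSR");
  return s;
}

// Net membrane current (pA) with voltage-gated channels at steady state for V;
// used to balance the resting potential when fixing background conductances.
// [[Rcpp::export]]
double myo_rest_current_cpp(List params, double V, double Nai, double Ki,
                            double Cai, double CaSR) {
  MyoParams p = myo_params_from_list(params);
  double s[MYO_NSTATE];
  myo_init_state(s, p, V, Nai, Ki, Cai, CaSR);
  double tmp[MYO_NSTATE];
  std::copy(s, s + MYO_NSTATE, tmp);
  MyoCurrents c = myo_step_exact(tmp, p, 0.0, 0.0, 0.0, 0.0);
  return c.I_ion;
}

// [[Rcpp::export]]
double fib_rest_current_cpp(List params, double V) {
  FibParams p = fib_params_from_list(params);
  double s[FIB_NSTATE];
  fib_init_state(s, V);
  double winf[FIB_NGATE], tau[FIB_NGATE], efac[FIB_NGATE] = {1.0, 1.0};
  fib_gate_rates(V, winf, tau);
  double tmp[FIB_NSTATE];
  std::copy(s, s + FIB_NSTATE, tmp);
  return fib_step(tmp, p, 0.0, 0.0, winf, efac);
}

// Single myocyte, exact (non-tabulated) gate rates.
// [[Rcpp::export]]
List sim_myocyte_cpp(List params, NumericVector state0, double duration,
                     double dt, int n_pulses, double period, double stim_dur,
                     double stim_amp, double i_gap_na, double i_gap_k,
                     int record_stride) {
  MyoParams p = myo_params_from_list(params);
  if (state0.size() != MYO_NSTATE) stop("state0 must have %d elements", MYO_NSTATE);
  double s[MYO_NSTATE];
  std::copy(state0.begin(), state0.end(), s);

  const int nsteps = static_cast<int>(std::round(duration / dt));
  const int nrec = nsteps / record_stride + 1;
  NumericVector t_out(nrec), v_out(nrec), cai_out(nrec);
  int ir = 0;
  t_out[0] = 0.0; v_out[0] = s[M_V]; cai_out[0] = s[M_Cai]; ir = 1;

  for (int i = 0; i < nsteps; ++i) {
    double t = i * dt;
    double istim = stim_at(t, n_pulses, period, stim_dur, stim_amp);
    myo_step_exact(s, p, dt, istim, i_gap_na, i_gap_k);
    if ((i + 1) % record_stride == 0 && ir < nrec) {
      t_out[ir] = (i + 1) * dt; v_out[ir] = s[M_V]; cai_out[ir] = s[M_Cai];
      ++ir;
    }
    if ((i & 1023) == 0) check_finite_state(s, MYO_NSTATE, t);
  }
  check_finite_state(s, MYO_NSTATE, duration);
  NumericVector sf(MYO_NSTATE);
  std::copy(s, s + MYO_NSTATE, sf.begin());
  return List::create(_["time"] = t_out, _["V"] = v_out, _["Cai"] = cai_out,
                      _["state"] = sf);
}

// One Euler/Rush-Larsen step from an arbitrary state (for convergence checks).
// [[Rcpp::export]]
NumericVector step_myocyte_cpp(List params, NumericVector state0, double dt,
                               double i_stim, double i_gap_na, double i_gap_k) {
  MyoParams p = myo_params_from_list(params);
  double s[MYO_NSTATE];
  std::copy(state0.begin(), state0.end(), s);
  myo_step_exact(s, p, dt, i_stim, i_gap_na, i_gap_k);
  check_finite_state(s, MYO_NSTATE, dt);
  NumericVector out(MYO_NSTATE);
  std::copy(s, s + MYO_NSTATE, out.begin());
  out.attr("names") = state0.attr("names");
  return out;
}

// Single fibroblast with a constant injected gap current (pA).
// [[Rcpp::export]]
List sim_fibroblast_cpp(List params, double V0, double duration, double dt,
                        double i_gap_in, int record_stride) {
  FibParams p = fib_params_from_list(params);
  double s[FIB_NSTATE];
  fib_init_state(s, V0);
  const int nsteps = static_cast<int>(std::round(duration / dt));
  const int nrec = nsteps / record_stride + 1;
  NumericVector t_out(nrec), v_out(nrec);
  double winf[FIB_NGATE], tau[FIB_NGATE], efac[FIB_NGATE];
  int ir = 0;
  t_out[0] = 0.0; v_out[0] = s[F_V]; ir = 1;
  for (int i = 0; i < nsteps; ++i) {
    fib_gate_rates(s[F_V], winf, tau);
    for (int k = 0; k < FIB_NGATE; ++k) efac[k] = std::exp(-dt / tau[k]);
    fib_step(s, p, dt, i_gap_in, winf, efac);
    if ((i + 1) % record_stride == 0 && ir < nrec) {
      t_out[ir] = (i + 1) * dt; v_out[ir] = s[F_V]; ++ir;
    }
    if ((i & 1023) == 0) check_finite_state(s, FIB_NSTATE, i * dt);
  }
  check_finite_state(s, FIB_NSTATE, duration);
  NumericVector sf(FIB_NSTATE);
  std::copy(s, s + FIB_NSTATE, sf.begin());
  return List::create(_["time"] = t_out, _["V"] = v_out, _["state"] = sf);
}

// Myocyte coupled to n_fib identical fibroblasts through species-resolved
// ohmic gap junctions (G in nS per pair). Records both potentials and the
// per-pair gap currents so charge conservation can be asserted externally.
// [[Rcpp::export]]
List sim_pair_cpp(List myo_params, List fib_params, NumericVector state0,
                  double fib_V0, int n_fib, double g_gap_na, double g_gap_k,
                  double duration, double dt, int n_pulses, double period,
                  double stim_dur, double stim_amp, int record_stride) {
  MyoParams mp = myo_params_from_list(myo_params);
  FibParams fp = fib_params_from_list(fib_params);
  double s[MYO_NSTATE];
  std::copy(state0.begin(), state0.end(), s);
  std::vector<double> fs(FIB_NSTATE);
  fib_init_state(fs.data(), fib_V0);  // all fibroblasts identical -> simulate one

  const int nsteps = static_cast<int>(std::round(duration / dt));
  const int nrec = nsteps / record_stride + 1;
  NumericVector t_out(nrec), vm_out(nrec), vf_out(nrec), ina_out(nrec), ik_out(nrec);
  double fwinf[FIB_NGATE], ftau[FIB_NGATE], fefac[FIB_NGATE];
  int ir = 0;
  t_out[0] = 0; vm_out[0] = s[M_V]; vf_out[0] = fs[F_V];
  ina_out[0] = g_gap_na * (s[M_V] - fs[F_V]);
  ik_out[0] = g_gap_k * (s[M_V] - fs[F_V]);
  ir = 1;

  for (int i = 0; i < nsteps; ++i) {
    double t = i * dt;
    double dv = s[M_V] - fs[F_V];
    double i_na = g_gap_na * dv, i_k = g_gap_k * dv;  // per pair, pA
    double istim = stim_at(t, n_pulses, period, stim_dur, stim_amp);

    myo_step_exact(s, mp, dt, istim, n_fib * i_na, n_fib * i_k);

    fib_gate_rates(fs[F_V], fwinf, ftau);
    for (int k = 0; k < FIB_NGATE; ++k) fefac[k] = std::exp(-dt / ftau[k]);
    fib_step(fs.data(), fp, dt, i_na + i_k, fwinf, fefac);

    if ((i + 1) % record_stride == 0 && ir < nrec) {
      t_out[ir] = (i + 1) * dt;
      vm_out[ir] = s[M_V]; vf_out[ir] = fs[F_V];
      double dv2 = s[M_V] - fs[F_V];
      ina_out[ir] = g_gap_na * dv2; ik_out[ir] = g_gap_k * dv2;
      ++ir;
    }
    if ((i & 1023) == 0) {
      check_finite_state(s, MYO_NSTATE, t);
      check_finite_state(fs.data(), FIB_NSTATE, t);
    }
  }
  NumericVector sf(MYO_NSTATE);
  std::copy(s, s + MYO_NSTATE, sf.begin());
  return List::create(_["time"] = t_out, _["V_myocyte"] = vm_out,
                      _["V_fibroblast"] = vf_out, _["I_gap_Na"] = ina_out,
                      _["I_gap_K"] = ik_out, _["state_myocyte"] = sf,
                      _["V_fib_final"] = fs[F_V]);
}

// Individual membrane currents (pA) at the supplied state, gates as given.
// [[Rcpp::export]]
NumericVector myo_currents_cpp(List params, NumericVector state0) {
  MyoParams p = myo_params_from_list(params);
  double s[MYO_NSTATE];
  std::copy(state0.begin(), state0.end(), s);
  double comps[MYO_NCURR];
  double tmp[MYO_NSTATE];
  std::copy(s, s + MYO_NSTATE, tmp);
  MyoCurrents c = myo_step_exact(tmp, p, 0.0, 0.0, 0.0, 0.0, comps);
  NumericVector out(MYO_NCURR + 1);
  std::copy(comps, comps + MYO_NCURR, out.begin());
  out[MYO_NCURR] = c.I_ion;
  out.attr("names") = CharacterVector::create(
      "INa", "ICaL", "It", "IKur", "IKs", "IKr", "IK1", "ISK", "INaK",
      "INaCa", "ICaP", "IbNa", "IbCa", "I_ion");
  return out;
}
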