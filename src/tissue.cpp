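#include "model.h"
using namespace Rcpp;
using namespace atriasim;

// 2D monodomain solver on an nx * ny grid (column-major, ny rows; node index
// iy + ix*ny). Masked nodes are fibroblasts: they do not take part in the
// diffusive term (zero-flux at myocyte/fibroblast faces and at the outer
// boundary) and exchange species-resolved ohmic gap currents with each
// von-Neumann myocyte neighbour. Forward Euler in time, Rush-Larsen gating
// with voltage lookup tables. Per-node, per-beat activation / repolarization
// statistics are extracted online.
//
// [[Rcpp::export]]
List sim_tissue_cpp(int nx, int ny, double dx, LogicalVector mask,
                    List myo_params, List fib_params,
                    NumericVector myo_state0, double fib_V0,
                    double g_gap_na, double g_gap_k,
                    int n_pulses, double period, double stim_dur,
                    double stim_amp, int stim_cols,
                    double dt, int record_stride, IntegerVector probe_idx,
                    double dvdt_min, double v_thresh, double rmp_window,
                    bool pure_diffusion, Nullable<NumericVector> v0_field) {
  const int nnode = nx * ny;
  if (mask.size() != nnode) stop("mask length must be nx*ny");
  MyoParams mp = myo_params_from_list(myo_params);
  FibParams fp = fib_params_from_list(fib_params);

  const double Dh = mp.D / (dx * dx);  // 1/ms
  if (dt * Dh * 4.0 > 1.0)
    stop("explicit diffusion stability violated: dt*4*D/dx^2 = %.3f > 1", dt * Dh * 4.0);

  // flattened neighbour lists (same-type for diffusion, cross-type for gap)
  std::vector<char> isfib(nnode);
  for (int i = 0; i < nnode; ++i) isfib[i] = mask[i] ? 1 : 0;
  std::vector<int> same_off(nnode + 1, 0), cross_off(nnode + 1, 0);
  std::vector<int> same_idx, cross_idx;
  {
    std::vector<std::vector<int> > same(nnode), cross(nnode);
    for (int ix = 0; ix < nx; ++ix) {
      for (int iy = 0; iy < ny; ++iy) {
        int i = iy + ix * ny;
        int nb[4]; int nn = 0;
        if (ix > 0) nb[nn++] = iy + (ix - 1) * ny;
        if (ix < nx - 1) nb[nn++] = iy + (ix + 1) * ny;
        if (iy > 0) nb[nn++] = (iy - 1) + ix * ny;
        if (iy < ny - 1) nb[nn++] = (iy + 1) + ix * ny;
        for (int k = 0; k < nn; ++k) {
          if (isfib[nb[k]] == isfib[i]) same[i].push_back(nb[k]);
          else cross[i].push_back(nb[k]);
        }
      }
    }
    for (int i = 0; i < nnode; ++i) {
      same_off[i + 1] = same_off[i] + same[i].size();
      cross_off[i + 1] = cross_off[i] + cross[i].size();
      same_idx.insert(same_idx.end(), same[i].begin(), same[i].end());
      cross_idx.insert(cross_idx.end(), cross[i].begin(), cross[i].end());
    }
  }

  // state
  std::vector<double> S(static_cast<size_t>(nnode) * MYO_NSTATE);
  for (int i = 0; i < nnode; ++i) {
    double* s = &S[static_cast<size_t>(i) * MYO_NSTATE];
    if (isfib[i]) fib_init_state(s, fib_V0);
    else std::copy(myo_state0.begin(), myo_state0.end(), s);
  }
  if (v0_field.isNotNull()) {
    NumericVector v0(v0_field);
    if (v0.size() != nnode) stop("v0_field length must be nx*ny");
    for (int i = 0; i < nnode; ++i) S[static_cast<size_t>(i) * MYO_NSTATE] = v0[i];
  }

  GateLUT lut;
  const double EK0 = RTF * std::log(mp.K_o / myo_state0[M_Ki]);
  lut.build(mp, dt, EK0);

  // per-node Nernst potentials, refreshed every NERNST_STRIDE steps
  // (intracellular concentrations drift slowly on that timescale)
  const int NERNST_STRIDE = 25;
  std::vector<double> ena(nnode), ekv(nnode), eca(nnode);
  const double EKF = RTF * std::log(fp.K_o / fp.K_i);  // fibroblast (fixed)
  auto refresh_nernst = [&]() {
    for (int i = 0; i < nnode; ++i) {
      if (isfib[i]) { ekv[i] = EKF; continue; }
      const double* s0 = &S[static_cast<size_t>(i) * MYO_NSTATE];
      ena[i] = RTF * std::log(mp.Na_o / s0[M_Nai]);
      ekv[i] = RTF * std::log(mp.K_o / s0[M_Ki]);
      eca[i] = 0.5 * RTF * std::log(mp.Ca_o / s0[M_Cai]);
    }
  };
  refresh_nernst();

  const int nsteps = static_cast<int>(std::round(n_pulses * period / dt));
  const int nprobe = probe_idx.size();
  const int nrec = nsteps / record_stride + 1;
  NumericMatrix probes(nrec, nprobe);
  NumericVector rec_time(nrec);

  // per-beat outputs
  NumericMatrix t_act(nnode, n_pulses), v_max_out(nnode, n_pulses),
      v_rest_out(nnode, n_pulses), t_repol_out(nnode, n_pulses);
  std::fill(t_act.begin(), t_act.end(), NA_REAL);
  std::fill(v_max_out.begin(), v_max_out.end(), NA_REAL);
  std::fill(v_rest_out.begin(), v_rest_out.end(), NA_REAL);
  std::fill(t_repol_out.begin(), t_repol_out.end(), NA_REAL);

  // per-node trackers
  std::vector<double> vold(nnode), diff(nnode, 0.0);
  std::vector<double> dvdtmax(nnode), t_dvdtmax(nnode), vmax(nnode),
      vrest_beat(nnode), premin(nnode), trepol(nnode);
  std::vector<char> phase(nnode), crossed(nnode);
  int beat = 0;
  bool collecting = false;

  double vinit_probe = 0.0;
  for (int i = 0; i < nnode; ++i) {
    double V = S[static_cast<size_t>(i) * MYO_NSTATE];
    dvdtmax[i] = -1e30; t_dvdtmax[i] = NA_REAL; vmax[i] = -1e30;
    vrest_beat[i] = V; premin[i] = V; trepol[i] = NA_REAL;
    phase[i] = 0; crossed[i] = 0;
    (void)vinit_probe;
  }
  for (int pnum = 0; pnum < nprobe; ++pnum)
    probes(0, pnum) = S[static_cast<size_t>(probe_idx[pnum]) * MYO_NSTATE];
  rec_time[0] = 0.0;
  int ir = 1;

  double winf[MYO_NGATE], efac[MYO_NGATE], fwinf[FIB_NGATE], fefac[FIB_NGATE];

  auto finalize_beat = [&](int b) {
    for (int i = 0; i < nnode; ++i) {
      if (isfib[i]) continue;
      v_rest_out(i, b) = vrest_beat[i];
      if (crossed[i] && dvdtmax[i] >= dvdt_min) {
        t_act(i, b) = t_dvdtmax[i];
        v_max_out(i, b) = vmax[i];
        t_repol_out(i, b) = trepol[i];
      }
    }
  };
  auto reset_beat = [&](double new_rest_src_is_premin) {
    for (int i = 0; i < nnode; ++i) {
      vrest_beat[i] = new_rest_src_is_premin ? premin[i]
                                             : S[static_cast<size_t>(i) * MYO_NSTATE];
      dvdtmax[i] = -1e30; t_dvdtmax[i] = NA_REAL; vmax[i] = -1e30;
      trepol[i] = NA_REAL; phase[i] = 0; crossed[i] = 0;
    }
  };

  for (int istep = 0; istep < nsteps; ++istep) {
    double t = istep * dt;

    // beat bookkeeping (shared timing)
    double t_next_beat = (beat + 1) * period;
    if (!collecting && t >= t_next_beat - rmp_window && beat + 1 < n_pulses) {
      collecting = true;
      for (int i = 0; i < nnode; ++i)
        premin[i] = S[static_cast<size_t>(i) * MYO_NSTATE];
    }
    if (t >= t_next_beat - 0.5 * dt && beat + 1 < n_pulses) {
      finalize_beat(beat);
      reset_beat(true);
      collecting = false;
      ++beat;
    }

    bool stim_on = (t - beat * period) < stim_dur && beat < n_pulses;

    if (istep % NERNST_STRIDE == 0) refresh_nernst();

    // pass 1: snapshot V, diffusion from pre-step field
    for (int i = 0; i < nnode; ++i) vold[i] = S[static_cast<size_t>(i) * MYO_NSTATE];
    for (int i = 0; i < nnode; ++i) {
      if (isfib[i]) { diff[i] = 0.0; continue; }
      double acc = 0.0;
      for (int k = same_off[i]; k < same_off[i + 1]; ++k)
        acc += vold[same_idx[k]] - vold[i];
      diff[i] = Dh * acc;
    }

    if (pure_diffusion) {
      for (int i = 0; i < nnode; ++i)
        if (!isfib[i]) S[static_cast<size_t>(i) * MYO_NSTATE] += dt * diff[i];
    } else {
      for (int i = 0; i < nnode; ++i) {
        double* s = &S[static_cast<size_t>(i) * MYO_NSTATE];
        double vo = vold[i];
        if (isfib[i]) {
          double igap_in = 0.0;
          for (int k = cross_off[i]; k < cross_off[i + 1]; ++k)
            igap_in += (g_gap_na + g_gap_k) * (vold[cross_idx[k]] - vo);
          lut.fib_row(vo, fwinf, fefac);
          fib_step(s, fp, dt, igap_in, fwinf, fefac);
        } else {
          double igap_na = 0.0, igap_k = 0.0;
          for (int k = cross_off[i]; k < cross_off[i + 1]; ++k) {
            double dv = vo - vold[cross_idx[k]];
            igap_na += g_gap_na * dv;
            igap_k += g_gap_k * dv;
          }
          double istim = 0.0;
          if (stim_on && (i / ny) < stim_cols) istim = stim_amp;
          MyoVF vf;
          lut.myo_row(vo, winf, efac, vf);
          myo_step(s, mp, dt, istim, igap_na, igap_k, winf, efac, vf,
                   ena[i], ekv[i], eca[i], lut.e_rel_act, lut.e_rel_inact);
          s[M_V] += dt * diff[i];
        }
      }
    }

    double tnew = (istep + 1) * dt;

    // trackers (myocytes)
    if (!pure_diffusion) {
      for (int i = 0; i < nnode; ++i) {
        if (isfib[i]) continue;
        double vn = S[static_cast<size_t>(i) * MYO_NSTATE];
        if (collecting && premin[i] > vn) premin[i] = vn;
        if (phase[i] == 2) continue;
        double dvdt = (vn - vold[i]) / dt;
        if (dvdt > dvdtmax[i]) { dvdtmax[i] = dvdt; t_dvdtmax[i] = tnew; }
        if (vn > v_thresh) crossed[i] = 1;
        if (crossed[i]) {
          if (vn > vmax[i]) vmax[i] = vn;
          if (phase[i] == 0) phase[i] = 1;
          if (phase[i] == 1 && dvdt < 0.0) {
            double v90 = vrest_beat[i] + 0.1 * (vmax[i] - vrest_beat[i]);
            if (vn <= v90) {
              double frac = (vold[i] - v90) / (vold[i] - vn);
              if (frac < 0.0) frac = 0.0;
              if (frac > 1.0) frac = 1.0;
              trepol[i] = t + frac * dt;
              phase[i] = 2;
            }
          }
        }
      }
    }

    if ((istep + 1) % record_stride == 0 && ir < nrec) {
      rec_time[ir] = tnew;
      for (int pnum = 0; pnum < nprobe; ++pnum)
        probes(ir, pnum) = S[static_cast<size_t>(probe_idx[pnum]) * MYO_NSTATE];
      ++ir;
    }

    if ((istep & 2047) == 0) {
      for (int i = 0; i < nnode; ++i)
        if (!std::isfinite(S[static_cast<size_t>(i) * MYO_NSTATE]))
          stop("numerical blow-up: non-finite Vm at t = " + std::to_string(t) + " ms, node " + std::to_string(i + 1));
    }
  }
  finalize_beat(beat);

  for (int i = 0; i < nnode; ++i)
    if (!std::isfinite(S[static_cast<size_t>(i) * MYO_NSTATE]))
      stop("numerical blow-up: non-finite Vm at end of run, node " + std::to_string(i + 1));

  NumericVector v_final(nnode);
  for (int i = 0; i < nnode; ++i) v_final[i] = S[static_cast<size_t>(i) * MYO_NSTATE];

  return List::create(
      _["time"] = rec_time, _["probe_V"] = probes,
      _["t_act"] = t_act, _["v_max"] = v_max_out,
      _["v_rest"] = v_rest_out, _["t_repol"] = t_repol_out,
      _["v_final"] = v_final);
}
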