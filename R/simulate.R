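#' Simulate a single paced myocyte
#'
#' Integrates the atrial myocyte model with forward Euler (concentrations)
#' and Rush-Larsen gating, under an S1 pulse train starting at t = 0.
#'
#' @param params myocyte `cell_parameters` (profile-scaled / drugged as
#'   needed).
#' @param n_pulses,period,stim_dur,stim_amp stimulus train (see
#'   [stimulus_protocol()]); `n_pulses = 0` gives an unstimulated run.
#' @param duration total time (ms); default `n_pulses * period` (or 1000 ms
#'   if unstimulated).
#' @param dt time step (ms).
#' @param state0 initial state; default [myocyte_initial_state()].
#' @param i_gap_na,i_gap_k constant injected gap currents (pA, positive =
#'   leaving the cell).
#' @param record_stride steps between recorded samples.
#' @return `data.frame` with `time`, `V`, `Cai`; final state in attribute
#'   `"state"`.
#' @export
simulate_myocyte <- function(params = myocyte_parameters(), n_pulses = 4,
                             period = 1000, stim_dur = 3, stim_amp = 60.6,
                             duration = NULL, dt = 0.01, state0 = NULL,
                             i_gap_na = 0, i_gap_k = 0, record_stride = 10) {
  if (is.null(duration))
    duration <- if (n_pulses > 0) n_pulses * period else 1000
  if (is.null(state0)) state0 <- myocyte_initial_state(params)
  res <- sim_myocyte_cpp(unclass(params), state0, duration, dt, n_pulses,
                         period, stim_dur, stim_amp, i_gap_na, i_gap_k,
                         record_stride)
  out <- data.frame(time = res$time, V = res$V, Cai = res$Cai)
  st <- res$state
  names(st) <- names(state0)
  attr(out, "state") <- st
  attr(out, "stim_times") <- if (n_pulses > 0) (seq_len(n_pulses) - 1) * period else numeric(0)
  attr(out, "period") <- period
  out
}

#' Advance a myocyte state by one explicit step
#'
#' One forward-Euler / Rush-Larsen step; exposed for convergence and
#' stability checks.
#'
#' @param state named myocyte state vector.
#' @param params myocyte `cell_parameters`.
#' @param dt step (ms).
#' @param i_stim stimulus density (pA/pF).
#' @param i_gap_na,i_gap_k gap currents (pA).
#' @return Updated state vector.
#' @export
step_myocyte <- function(state, params, dt, i_stim = 0,
                         i_gap_na = 0, i_gap_k = 0) {
  stopifnot(dt > 0)
  step_myocyte_cpp(unclass(params), state, dt, i_stim, i_gap_na, i_gap_k)
}

#' Simulate a single fibroblast
#'
#' @param params fibroblast `cell_parameters`.
#' @param V0 initial membrane potential (mV); default the resting -47.75 mV.
#' @param duration total time (ms).
#' @param dt step (ms).
#' @param i_gap_in injected gap current (pA, depolarizing positive).
#' @param record_stride steps between samples.
#' @return `data.frame` with `time`, `V`.
#' @export
simulate_fibroblast <- function(params = fibroblast_parameters(),
                                V0 = fibroblast_resting_potential(),
                                duration = 2000, dt = 0.01, i_gap_in = 0,
                                record_stride = 10) {
  res <- sim_fibroblast_cpp(unclass(params), V0, duration, dt, i_gap_in,
                            record_stride)
  data.frame(time = res$time, V = res$V)
}

#' Simulate a gap-coupled myocyte-fibroblast pair
#'
#' One myocyte coupled to `n_fib` identical fibroblasts through
#' species-resolved ohmic gap junctions. Records both membrane potentials and
#' the per-pair Na+/K+ gap currents (positive = myocyte to fibroblast), so
#' gap charge conservation can be asserted directly.
#'
#' @inheritParams simulate_myocyte
#' @param fib_params fibroblast parameters.
#' @param n_fib number of attached fibroblasts.
#' @param g_gap_na,g_gap_k gap conductance components per pair (nS).
#' @return `data.frame` with `time`, `V_myocyte`, `V_fibroblast`, `I_gap_Na`,
#'   `I_gap_K`.
#' @export
simulate_cell_pair <- function(params = myocyte_parameters(),
                               fib_params = fibroblast_parameters(),
                               n_fib = 1, g_gap_na = 0.25, g_gap_k = 0.25,
                               n_pulses = 0, period = 1000, stim_dur = 3,
                               stim_amp = 60.6, duration = 2000, dt = 0.01,
                               record_stride = 10) {
  res <- sim_pair_cpp(unclass(params), unclass(fib_params),
                      myocyte_initial_state(params),
                      fibroblast_resting_potential(), n_fib, g_gap_na,
                      g_gap_k, duration, dt, n_pulses, period, stim_dur,
                      stim_amp, record_stride)
  data.frame(time = res$time, V_myocyte = res$V_myocyte,
             V_fibroblast = res$V_fibroblast, I_gap_Na = res$I_gap_Na,
             I_gap_K = res$I_gap_K)
}

#' Run a 2D monodomain tissue simulation
#'
#' Integrates every node of the plane (myocyte or fibroblast according to the
#' fibrosis mask) with gap coupling at myocyte-fibroblast adjacencies, the S1
#' protocol applied to the left edge, and online per-node, per-beat
#' activation/repolarization extraction. Fully deterministic given the
#' configuration and mask seed.
#'
#' @param geometry a [tissue_geometry()].
#' @param profile a [profile_scaling()] or `NULL` for baseline.
#' @param drug a [drug_spec()] or `NULL`.
#' @param protocol a [stimulus_protocol()].
#' @param numerics a [numerics_config()].
#' @param g_gap_na,g_gap_k gap conductance components per
#'   myocyte-fibroblast neighbour pair (nS; default split of the fixed 0.5 nS
#'   total).
#' @param base_params baseline myocyte parameters.
#' @param fib_params fibroblast parameters.
#' @param pure_diffusion if `TRUE`, freeze all ionic currents and integrate
#'   diffusion only (conservation checks).
#' @param v0_field optional initial Vm field (`ny x nx` matrix).
#' @return Object of class `simulation_result`: probe traces, per-node
#'   per-beat activation times / peaks / resting potentials / repolarization
#'   times, the final Vm field, and the `conducted` flag.
#' @export
run_simulation <- function(geometry, profile = NULL, drug = NULL,
                           protocol = stimulus_protocol(),
                           numerics = numerics_config(),
                           g_gap_na = 0.25, g_gap_k = 0.25,
                           base_params = myocyte_parameters(),
                           fib_params = fibroblast_parameters(),
                           pure_diffusion = FALSE, v0_field = NULL) {
  params <- base_params
  if (!is.null(profile)) params <- apply_profile_scaling(params, profile)
  params <- apply_drug(params, drug)
  if (numerics$dt * 4 * params$D / geometry$dx^2 > 1)
    stop("dt violates the explicit diffusion stability bound for this D and dx")
  pidx <- c(probe_index(geometry, geometry$probe_left),
            probe_index(geometry, geometry$probe_right))
  raw <- sim_tissue_cpp(
    geometry$nx, geometry$ny, geometry$dx, as.logical(geometry$mask),
    unclass(params), unclass(fib_params), myocyte_initial_state(params),
    fibroblast_resting_potential(), g_gap_na, g_gap_k,
    protocol$n_pulses, protocol$period, protocol$duration,
    protocol$amplitude, protocol$stim_cols,
    numerics$dt, numerics$record_stride, pidx,
    numerics$dvdt_min, numerics$v_thresh, numerics$rmp_window,
    pure_diffusion, v0_field)
  res <- structure(
    list(time = raw$time,
         probe_V = raw$probe_V,
         t_act = raw$t_act, v_max = raw$v_max, v_rest = raw$v_rest,
         t_repol = raw$t_repol, v_final = raw$v_final,
         geometry = geometry, protocol = protocol, numerics = numerics,
         D = params$D, drug = if (is.null(drug)) "none" else drug$name,
         profile = profile),
    class = "simulation_result")
  res$conducted <- if (pure_diffusion) NA else classify_conduction(res)
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result: %d x %d plane, %.1f%% fibrosis, drug = %s, %d beats, conducted = %s>\n",
    x$geometry$nx, x$geometry$ny, 100 * x$geometry$fibrosis_fraction, x$drug,
    x$protocol$n_pulses, x$conducted))
  invisible(x)
}
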