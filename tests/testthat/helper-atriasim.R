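# Shared fixtures. Tissue runs are memoised so different tests in one file can
# reuse the same simulation.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# Coarse-step (10 us) toy-plane run used by direction-of-effect checks.
toy_run <- function(fraction = 0, mask_seed = 1L, drug = NULL, nx = 20, ny = 20,
                    n_pulses = 2, dt_us = 10, D_scale = 0) {
  key <- paste("toy", nx, ny, fraction, mask_seed,
               if (is.null(drug)) "none" else drug$name, n_pulses, dt_us,
               D_scale, sep = "_")
  cached(key, {
    g <- tissue_geometry(nx = nx, ny = ny, fibrosis_fraction = fraction,
                         mask_seed = mask_seed)
    prof <- if (D_scale != 0) profile_scaling(D = D_scale) else NULL
    run_simulation(g, profile = prof, drug = drug,
                   protocol = stimulus_protocol(n_pulses = n_pulses),
                   numerics = numerics_config(dt_us = dt_us))
  })
}

# Paced single-cell trace at the baseline (5 beats, 10 us step).
baseline_paced_trace <- function() {
  cached("paced5", simulate_myocyte(myocyte_parameters(), n_pulses = 5,
                                    dt = 0.01, record_stride = 20,
                                    stim_amp = 30))
}

# Minimal hand-built simulation_result for probe arithmetic tests.
fake_result <- function(t_left, t_right, repol_right = TRUE, nx = 200, ny = 200) {
  g <- tissue_geometry(nx = nx, ny = ny, fibrosis_fraction = 0)
  nnode <- nx * ny
  il <- atriasim:::probe_index(g, g$probe_left) + 1L
  ir <- atriasim:::probe_index(g, g$probe_right) + 1L
  t_act <- matrix(NA_real_, nnode, 2)
  t_repol <- matrix(NA_real_, nnode, 2)
  for (b in 1:2) {
    t_act[il, b] <- t_left + (b - 1) * 1000
    t_act[ir, b] <- t_right + (b - 1) * 1000
    t_repol[il, b] <- t_act[il, b] + 150
    if (repol_right) t_repol[ir, b] <- t_act[ir, b] + 150
  }
  structure(list(geometry = g, t_act = t_act, t_repol = t_repol),
            class = "simulation_result")
}
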