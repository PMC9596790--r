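#' Random diffuse fibrosis mask
#'
#' Draws exactly `round(fraction * nx * ny)` fibroblast nodes uniformly
#' without replacement. Deterministic for a given `(nx, ny, fraction, seed)`;
#' the same mask is intended to be reused across all profiles at a given
#' fibrosis fraction.
#'
#' @param nx,ny grid size (columns along propagation, rows across).
#' @param fraction fibrotic proportion in \[0, 1).
#' @param seed integer RNG seed.
#' @return Logical `ny x nx` matrix, `TRUE` = fibroblast.
#' @export
build_fibrosis_mask <- function(nx, ny, fraction, seed) {
  if (fraction < 0 || fraction >= 1)
    stop("fibrosis fraction must lie in [0, 1)")
  n_fib <- round(fraction * nx * ny)
  mask <- matrix(FALSE, nrow = ny, ncol = nx)
  if (n_fib > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    mask[sample.int(nx * ny, n_fib)] <- TRUE
  }
  mask
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Tissue geometry for the 2D monodomain simulation
#'
#' Defaults give the 200 x 200-node, 2 cm-side plane (node spacing
#' `dx = 0.01` cm). Conduction-velocity probes are placed by proportional
#' mapping of the physical coordinates (0.5 mm, 10 mm) and (19.5 mm, 10 mm)
#' on the 2 cm plane, i.e. at 2.5% and 97.5% of the x-extent, centred in y.
#' If a probe lands on a fibroblast the mask is re-drawn (continuing the
#' seeded stream) until both probes are myocytes.
#'
#' @param nx,ny node counts (default 200 x 200).
#' @param dx node spacing in cm (default 0.01).
#' @param fibrosis_fraction proportion of fibroblast nodes.
#' @param mask_seed seed for the fibrosis mask.
#' @return List of class `tissue_geometry`.
#' @export
tissue_geometry <- function(nx = 200, ny = 200, dx = 0.01,
                            fibrosis_fraction = 0, mask_seed = 1L) {
  stopifnot(nx >= 3, ny >= 1, dx > 0)
  L <- nx * dx
  px_l <- max(1L, min(nx, as.integer(round(0.025 * L / dx))))
  px_r <- max(1L, min(nx, as.integer(round(0.975 * L / dx))))
  py <- max(1L, min(ny, as.integer(ceiling(ny / 2))))
  mask <- build_fibrosis_mask(nx, ny, fibrosis_fraction, mask_seed)
  tries <- 0L
  while ((mask[py, px_l] || mask[py, px_r]) && tries < 100L) {
    tries <- tries + 1L
    mask <- build_fibrosis_mask(nx, ny, fibrosis_fraction,
                                mask_seed + 100003L * tries)
  }
  if (mask[py, px_l] || mask[py, px_r])
    stop("could not place probes on myocyte nodes")
  structure(list(nx = nx, ny = ny, dx = dx,
                 fibrosis_fraction = fibrosis_fraction,
                 mask = mask, mask_seed = mask_seed, mask_redraws = tries,
                 probe_left = c(col = px_l, row = py),
                 probe_right = c(col = px_r, row = py)),
            class = "tissue_geometry")
}

#' @export
print.tissue_geometry <- function(x, ...) {
  cat(sprintf(
    "<tissue_geometry: %d x %d nodes, dx = %g cm (%.2g cm side), %.1f%% fibrosis (%d nodes), probes at columns %d/%d>\n",
    x$nx, x$ny, x$dx, x$nx * x$dx, 100 * x$fibrosis_fraction, sum(x$mask),
    x$probe_left["col"], x$probe_right["col"]))
  invisible(x)
}

## 0-based node index of a (row, col) probe for the C++ solver
probe_index <- function(geometry, probe) {
  (probe[["col"]] - 1L) * geometry$ny + (probe[["row"]] - 1L)
}

#' S1 stimulation protocol
#'
#' A train of identical pulses applied to the myocyte nodes of the left-edge
#' column. The shipped default is 4 pulses of 3 ms at 1 Hz. The default
#' amplitude of 60.6 pA/pF corresponds to a 4000 pA pulse distributed over
#' the 66 pF myocyte membrane; the amplitude is configuration-exposed.
#'
#' @param n_pulses number of S1 pulses.
#' @param amplitude stimulus current density (pA/pF), > 0.
#' @param duration pulse duration (ms), < `period`.
#' @param period cycle length (ms; 1000 = 1 Hz).
#' @param stim_cols number of left-edge columns stimulated.
#' @return List of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(n_pulses = 4, amplitude = 60.6, duration = 3,
                              period = 1000, stim_cols = 3L) {
  stopifnot(n_pulses >= 1, amplitude > 0, duration > 0, duration < period)
  structure(list(n_pulses = as.integer(n_pulses), amplitude = amplitude,
                 duration = duration, period = period,
                 stim_cols = as.integer(stim_cols)),
            class = "stimulus_protocol")
}

#' Numerical configuration for the explicit solver
#'
#' Forward Euler with Rush-Larsen gating. The desk-scale default step is
#' 10 us; the explicit diffusion stability bound `dt <= dx^2 / (4 D)` is
#' checked at simulation start. Activation detection: time of maximum dV/dt
#' within each beat window, requiring an upstroke (`dV/dt > dvdt_min` and a
#' crossing of `v_thresh`) to reject subthreshold humps.
#'
#' @param dt_us time step in microseconds.
#' @param record_stride steps between recorded probe samples.
#' @param dvdt_min minimum upstroke slope (mV/ms).
#' @param v_thresh activation crossing threshold (mV).
#' @param rmp_window diastolic window before each stimulus over which the
#'   per-beat resting potential is taken as the Vm minimum (ms).
#' @return List of class `numerics_config`.
#' @export
numerics_config <- function(dt_us = 5, record_stride = 100, dvdt_min = 1,
                            v_thresh = -20, rmp_window = 100) {
  stopifnot(dt_us > 0, record_stride >= 1)
  structure(list(dt = dt_us / 1000, record_stride = as.integer(record_stride),
                 dvdt_min = dvdt_min, v_thresh = v_thresh,
                 rmp_window = rmp_window),
            class = "numerics_config")
}

#' Discrete heterogeneous-D Laplacian with no-flux boundaries
#'
#' 5-point stencil on myocyte nodes with zero flux at the outer edges and at
#' faces adjoining fibroblast nodes (fibroblasts do not take part in
#' diffusion). For uniform `D` the sum over all myocyte nodes is zero
#' (discrete conservation). Returned in mV/ms.
#'
#' @param vm_field `ny x nx` matrix of membrane potentials (mV).
#' @param geometry a [tissue_geometry()].
#' @param D diffusion coefficient (cm^2/ms).
#' @return `ny x nx` matrix; fibroblast nodes are 0.
#' @export
diffusion_term <- function(vm_field, geometry, D) {
  if (!all(is.finite(vm_field))) stop("non-finite Vm field")
  ny <- geometry$ny; nx <- geometry$nx
  stopifnot(nrow(vm_field) == ny, ncol(vm_field) == nx)
  myo <- !geometry$mask
  acc <- matrix(0, ny, nx)
  shift <- function(dr, dc) {
    vs <- matrix(NA_real_, ny, nx)
    ms <- matrix(FALSE, ny, nx)
    rs <- seq_len(ny) + dr; cs <- seq_len(nx) + dc
    ok_r <- rs >= 1 & rs <= ny; ok_c <- cs >= 1 & cs <= nx
    vs[ok_r, ok_c] <- vm_field[rs[ok_r], cs[ok_c]]
    ms[ok_r, ok_c] <- myo[rs[ok_r], cs[ok_c]]
    list(v = vs, m = ms)
  }
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    s <- shift(d[1], d[2])
    contrib <- ifelse(s$m, s$v - vm_field, 0)
    contrib[is.na(contrib)] <- 0
    acc <- acc + contrib
  }
  out <- (D / geometry$dx^2) * acc
  out[!myo] <- 0
  out
}
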