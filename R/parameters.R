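#' Baseline cell model parameters
#'
#' Load the shipped baseline parameter sets for the human atrial myocyte and
#' the active atrial fibroblast. Values are stored as versioned JSON under
#' `inst/extdata/` and returned as named lists of class `cell_parameters`.
#' Units: conductances nS, pump/exchanger maxima pA, capacitance pF,
#' concentrations mM, volumes L, diffusion `D` cm^2/ms.
#'
#' @return A named list of class `cell_parameters`.
#' @export
myocyte_parameters <- function() {
  p <- jsonlite::read_json(system.file("extdata", "myocyte_baseline.json",
                                       package = "atriasim"),
                           simplifyVector = TRUE)
  structure(p$parameters, class = "cell_parameters",
            cell_type = "myocyte", initial = p$initial)
}

#' @rdname myocyte_parameters
#' @export
fibroblast_parameters <- function() {
  p <- jsonlite::read_json(system.file("extdata", "fibroblast_baseline.json",
                                       package = "atriasim"),
                           simplifyVector = TRUE)
  structure(p$parameters, class = "cell_parameters",
            cell_type = "fibroblast", initial = p$initial)
}

#' @export
print.cell_parameters <- function(x, ...) {
  cat(sprintf("<cell_parameters: %s, %d entries, Cm = %g pF>\n",
              attr(x, "cell_type"), length(x), x$Cm))
  invisible(x)
}

#' Canonical initial state vectors
#'
#' Myocyte state: membrane potential at -79.83 mV, \[K+\]i = 129.43 mM,
#' \[Na+\]i = 8.5547 mM, gates at their steady state for the resting
#' potential. Fibroblast rests at -47.75 mV.
#'
#' @param params parameter list from [myocyte_parameters()].
#' @return Named numeric state vector.
#' @export
myocyte_initial_state <- function(params = myocyte_parameters()) {
  init <- attr(params, "initial")
  if (is.null(init)) init <- attr(myocyte_parameters(), "initial")
  myo_initial_state_cpp(unclass(params), init$V, init$Nai, init$Ki,
                        init$Cai, init$CaSR)
}

#' @rdname myocyte_initial_state
#' @export
fibroblast_resting_potential <- function() -47.75

valid_cell_state <- function(state) {
  gates <- state[c("m", "h1", "h2", "d", "f1", "f2", "r", "s",
                   "rsus", "ssus", "n", "pa", "arel", "irel")]
  all(is.finite(state)) &&
    all(gates >= 0 & gates <= 1) &&
    all(state[c("Nai", "Ki", "Cai", "CaSR")] > 0) &&
    state[["V"]] >= -120 && state[["V"]] <= 80
}

#' Rush-Larsen update for a Hodgkin-Huxley gating variable
#'
#' Exact exponential integrator for `dw/dt = alpha (1 - w) - beta w` with
#' rates frozen over the step `h`: `w' = e^{a h} (w + b/a) - b/a` with
#' `a = -(alpha + beta)`, `b = alpha`. The `alpha = beta = 0` limit is the
#' identity. The result stays in \[0, 1\] whenever `w` does.
#'
#' @param w gating variable(s) in \[0, 1\] (vectorised).
#' @param alpha,beta voltage-dependent rates (1/ms), non-negative.
#' @param h time step (ms), positive.
#' @return Updated gating value(s).
#' @export
rush_larsen_update <- function(w, alpha, beta, h) {
  stopifnot(all(alpha >= 0), all(beta >= 0), all(h > 0))
  a <- -(alpha + beta)
  ifelse(a == 0, w, exp(a * h) * (w + alpha / a) - alpha / a)
}

#' Species-resolved gap-junction current between a myocyte and a fibroblast
#'
#' Na+ and K+ are treated as independent ohmic pathways driven by the
#' transmembrane voltage difference. Sign convention: positive currents leave
#' the myocyte (and enter the fibroblast).
#'
#' @param vm_myocyte,vm_fibroblast membrane potentials (mV).
#' @param g_gap_na,g_gap_k gap conductance components (nS); their default sum
#'   is the fixed total gap conductance of 0.5 nS.
#' @return List with `I_gap_Na`, `I_gap_K` and `I_gap_total` (pA).
#' @export
gap_current <- function(vm_myocyte, vm_fibroblast,
                        g_gap_na = 0.25, g_gap_k = 0.25) {
  if (!all(is.finite(c(vm_myocyte, vm_fibroblast))))
    stop("gap_current: non-finite membrane potential")
  stopifnot(g_gap_na >= 0, g_gap_k >= 0)
  dv <- vm_myocyte - vm_fibroblast
  list(I_gap_Na = g_gap_na * dv, I_gap_K = g_gap_k * dv,
       I_gap_total = (g_gap_na + g_gap_k) * dv)
}

## Names of the nine population-varied parameters (profile CSV header order)
## and their targets in the myocyte parameter list.
profile_parameter_names <- function() {
  c("gNa", "INaK", "gK1", "gCaL", "gKur", "IKCa", "D", "Ko", "Nao")
}

profile_target_map <- c(
  gNa = "g_Na", INaK = "I_NaK_max", gK1 = "g_K1", gCaL = "g_CaL",
  gKur = "g_Kur", IKCa = "g_SK", D = "D", Ko = "K_o", Nao = "Na_o")

#' Construct a profile scaling vector
#'
#' A profile is a set of nine percent-modifiers, relative to the baseline
#' myocyte model, for: `gNa`, `INaK`, `gK1`, `gCaL`, `gKur`, `IKCa`
#' (the Ca2+-activated K+ current), `D` (tissue diffusion), `Ko` and `Nao`
#' (extracellular K+ / Na+). Each entry must lie in \[-50, 100\] percent.
#'
#' @param gNa,INaK,gK1,gCaL,gKur,IKCa,D,Ko,Nao percent modifiers.
#' @return Named numeric vector of class `profile_scaling`.
#' @export
profile_scaling <- function(gNa = 0, INaK = 0, gK1 = 0, gCaL = 0, gKur = 0,
                            IKCa = 0, D = 0, Ko = 0, Nao = 0) {
  x <- c(gNa = gNa, INaK = INaK, gK1 = gK1, gCaL = gCaL, gKur = gKur,
         IKCa = IKCa, D = D, Ko = Ko, Nao = Nao)
  if (any(x < -50 | x > 100))
    stop("profile scalings must lie in [-50, 100] percent")
  structure(x, class = c("profile_scaling", "numeric"))
}

#' Apply a profile scaling to the baseline parameters
#'
#' Each of the nine targeted parameters is multiplied by
#' `(1 + scaling / 100)`; all other parameters are untouched. The pump and
#' Ca2+-activated K+ modifiers (`INaK`, `IKCa`) act multiplicatively on the
#' corresponding current magnitudes.
#'
#' @param base `cell_parameters` for the myocyte.
#' @param scaling named vector of percent modifiers (see [profile_scaling()]);
#'   unknown names are an error.
#' @return Modified `cell_parameters`.
#' @export
apply_profile_scaling <- function(base, scaling) {
  nm <- names(scaling)
  if (is.null(nm) || !all(nm %in% names(profile_target_map)))
    stop("unknown profile parameter(s): ",
         paste(setdiff(nm, names(profile_target_map)), collapse = ", "))
  if (any(scaling < -50 | scaling > 100))
    stop("profile scalings must lie in [-50, 100] percent")
  out <- base
  for (k in nm) {
    tgt <- profile_target_map[[k]]
    out[[tgt]] <- out[[tgt]] * (1 + scaling[[k]] / 100)
  }
  out
}
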