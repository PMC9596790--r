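#' Latin hypercube sample of profile scalings
#'
#' Stratified sampling over the nine varied parameters: for each parameter
#' exactly one sample falls in each of `n` equal-width strata of its range
#' (default -50% to +100% for every parameter). Deterministic under `seed`.
#'
#' @param n number of profiles (>= 1).
#' @param seed integer RNG seed.
#' @param bounds 2 x 9 matrix (or list) of per-parameter `c(min, max)` in
#'   percent; defaults to \[-50, 100\] everywhere. Degenerate bounds
#'   (min = max) give a constant column with a warning.
#' @return `data.frame` with `profile_id` and the nine parameter columns.
#' @export
lhs_profiles <- function(n, seed = 1L, bounds = NULL) {
  stopifnot(n >= 1)
  nm <- profile_parameter_names()
  if (is.null(bounds))
    bounds <- matrix(rep(c(-50, 100), 9), nrow = 2,
                     dimnames = list(c("min", "max"), nm))
  bounds <- as.matrix(bounds)
  stopifnot(ncol(bounds) == 9, nrow(bounds) == 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  u <- lhs::randomLHS(n, 9)
  out <- as.data.frame(lapply(seq_len(9), function(j) {
    lo <- bounds[1, j]; hi <- bounds[2, j]
    if (lo == hi) {
      warning("degenerate bounds for ", nm[j], "; column held constant")
      rep(lo, n)
    } else lo + u[, j] * (hi - lo)
  }))
  names(out) <- nm
  cbind(profile_id = seq_len(n), out)
}

#' Biomarker acceptance ranges for population calibration
#'
#' Inclusive min/max bounds per biomarker (APD90 ms, CV cm/s, RMP mV, peak
#' amplitude mV), shipped as an editable JSON file with defaults from
#' published human atrial ranges.
#'
#' @param file optional path to a custom ranges JSON.
#' @return Named list of `c(min, max)` per biomarker.
#' @export
biomarker_ranges <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "biomarker_ranges.json", package = "atriasim")
  r <- jsonlite::read_json(file, simplifyVector = TRUE)
  for (v in names(r))
    if (r[[v]][1] >= r[[v]][2]) stop("range min must be < max for ", v)
  r
}

#' Default calibration geometry: an 8 x 256-cell strip
#'
#' @param nx,ny strip dimensions (propagation along x).
#' @param dx node spacing (cm).
#' @return A [tissue_geometry()] with 0% fibrosis.
#' @export
calibration_geometry <- function(nx = 256, ny = 8, dx = 0.01) {
  tissue_geometry(nx = nx, ny = ny, dx = dx, fibrosis_fraction = 0)
}

#' Calibrate a candidate population against biomarker ranges
#'
#' Simulates each candidate profile on a fibrosis-free strip under the S1
#' protocol, measures plane-averaged biomarkers over the last two beats, and
#' accepts the profiles whose biomarkers all fall inside the ranges.
#' Candidates whose simulation blows up are rejected with reason
#' `"numerical failure"`. Acceptance is deterministic given the
#' configuration, and monotone in range width.
#'
#' @param candidates `data.frame` from [lhs_profiles()] (or a CSV of
#'   profiles read with [read_profiles()]).
#' @param ranges list from [biomarker_ranges()].
#' @param geometry calibration geometry; default [calibration_geometry()].
#' @param protocol,numerics simulation configuration.
#' @param verbose print progress.
#' @return `data.frame`: the candidate columns plus measured biomarkers,
#'   `accepted` flag and `reason` for rejections (provenance per candidate).
#' @export
calibrate_population <- function(candidates, ranges = biomarker_ranges(),
                                 geometry = calibration_geometry(),
                                 protocol = stimulus_protocol(),
                                 numerics = numerics_config(),
                                 verbose = FALSE) {
  base <- myocyte_parameters()
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    prof <- as.numeric(candidates[i, profile_parameter_names()])
    names(prof) <- profile_parameter_names()
    bm <- tryCatch({
      res <- run_simulation(geometry, profile = prof, protocol = protocol,
                            numerics = numerics, base_params = base)
      tissue_biomarkers(res)
    }, error = function(e) e)
    if (inherits(bm, "error")) {
      out <- data.frame(apd90 = NA_real_, cv = NA_real_, rmp = NA_real_,
                        peak = NA_real_, conducted = FALSE,
                        accepted = FALSE, reason = "numerical failure")
    } else {
      checks <- c(
        apd90 = is.finite(bm$apd90) && bm$apd90 >= ranges$apd90[1] && bm$apd90 <= ranges$apd90[2],
        cv = is.finite(bm$cv) && bm$cv >= ranges$cv[1] && bm$cv <= ranges$cv[2],
        rmp = is.finite(bm$rmp) && bm$rmp >= ranges$rmp[1] && bm$rmp <= ranges$rmp[2],
        peak = is.finite(bm$peak) && bm$peak >= ranges$peak[1] && bm$peak <= ranges$peak[2])
      ok <- bm$conducted && all(checks)
      reason <- if (ok) "" else if (!bm$conducted) "no conduction" else
        paste(names(checks)[!checks], "out of range", collapse = "; ")
      out <- data.frame(apd90 = bm$apd90, cv = bm$cv, rmp = bm$rmp,
                        peak = bm$peak, conducted = bm$conducted,
                        accepted = ok, reason = reason)
    }
    if (verbose)
      message(sprintf("candidate %d/%d: %s", i, nrow(candidates),
                      if (out$accepted) "accepted" else out$reason))
    cbind(candidates[i, , drop = FALSE], out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write profile tables
#'
#' CSV interchange format: header row naming the nine parameters exactly
#' (`gNa, INaK, gK1, gCaL, gKur, IKCa, D, Ko, Nao`) plus `profile_id` and,
#' for calibrated tables, the `accepted` flag and biomarker columns.
#'
#' @param path CSV file path.
#' @param profiles `data.frame` of profiles.
#' @return `read_profiles` returns the validated `data.frame`.
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(profile_parameter_names(), names(df))
  if (length(miss) > 0)
    stop("profile CSV is missing columns: ", paste(miss, collapse = ", "))
  rng <- df[, profile_parameter_names()]
  if (any(rng < -50 | rng > 100))
    stop("profile scalings outside [-50, 100] percent")
  df
}

#' @rdname read_profiles
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE)
  invisible(path)
}
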