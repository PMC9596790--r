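#' Run the (profile x fibrosis x drug) simulation matrix
#'
#' Simulates every combination of the supplied profiles, fibrosis fractions
#' and drug conditions on planes of the given size. One fibrosis mask is
#' drawn per fraction (seeded) and reused across all profiles and drugs at
#' that fraction, matching the study design. Returns the flat biomarker
#' table consumed by [assemble_features()] and [summarize_condition()].
#'
#' @param profiles `data.frame` with `profile_id` and the nine parameter
#'   columns (e.g. the accepted rows from [calibrate_population()]).
#' @param fibrosis_levels fibrosis fractions (default 0, 0.05, 0.10).
#' @param drugs drug names (default none + the three shipped drugs).
#' @param nx,ny plane size in nodes.
#' @param mask_seed base seed; the mask for fraction `f` uses
#'   `mask_seed + round(1000 f)`.
#' @param protocol,numerics simulation configuration.
#' @param verbose print progress.
#' @return `data.frame` with one row per run: `profile_id`, `fibrosis`
#'   (percent), `drug`, biomarkers, `conducted`, `mask_seed`.
#' @export
run_study <- function(profiles, fibrosis_levels = c(0, 0.05, 0.10),
                      drugs = c("none", "amiodarone", "dofetilide", "sotalol"),
                      nx = 200, ny = 200, mask_seed = 1L,
                      protocol = stimulus_protocol(),
                      numerics = numerics_config(), verbose = FALSE) {
  geoms <- lapply(fibrosis_levels, function(f)
    tissue_geometry(nx = nx, ny = ny, fibrosis_fraction = f,
                    mask_seed = mask_seed + as.integer(round(1000 * f))))
  rows <- list()
  for (gi in seq_along(fibrosis_levels)) {
    for (dg in drugs) {
      drug <- drug_spec(dg)
      for (pi in seq_len(nrow(profiles))) {
        prof <- as.numeric(profiles[pi, profile_parameter_names()])
        names(prof) <- profile_parameter_names()
        bm <- tryCatch({
          res <- run_simulation(geoms[[gi]], profile = prof, drug = drug,
                                protocol = protocol, numerics = numerics)
          tissue_biomarkers(res)
        }, error = function(e) {
          data.frame(apd90 = NA_real_, cv = NA_real_, rmp = NA_real_,
                     peak = NA_real_, v_max_abs = NA_real_,
                     conducted = FALSE, n_beats_used = NA_integer_,
                     n_myocytes = NA_integer_)
        })
        rows[[length(rows) + 1]] <- cbind(
          data.frame(profile_id = profiles$profile_id[pi],
                     fibrosis = 100 * fibrosis_levels[gi], drug = dg),
          bm,
          data.frame(mask_seed = geoms[[gi]]$mask_seed))
        if (verbose)
          message(sprintf("fibrosis %g%% drug %-10s profile %s: conducted = %s",
                          100 * fibrosis_levels[gi], dg,
                          profiles$profile_id[pi],
                          rows[[length(rows)]]$conducted))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate drug-induced biomarker deltas per fibrosis level
#'
#' For each (fibrosis, drug) condition, computes per-profile deltas against
#' the no-drug run at the same fibrosis level, restricted to profiles
#' conducting in both conditions.
#'
#' @param study_table output of [run_study()].
#' @return `data.frame` with one row per (fibrosis, drug): conducting
#'   counts, counts of CV increase/decrease, and mean/SD of each delta.
#' @export
delta_table <- function(study_table) {
  drugs <- setdiff(unique(study_table$drug), "none")
  out <- list()
  for (f in unique(study_table$fibrosis)) {
    basal <- study_table[study_table$fibrosis == f & study_table$drug == "none", ]
    for (dg in drugs) {
      trt <- study_table[study_table$fibrosis == f & study_table$drug == dg, ]
      idx <- match(trt$profile_id, basal$profile_id)
      deltas <- t(vapply(seq_len(nrow(trt)), function(i) {
        b <- basal[idx[i], ]; d <- trt[i, ]
        biomarker_delta(d, b)
      }, numeric(4)))
      ok <- is.finite(deltas[, "dCV"])
      out[[length(out) + 1]] <- data.frame(
        fibrosis = f, drug = dg,
        n_both_conducting = sum(ok),
        n_cv_increase = sum(deltas[ok, "dCV"] > 0),
        n_cv_decrease = sum(deltas[ok, "dCV"] < 0),
        dCV_mean = if (any(ok)) mean(deltas[ok, "dCV"]) else NA_real_,
        dCV_sd = if (sum(ok) > 1) sd(deltas[ok, "dCV"]) else NA_real_,
        dAPD90_mean = if (any(ok)) mean(deltas[ok, "dAPD90"]) else NA_real_,
        dRMP_mean = if (any(ok)) mean(deltas[ok, "dRMP"]) else NA_real_,
        dPeak_mean = if (any(ok)) mean(deltas[ok, "dPeak"]) else NA_real_)
    }
  }
  do.call(rbind, out)
}
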