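## Per-beat AP statistics from a uniformly sampled Vm trace.
## Activation = time of maximum dV/dt within the beat window, accepted only if
## the upstroke exceeds `dvdt_min` and Vm crosses `v_thresh`; APD90 runs from
## activation to the downward crossing of RMP + 0.1 * (peak - RMP), linearly
## interpolated between samples.
trace_beat_stats <- function(time, V, win_start, win_end, pre_start,
                             dvdt_min = 1, v_thresh = -20) {
  # centred ~1 ms moving average for the noise-sensitive parts (diastolic
  # minimum and the 90%-repolarization crossing); raw samples keep the peak
  # and upstroke sharp
  dts <- stats::median(diff(time))
  w <- max(1L, round(1 / dts))
  if (w %% 2 == 0) w <- w + 1L
  Vs <- if (w > 1) {
    f <- as.numeric(stats::filter(V, rep(1 / w, w), sides = 2))
    f[is.na(f)] <- V[is.na(f)]
    f
  } else V
  pre <- time >= pre_start & time <= win_start + 1e-9
  win <- time >= win_start - 1e-9 & time <= win_end + 1e-9
  rmp <- if (any(pre)) min(Vs[pre]) else Vs[which(win)[1]]
  ti <- time[win]; vi <- V[win]; vsi <- Vs[win]
  if (length(ti) < 3)
    return(list(t_act = NA_real_, apd90 = NA_real_, rmp = rmp,
                peak = NA_real_, amplitude = NA_real_))
  dvdt <- diff(vi) / diff(ti)
  imax <- which.max(dvdt)
  no_ap <- max(dvdt) < dvdt_min || max(vi) < v_thresh
  if (no_ap)
    return(list(t_act = NA_real_, apd90 = NA_real_, rmp = rmp,
                peak = NA_real_, amplitude = NA_real_))
  t_act <- ti[imax + 1]
  ipk <- which.max(vi[seq(imax, length(vi))]) + imax - 1
  peak <- vi[ipk]
  v90 <- rmp + 0.1 * (peak - rmp)
  below <- which(vsi[seq(ipk, length(vsi))] <= v90)
  if (length(below) == 0)
    return(list(t_act = t_act, apd90 = NA_real_, rmp = rmp, peak = peak,
                amplitude = peak - rmp))
  j <- below[1] + ipk - 1      # first smoothed sample at/below v90 after peak
  if (j == 1) j <- 2
  den <- vsi[j - 1] - vsi[j]
  frac <- if (den > 0) (vsi[j - 1] - v90) / den else 0.5
  frac <- min(max(frac, 0), 1)
  t_repol <- ti[j - 1] + frac * (ti[j] - ti[j - 1])
  list(t_act = t_act, apd90 = t_repol - t_act, rmp = rmp, peak = peak,
       amplitude = peak - rmp)
}

beat_windows_for <- function(trace, beat_starts, period) {
  if (is.null(beat_starts)) beat_starts <- attr(trace, "stim_times")
  if (is.null(period)) period <- attr(trace, "period")
  if (is.null(beat_starts) || length(beat_starts) == 0) beat_starts <- 0
  if (is.null(period)) period <- max(trace$time) - beat_starts[length(beat_starts)]
  list(starts = beat_starts, period = period)
}

#' Action potential duration at 90% repolarization
#'
#' Per beat: time from activation (maximum dV/dt) to the downward crossing of
#' `RMP + 0.1 * (peak - RMP)`, with linear interpolation between samples.
#' Beats without a detected upstroke yield `NA` (feeding the conduction-block
#' logic).
#'
#' @param trace `data.frame` with `time` (ms) and `V` (mV), uniformly
#'   sampled; typically from [simulate_myocyte()] or [synthetic_ap_trace()].
#' @param beat_starts beat window onsets (ms); defaults to the stimulus times
#'   stored on the trace, else a single window.
#' @param period beat window length (ms).
#' @param dvdt_min,v_thresh upstroke acceptance thresholds.
#' @return Numeric vector, one APD90 (ms) per beat.
#' @export
apd90 <- function(trace, beat_starts = NULL, period = NULL,
                  dvdt_min = 1, v_thresh = -20) {
  ap_biomarkers(trace, beat_starts, period, dvdt_min, v_thresh)$apd90
}

#' Per-beat AP biomarkers from a sampled trace
#'
#' @inheritParams apd90
#' @return `data.frame` with one row per beat: `t_act`, `apd90`, `rmp`,
#'   `peak` (absolute mV) and `amplitude` (peak - RMP, mV).
#' @export
ap_biomarkers <- function(trace, beat_starts = NULL, period = NULL,
                          dvdt_min = 1, v_thresh = -20) {
  w <- beat_windows_for(trace, beat_starts, period)
  rows <- lapply(seq_along(w$starts), function(k) {
    s <- w$starts[k]
    pre <- if (k == 1) min(trace$time) else s - 100
    st <- trace_beat_stats(trace$time, trace$V, s, s + w$period, pre,
                           dvdt_min, v_thresh)
    as.data.frame(st)
  })
  do.call(rbind, rows)
}

#' Conduction velocity from the probe activation times
#'
#' Probe distance divided by the activation-time difference, averaged over
#' the last two beats; `NA` when the run did not conduct.
#'
#' @param result a `simulation_result`.
#' @return CV in cm/s, or `NA` if non-conducting.
#' @export
conduction_velocity <- function(result) {
  g <- result$geometry
  if (!isTRUE(classify_conduction(result))) return(NA_real_)
  il <- probe_index(g, g$probe_left) + 1L
  ir <- probe_index(g, g$probe_right) + 1L
  nb <- ncol(result$t_act)
  beats <- unique(pmax(1L, c(nb - 1L, nb)))
  dist_cm <- (g$probe_right[["col"]] - g$probe_left[["col"]]) * g$dx
  cvs <- vapply(beats, function(b) {
    tl <- result$t_act[il, b]; tr <- result$t_act[ir, b]
    if (!is.finite(tl) || !is.finite(tr)) return(NA_real_)
    if (tr <= tl)
      stop("right probe activated before left probe in a conducting run")
    1000 * dist_cm / (tr - tl)
  }, numeric(1))
  if (all(is.na(cvs))) NA_real_ else mean(cvs, na.rm = TRUE)
}

#' Classify conduction versus block
#'
#' `TRUE` iff, after the final stimulus, the right-probe cell both
#' depolarizes (an accepted upstroke) and repolarizes (returns below
#' RMP + 10% of the AP amplitude before the record ends). Failure to be
#' stimulated, to conduct, or to repolarize all yield `FALSE`.
#'
#' @param result a `simulation_result`.
#' @return Logical.
#' @export
classify_conduction <- function(result) {
  g <- result$geometry
  ir <- probe_index(g, g$probe_right) + 1L
  b <- ncol(result$t_act)
  is.finite(result$t_act[ir, b]) && is.finite(result$t_repol[ir, b])
}

#' Plane-averaged biomarkers for one tissue run
#'
#' APD90, RMP and peak are averaged over myocyte nodes (fibroblasts carry no
#' AP) and over the last two beats; CV comes from the probe pair. Peak is
#' reported as the AP amplitude (Vmax - RMP); the absolute maximum is also
#' returned.
#'
#' @param result a `simulation_result`.
#' @return One-row `data.frame`: `apd90`, `cv`, `rmp`, `peak`, `v_max_abs`,
#'   `conducted`, `n_beats_used`, `n_myocytes`.
#' @export
tissue_biomarkers <- function(result) {
  g <- result$geometry
  myo <- !as.logical(g$mask)
  nb <- ncol(result$t_act)
  beats <- unique(pmax(1L, c(nb - 1L, nb)))
  per_beat <- lapply(beats, function(b) {
    ta <- result$t_act[myo, b]; tr <- result$t_repol[myo, b]
    vmax <- result$v_max[myo, b]; vrest <- result$v_rest[myo, b]
    ok <- is.finite(ta) & is.finite(tr)
    c(apd90 = if (any(ok)) mean(tr[ok] - ta[ok]) else NA_real_,
      rmp = mean(vrest[is.finite(vrest)]),
      peak = if (any(is.finite(vmax))) {
        okp <- is.finite(vmax) & is.finite(vrest)
        mean(vmax[okp] - vrest[okp])
      } else NA_real_,
      v_max_abs = if (any(is.finite(vmax))) mean(vmax[is.finite(vmax)]) else NA_real_)
  })
  m <- colMeans(do.call(rbind, per_beat), na.rm = TRUE)
  conducted <- classify_conduction(result)
  data.frame(apd90 = unname(m["apd90"]),
             cv = if (conducted) conduction_velocity(result) else NA_real_,
             rmp = unname(m["rmp"]), peak = unname(m["peak"]),
             v_max_abs = unname(m["v_max_abs"]),
             conducted = conducted, n_beats_used = length(beats),
             n_myocytes = sum(myo))
}

#' Drug-induced biomarker differences
#'
#' `Delta biomarker = biomarker(drug) - biomarker(basal)`, defined only when
#' both conditions conduct; otherwise all components are `NA` (such profiles
#' are excluded from delta summaries, shrinking the denominators).
#'
#' @param drug_set,basal_set one-row `data.frame`s from
#'   [tissue_biomarkers()].
#' @return Named numeric vector `dCV`, `dAPD90`, `dRMP`, `dPeak`.
#' @export
biomarker_delta <- function(drug_set, basal_set) {
  if (!isTRUE(drug_set$conducted) || !isTRUE(basal_set$conducted))
    return(c(dCV = NA_real_, dAPD90 = NA_real_, dRMP = NA_real_,
             dPeak = NA_real_))
  c(dCV = drug_set$cv - basal_set$cv,
    dAPD90 = drug_set$apd90 - basal_set$apd90,
    dRMP = drug_set$rmp - basal_set$rmp,
    dPeak = drug_set$peak - basal_set$peak)
}

#' Group summary of biomarkers across profiles
#'
#' Mean and SD per biomarker across conducting profiles, plus conducting
#' counts.
#'
#' @param biomarker_table `data.frame` with one row per profile (columns
#'   `apd90`, `cv`, `rmp`, `peak`, `conducted`).
#' @return List with `n`, `n_conducting` and a `data.frame` of mean/sd per
#'   biomarker.
#' @export
summarize_condition <- function(biomarker_table) {
  cond <- biomarker_table[isTRUE_vec(biomarker_table$conducted), , drop = FALSE]
  vars <- intersect(c("apd90", "cv", "rmp", "peak"), names(biomarker_table))
  stats_df <- if (nrow(cond) > 0) {
    do.call(rbind, lapply(vars, function(v) {
      x <- cond[[v]][is.finite(cond[[v]])]
      data.frame(biomarker = v, mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
                 n = length(x))
    }))
  } else data.frame(biomarker = character(), mean = numeric(),
                    sd = numeric(), n = integer())
  list(n = nrow(biomarker_table), n_conducting = nrow(cond), stats = stats_df)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Group comparison tests for biomarker tables
#'
#' Reporting utility: two-sided t-test (two groups), one-way ANOVA and
#' Kruskal-Wallis for continuous biomarkers; chi-square for conduction
#' proportions. Groups with fewer than 2 observations are flagged rather
#' than tested.
#'
#' @param x numeric biomarker values, or logical/0-1 conduction flags when
#'   `binary = TRUE`.
#' @param group grouping factor (>= 2 levels).
#' @param binary treat `x` as a binary outcome.
#' @param paired paired t-test (two equally sized groups only).
#' @return List of p-values and flags; significance threshold p < 0.05.
#' @export
group_tests <- function(x, group, binary = FALSE, paired = FALSE) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (binary) {
    tab <- table(group, factor(x, levels = c(FALSE, TRUE)))
    ct <- suppressWarnings(chisq.test(tab))
    return(list(test = "chi-square", p = ct$p.value,
                table = tab, significant = ct$p.value < 0.05))
  }
  sizes <- table(group)
  out <- list(test = "location", group_sizes = as.vector(sizes))
  if (any(sizes < 2)) {
    out$flag <- "group with fewer than 2 observations; variance-based tests not computed"
    return(out)
  }
  out$anova_p <- summary(aov(x ~ group))[[1]][["Pr(>F)"]][1]
  out$kruskal_p <- kruskal.test(x, group)$p.value
  if (nlevels(group) == 2) {
    g1 <- x[group == levels(group)[1]]
    g2 <- x[group == levels(group)[2]]
    out$t_p <- t.test(g1, g2, paired = paired)$p.value
  }
  out$significant <- min(out$anova_p, out$kruskal_p) < 0.05
  out
}
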