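#' Synthetic action-potential trace with planted biomarkers
#'
#' Piecewise-smooth AP-like waveform whose analytic APD90, RMP and amplitude
#' equal the planted values: a half-cosine upstroke (maximum dV/dt at its
#' midpoint, which defines the activation time) followed by a linear
#' repolarization whose crossing of RMP + 0.1 x amplitude falls exactly
#' APD90 after activation. Optional seeded Gaussian noise.
#'
#' @param apd90 planted APD90 (ms).
#' @param rmp resting potential (mV).
#' @param amplitude AP amplitude above RMP (mV), > 0.
#' @param upstroke upstroke duration (ms).
#' @param period beat period (ms), > APD90.
#' @param n_beats number of beats.
#' @param dt sampling interval (ms).
#' @param noise_sd additive Gaussian noise SD (mV), >= 0.
#' @param seed RNG seed for the noise.
#' @return `data.frame` with `time`, `V`; planted truth in attribute
#'   `"truth"`, beat onsets in `"stim_times"`.
#' @export
synthetic_ap_trace <- function(apd90 = 150, rmp = -80, amplitude = 100,
                               upstroke = 1, period = 1000, n_beats = 1,
                               dt = 0.1, noise_sd = 0, seed = 1L) {
  stopifnot(apd90 < period, amplitude > 0, noise_sd >= 0, upstroke > 0)
  t0 <- 5                         # quiescent lead-in within each beat
  t_lin <- (apd90 - upstroke / 2) / 0.9   # linear decay span, peak -> RMP
  beat_v <- function(tb) {
    v <- rep(rmp, length(tb))
    up <- tb >= t0 & tb < t0 + upstroke
    v[up] <- rmp + amplitude * 0.5 * (1 - cos(pi * (tb[up] - t0) / upstroke))
    rep_ph <- tb >= t0 + upstroke & tb < t0 + upstroke + t_lin
    v[rep_ph] <- rmp + amplitude * (1 - (tb[rep_ph] - t0 - upstroke) / t_lin)
    v
  }
  time <- seq(0, n_beats * period - dt, by = dt)
  V <- beat_v(time %% period)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    V <- V + rnorm(length(V), 0, noise_sd)
  }
  out <- data.frame(time = time, V = V)
  attr(out, "stim_times") <- (seq_len(n_beats) - 1) * period
  attr(out, "period") <- period
  attr(out, "truth") <- list(apd90 = apd90, rmp = rmp, amplitude = amplitude,
                             t_act = t0 + upstroke / 2)
  out
}

#' Surrogate feature table with a known decision rule
#'
#' Feature rows with the study's exact schema (nine profile modifiers, three
#' drug factors, fibrosis percentage, label). Labels follow a known rule -
#' conduction iff the effective sodium availability
#' `(1 + gNa/100) * f_INa` exceeds a threshold - with a stated flip rate, so
#' the Bayes accuracy `1 - noise_rate` is known analytically. Rows inside
#' the exclusion margin around the boundary are resampled, keeping the
#' classes separable up to the label noise.
#'
#' @param n number of rows (>= 10).
#' @param noise_rate label flip probability in \[0, 0.5).
#' @param seed RNG seed.
#' @param rule labeling rule family: `"na_availability"` (default, block iff
#'   `(1 + gNa/100) * f_INa` is below the threshold) or `"gna"` (block iff
#'   the `gNa` modifier alone is below the threshold; planted single-feature
#'   signal for importance-recovery tests).
#' @param threshold decision threshold on the rule's score (defaults: 0.55
#'   for `"na_availability"`, 25 for `"gna"`).
#' @param margin half-width of the excluded boundary band, in score units
#'   (default 0.2 / 15 by rule).
#' @return Feature `data.frame` with `label`; attributes `"bayes_accuracy"`
#'   and `"rule"`.
#' @export
surrogate_ml_dataset <- function(n, noise_rate = 0, seed = 1L,
                                 rule = c("na_availability", "gna"),
                                 threshold = NULL, margin = NULL) {
  stopifnot(n >= 10, noise_rate >= 0, noise_rate < 0.5)
  rule <- match.arg(rule)
  if (is.null(threshold)) threshold <- if (rule == "gna") 25 else 0.55
  if (is.null(margin)) margin <- if (rule == "gna") 15 else 0.2
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  drugs <- c("none", "amiodarone", "dofetilide", "sotalol")
  fac <- vapply(drugs, function(d) drug_factors(drug_spec(d)), numeric(3))
  draw <- function(m) {
    p <- matrix(runif(m * 9, -50, 100), ncol = 9,
                dimnames = list(NULL, profile_parameter_names()))
    dr <- sample(drugs, m, replace = TRUE)
    data.frame(p, f_IKr = fac["IKr", dr], f_ICaL = fac["ICaL", dr],
               f_INa = fac["INa", dr],
               fibrosis = sample(c(0, 5, 10), m, replace = TRUE))
  }
  score_of <- function(df)
    if (rule == "gna") df$gNa else (1 + df$gNa / 100) * df$f_INa
  out <- draw(n)
  score <- score_of(out)
  for (it in 1:100) {
    bad <- abs(score - threshold) < margin
    if (!any(bad)) break
    out[bad, ] <- draw(sum(bad))
    score <- score_of(out)
  }
  lab <- score > threshold
  if (noise_rate > 0) {
    flip <- runif(n) < noise_rate
    lab <- xor(lab, flip)
  }
  out$label <- factor(ifelse(lab, "conduct", "block"),
                      levels = c("block", "conduct"))
  rownames(out) <- NULL
  attr(out, "bayes_accuracy") <- 1 - noise_rate
  attr(out, "rule") <- if (rule == "gna")
    sprintf("gNa > %g", threshold)
  else sprintf("(1 + gNa/100) * f_INa > %g", threshold)
  out
}

#' Ready-to-run toy tissue bundle
#'
#' A small plane with probes rescaled proportionally to the 2.5% / 97.5%
#' x-extent convention (centred in y), a two-pulse S1 protocol and
#' desk-scale numerics. Used by the solver tests and examples.
#'
#' @param nx,ny plane size (>= 10).
#' @param fraction fibrosis fraction.
#' @param seed mask seed.
#' @param n_pulses S1 pulses.
#' @return List with `geometry`, `protocol`, `numerics`.
#' @export
toy_plane <- function(nx = 20, ny = 20, fraction = 0, seed = 1L,
                      n_pulses = 2) {
  stopifnot(nx >= 10, ny >= 10)
  list(geometry = tissue_geometry(nx = nx, ny = ny, dx = 0.01,
                                  fibrosis_fraction = fraction,
                                  mask_seed = seed),
       protocol = stimulus_protocol(n_pulses = n_pulses),
       numerics = numerics_config())
}
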