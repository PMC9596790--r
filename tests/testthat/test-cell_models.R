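test_that("Rush-Larsen update is exact for constant rates and bounded", {
  # alpha = beta = 0 is the identity
  expect_equal(rush_larsen_update(0.3, 0, 0, 1), 0.3)
  # long-step limit is the steady state alpha/(alpha+beta)
  expect_equal(rush_larsen_update(0.9, 1, 3, 1e6), 0.25, tolerance = 1e-12)
  expect_equal(rush_larsen_update(0.0, 1, 3, 1e6), 0.25, tolerance = 1e-12)
  # exact solution of dw/dt = a(1-w) - b w over one step
  w0 <- 0.2; a <- 1; b <- 3; h <- 0.5
  winf <- a / (a + b)
  exact <- winf + (w0 - winf) * exp(-(a + b) * h)
  expect_equal(rush_larsen_update(w0, a, b, h), exact, tolerance = 1e-14)
  # matches forward Euler at tiny h
  h <- 1e-4
  euler <- w0 + h * (a * (1 - w0) - b * w0)
  expect_equal(rush_larsen_update(w0, a, b, h), euler, tolerance = 1e-7)
})

test_that("gating stays in [0, 1] for random rate schedules", {
  set.seed(11)
  for (rep in 1:20) {
    w <- runif(1)
    for (i in 1:200) {
      w <- rush_larsen_update(w, runif(1, 0, 50), runif(1, 0, 50),
                              runif(1, 1e-4, 5))
      expect_gte(w, 0)
      expect_lte(w, 1)
    }
  }
})

test_that("gap current is species-resolved, ohmic, and zero at equal potentials", {
  z <- gap_current(-60, -60)
  expect_equal(z$I_gap_Na, 0)
  expect_equal(z$I_gap_K, 0)
  g <- gap_current(50, -50, g_gap_na = 0.25, g_gap_k = 0.25)
  expect_equal(g$I_gap_total, 50)          # 0.5 nS * 100 mV
  expect_equal(g$I_gap_Na, 25)
  expect_equal(g$I_gap_K, 25)
  # linear in the voltage difference
  expect_equal(gap_current(0, -10)$I_gap_total,
               gap_current(10, 0)$I_gap_total)
  expect_error(gap_current(NaN, -50), "non-finite")
})

test_that("gap coupling conserves charge and depolarizes the fibroblast", {
  tr <- simulate_cell_pair(n_fib = 1, n_pulses = 1, duration = 600,
                           stim_amp = 30, record_stride = 50)
  # recorded currents equal the ohmic law at every sample (charge leaving the
  # myocyte enters the fibroblast by construction of the same pair current)
  expect_equal(tr$I_gap_Na + tr$I_gap_K,
               0.5 * (tr$V_myocyte - tr$V_fibroblast), tolerance = 1e-12)
  # during the myocyte AP, Vm > Vfib drives current that depolarizes the
  # fibroblast above its resting potential
  expect_gt(max(tr$V_fibroblast), -47.75 + 5)
})

test_that("unstimulated myocyte holds its resting potential", {
  tr <- simulate_myocyte(n_pulses = 0, duration = 1000, dt = 0.01,
                         record_stride = 100)
  expect_lt(abs(tr$V[nrow(tr)] - tr$V[1]), 1)
  st <- attr(tr, "state")
  expect_true(atriasim:::valid_cell_state(st))
})

test_that("suprathreshold stimulus elicits an overshooting, repolarizing AP", {
  tr <- simulate_myocyte(n_pulses = 1, duration = 500, dt = 0.01,
                         stim_amp = 30, record_stride = 20)
  expect_gt(max(tr$V), 0)
  expect_lt(tr$V[nrow(tr)], -70)
})

test_that("single-step integration error is second order (Richardson)", {
  p <- myocyte_parameters()
  # state mid-upstroke: step a stimulated cell for 1 ms first
  s <- myocyte_initial_state(p)
  for (i in 1:100) s <- step_myocyte(s, p, 0.01, i_stim = 30)
  err <- sapply(c(0.01, 0.005, 0.0025), function(h) {
    big <- step_myocyte(s, p, h)
    small <- step_myocyte(step_myocyte(s, p, h / 2), p, h / 2)
    abs(big[["V"]] - small[["V"]])
  })
  # halving dt cuts the per-step defect ~4x
  expect_gt(err[1] / err[2], 2.5)
  expect_gt(err[2] / err[3], 2.5)
})

test_that("paced myocyte reaches beat-to-beat periodic APD90 by beat 4", {
  bm <- ap_biomarkers(baseline_paced_trace())
  expect_true(all(is.finite(bm$apd90)))
  expect_lt(abs(bm$apd90[4] - bm$apd90[3]), 2)
  expect_lt(abs(bm$apd90[5] - bm$apd90[4]), 2)
})

test_that("uncoupled fibroblast rests near -47.75 mV from several starts", {
  tr <- simulate_fibroblast(duration = 2000)
  expect_lt(abs(tr$V[nrow(tr)] - (-47.75)), 2)
  hi <- simulate_fibroblast(V0 = -80, duration = 6000)
  lo <- simulate_fibroblast(V0 = -30, duration = 6000)
  expect_lt(abs(hi$V[nrow(hi)] - lo$V[nrow(lo)]), 1)
})

test_that("fibroblast is non-excitable: sustained drive gives no regenerative spike", {
  tr <- simulate_fibroblast(duration = 2000, i_gap_in = 5)
  v <- tr$V
  # monotone depolarization up to its maximum, then delayed-rectifier sag --
  # never an AP-like overshoot
  imax <- which.max(v)
  expect_true(all(diff(v[1:imax]) > -1e-9))
  expect_lt(max(v), -10)
  expect_gt(v[length(v)], -47.75 + 3)       # settles on a depolarized plateau
})

test_that("coupling fibroblasts raises myocyte diastolic potential", {
  tr <- simulate_cell_pair(n_fib = 2, duration = 2000)
  expect_gt(tr$V_myocyte[nrow(tr)], -79.83 + 1)
})

test_that("profile scaling multiplies exactly the nine targets", {
  base <- myocyte_parameters()
  expect_identical(apply_profile_scaling(base, profile_scaling()), base)
  sc <- apply_profile_scaling(base, c(gNa = 73.13))
  expect_equal(sc$g_Na, 1.7313 * base$g_Na)
  expect_equal(sc$g_CaL, base$g_CaL)
  scD <- apply_profile_scaling(base, c(D = -50))
  expect_equal(scD$D, base$D / 2)
  expect_equal(scD$g_Na, base$g_Na)
  sc2 <- apply_profile_scaling(base, profile_scaling(INaK = 100, IKCa = -50))
  expect_equal(sc2$I_NaK_max, 2 * base$I_NaK_max)
  expect_equal(sc2$g_SK, base$g_SK / 2)
  expect_error(apply_profile_scaling(base, c(gFoo = 10)), "unknown")
  expect_error(profile_scaling(gNa = 150), "\\[-50, 100\\]")
})

test_that("scaling composes multiplicatively with drug block (order-independent)", {
  base <- myocyte_parameters()
  pr <- profile_scaling(gNa = 40, gCaL = -20)
  dg <- drug_spec("amiodarone")
  a <- apply_drug(apply_profile_scaling(base, pr), dg)
  b <- apply_profile_scaling(apply_drug(base, dg), pr)
  expect_equal(a, b)
})
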