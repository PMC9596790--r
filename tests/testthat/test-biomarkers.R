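test_that("planted APD90, RMP and amplitude are recovered from clean fixtures", {
  tr <- synthetic_ap_trace(apd90 = 150, rmp = -80, amplitude = 100, dt = 0.05)
  bm <- ap_biomarkers(tr)
  expect_equal(bm$apd90, 150, tolerance = 0.5)
  expect_equal(bm$rmp, -80, tolerance = 0.5)
  expect_equal(bm$amplitude, 100, tolerance = 0.5)
  # peak-amplitude value reported in the population summaries
  tr2 <- synthetic_ap_trace(apd90 = 180, rmp = -78.63, amplitude = 89.16,
                            dt = 0.05)
  expect_equal(ap_biomarkers(tr2)$amplitude, 89.16, tolerance = 0.5)
})

test_that("time dilation doubles the measured APD90", {
  tr <- synthetic_ap_trace(apd90 = 120, dt = 0.05)
  tr2 <- tr
  tr2$time <- tr$time * 2
  attr(tr2, "stim_times") <- attr(tr, "stim_times") * 2
  attr(tr2, "period") <- attr(tr, "period") * 2
  expect_equal(apd90(tr2), 2 * apd90(tr), tolerance = 1e-6)
})

test_that("windows without an upstroke yield the no-AP marker", {
  flat <- data.frame(time = seq(0, 500, by = 0.5), V = -80)
  bm <- ap_biomarkers(flat, beat_starts = 0, period = 500)
  expect_true(is.na(bm$apd90))
  expect_true(is.na(bm$t_act))
  expect_equal(bm$rmp, -80)
})

test_that("noisy fixtures are recovered without bias", {
  rec <- sapply(1:20, function(s) {
    tr <- synthetic_ap_trace(apd90 = 150, noise_sd = 1, seed = s, dt = 0.05)
    apd90(tr)
  })
  expect_lt(abs(mean(rec) - 150), 2)
})

test_that("trace biomarkers are invariant to sampling refinement", {
  f1 <- ap_biomarkers(synthetic_ap_trace(apd90 = 150, dt = 0.05))
  f5 <- ap_biomarkers(synthetic_ap_trace(apd90 = 150, dt = 0.25))
  expect_lt(abs(f1$apd90 - f5$apd90) / f1$apd90, 0.005)
})

test_that("baseline single-cell APD90 lies within the shipped acceptance band", {
  bm <- ap_biomarkers(baseline_paced_trace())
  r <- biomarker_ranges()
  expect_gt(bm$apd90[4], r$apd90[1])
  expect_lt(bm$apd90[4], r$apd90[2])
  expect_gt(bm$rmp[4], r$rmp[1])
  expect_lt(bm$rmp[4], r$rmp[2])
})

test_that("conduction velocity is probe distance over activation delay", {
  # 1.9 cm probe distance on the 200 x 200 plane
  res <- fake_result(t_left = 5, t_right = 5 + 28.13)
  expect_equal(conduction_velocity(res), 1.9 / 0.02813, tolerance = 1e-3)
  # right probe never activates -> absent
  res2 <- fake_result(t_left = 5, t_right = NA)
  expect_false(classify_conduction(res2))
  expect_true(is.na(conduction_velocity(res2)))
  # reversed order in a "conducting" run is a probe bug, not a value
  res3 <- fake_result(t_left = 30, t_right = 5)
  expect_error(conduction_velocity(res3), "before")
})

test_that("conduction classification requires depolarization and repolarization", {
  expect_true(classify_conduction(fake_result(5, 33)))
  # failure to repolarize after the last stimulus
  expect_false(classify_conduction(fake_result(5, 33, repol_right = FALSE)))
  # failure to be stimulated: zero-amplitude stimulus on a real toy plane
  g <- tissue_geometry(nx = 12, ny = 10, fibrosis_fraction = 0)
  res <- run_simulation(g, protocol = stimulus_protocol(n_pulses = 1,
                                                        period = 200,
                                                        amplitude = 1e-6),
                        numerics = numerics_config(dt_us = 10))
  expect_false(res$conducted)
})

test_that("biomarker deltas are componentwise, antisymmetric, and gated on conduction", {
  a <- data.frame(apd90 = 180, cv = 64, rmp = -79, peak = 105, conducted = TRUE)
  b <- data.frame(apd90 = 190, cv = 67.5, rmp = -80, peak = 110, conducted = TRUE)
  expect_equal(unname(biomarker_delta(a, a)), c(0, 0, 0, 0))
  d <- biomarker_delta(a, b)
  expect_equal(unname(d["dCV"]), -3.5)
  expect_equal(unname(d), -unname(biomarker_delta(b, a)))
  nb <- b; nb$conducted <- FALSE
  expect_true(all(is.na(biomarker_delta(a, nb))))
})

test_that("condition summaries give mean, SD and conducting counts", {
  tab <- data.frame(apd90 = c(180, 200), cv = c(60, 70), rmp = c(-80, -78),
                    peak = c(100, 110), conducted = c(TRUE, TRUE))
  s <- summarize_condition(tab)
  expect_equal(s$n_conducting, 2)
  cvrow <- s$stats[s$stats$biomarker == "cv", ]
  expect_equal(cvrow$mean, 65)
  expect_equal(cvrow$sd, sqrt(50), tolerance = 1e-6)
  one <- summarize_condition(tab[1, ])
  expect_equal(one$stats$sd, rep(0, 4))
  none <- summarize_condition(transform(tab, conducted = FALSE))
  expect_equal(none$n_conducting, 0)
  expect_equal(nrow(none$stats), 0)
})

test_that("group tests behave on identical, shifted, and contingency data", {
  x <- rep(c(1.1, 2.3, 3.7, 2.2, 1.9), 2)
  g <- rep(c("a", "b"), each = 5)
  res <- group_tests(x, g)
  expect_gt(res$t_p, 0.99)
  expect_gt(res$kruskal_p, 0.9)
  set.seed(4)
  y <- c(rnorm(30), rnorm(30, mean = 5))
  res2 <- group_tests(y, rep(c("a", "b"), each = 30))
  expect_lt(res2$t_p, 1e-3)
  expect_lt(res2$anova_p, 1e-3)
  expect_true(res2$significant)
  # conduction-proportion contingency (CV-increase counts by condition)
  flag <- c(rep(TRUE, 124), rep(FALSE, 0), rep(TRUE, 5), rep(FALSE, 11))
  cond <- c(rep("f0", 124), rep("f10", 16))
  res3 <- group_tests(flag, cond, binary = TRUE)
  expect_lt(res3$p, 0.05)
  # undersized groups flagged, not computed
  res4 <- group_tests(c(1, 2, 3), c("a", "b", "b"))
  expect_match(res4$flag, "fewer than 2")
  expect_null(res4$anova_p)
  expect_error(group_tests(1:3, rep("a", 3)), "2 groups")
})
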