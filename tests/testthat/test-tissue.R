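test_that("fibrosis mask has exact count, determinism, and seed sensitivity", {
  expect_equal(sum(build_fibrosis_mask(20, 20, 0, 1)), 0)
  expect_equal(sum(build_fibrosis_mask(200, 200, 0.10, 1)), 4000)
  expect_equal(sum(build_fibrosis_mask(30, 30, 0.05, 7)), round(0.05 * 900))
  m1 <- build_fibrosis_mask(50, 50, 0.1, 3)
  m2 <- build_fibrosis_mask(50, 50, 0.1, 3)
  m3 <- build_fibrosis_mask(50, 50, 0.1, 4)
  expect_identical(m1, m2)
  expect_gt(sum(m1 != m3), 0)
  expect_error(build_fibrosis_mask(10, 10, 1, 1), "fraction")
})

test_that("probes map the physical 0.5/19.5 mm convention and sit on myocytes", {
  g <- tissue_geometry(nx = 200, ny = 200, fibrosis_fraction = 0)
  expect_equal(unname(g$probe_left["col"]), 5)    # 0.5 mm at dx = 0.1 mm
  expect_equal(unname(g$probe_right["col"]), 195) # 19.5 mm
  expect_equal(unname(g$probe_left["row"]), 100)
  tp <- toy_plane(20, 20, fraction = 0.3, seed = 2)
  gt <- tp$geometry
  expect_false(gt$mask[gt$probe_left["row"], gt$probe_left["col"]])
  expect_false(gt$mask[gt$probe_right["row"], gt$probe_right["col"]])
  expect_equal(sum(gt$mask), round(0.3 * 400))
})

test_that("diffusion term: constant field, stencil symmetry, linear gradient", {
  g <- tissue_geometry(nx = 12, ny = 10, fibrosis_fraction = 0)
  D <- 0.001
  u <- matrix(-80, 10, 12)
  expect_true(all(diffusion_term(u, g, D) == 0))
  # single depolarized interior node
  u2 <- u; u2[5, 6] <- -70
  L <- diffusion_term(u2, g, D)
  scale <- D / g$dx^2
  expect_equal(L[5, 6], -4 * 10 * scale)
  expect_equal(L[5, 5], 10 * scale)
  expect_equal(L[4, 6], 10 * scale)
  # linear gradient along x: zero in the interior and zero net flux
  u3 <- matrix(rep(seq_len(12), each = 10), 10, 12)
  L3 <- diffusion_term(u3, g, D)
  expect_true(all(abs(L3[, 2:11]) < 1e-12))
  expect_equal(sum(L3), 0, tolerance = 1e-9)
  # conservation with fibroblasts present
  g2 <- tissue_geometry(nx = 12, ny = 10, fibrosis_fraction = 0.2, mask_seed = 5)
  u4 <- matrix(rnorm(120, -80, 5), 10, 12)
  expect_equal(sum(diffusion_term(u4, g2, D)), 0, tolerance = 1e-9)
  expect_error(diffusion_term(u4 * NA, g2, D), "non-finite")
})

test_that("solver rejects steps beyond the diffusion stability bound", {
  g <- tissue_geometry(nx = 12, ny = 10, fibrosis_fraction = 0)
  expect_error(run_simulation(g, numerics = numerics_config(dt_us = 500)),
               "stability")
})

test_that("pure diffusion conserves total Vm over myocyte nodes", {
  g <- tissue_geometry(nx = 20, ny = 20, fibrosis_fraction = 0.1, mask_seed = 2)
  v0 <- matrix(-80, 20, 20); v0[, 1:4] <- -20
  res <- run_simulation(g, protocol = stimulus_protocol(n_pulses = 1, period = 100),
                        numerics = numerics_config(dt_us = 10),
                        pure_diffusion = TRUE, v0_field = as.numeric(v0))
  myo <- !as.logical(g$mask)
  expect_equal(sum(res$v_final[myo]), sum(v0[myo]), tolerance = 1e-8)
})

test_that("a small homogeneous plane conducts left to right every beat", {
  res <- toy_run(fraction = 0, n_pulses = 2)
  expect_true(res$conducted)
  g <- res$geometry
  il <- atriasim:::probe_index(g, g$probe_left) + 1L
  ir <- atriasim:::probe_index(g, g$probe_right) + 1L
  for (b in 1:2) {
    expect_true(is.finite(res$t_act[il, b]))
    expect_gt(res$t_act[ir, b], res$t_act[il, b])
  }
  # activation times increase monotonically with distance along the centreline
  row <- g$probe_left[["row"]]
  ta <- res$t_act[row + (seq(4, 19) - 1) * g$ny, 2]
  expect_true(all(diff(ta) > 0))
})

test_that("identical configuration and seeds give bit-identical runs", {
  a <- toy_run(fraction = 0.05, mask_seed = 9)
  g <- tissue_geometry(nx = 20, ny = 20, fibrosis_fraction = 0.05, mask_seed = 9)
  b <- run_simulation(g, protocol = stimulus_protocol(n_pulses = 2),
                      numerics = numerics_config(dt_us = 10))
  expect_identical(a$t_act, b$t_act)
  expect_identical(a$v_final, b$v_final)
})

test_that("near-total Na-channel block abolishes propagation", {
  res <- toy_run(drug = drug_spec("sotalol"))
  expect_false(res$conducted)
  basal <- toy_run()
  expect_true(basal$conducted)
})

test_that("CV scales as sqrt(D) on a 1D-like strip", {
  strip <- function(D_scale) {
    g <- tissue_geometry(nx = 100, ny = 3, fibrosis_fraction = 0)
    run_simulation(g, profile = profile_scaling(D = D_scale),
                   protocol = stimulus_protocol(n_pulses = 2),
                   numerics = numerics_config(dt_us = 10))
  }
  cv1 <- conduction_velocity(strip(0))
  cv2 <- conduction_velocity(strip(100))   # doubled D
  expect_lt(abs(cv2 / cv1 - sqrt(2)), 0.05 * sqrt(2))
})

test_that("numerical blow-up is reported with a time stamp", {
  # an absurd stimulus drives the state non-finite
  g <- tissue_geometry(nx = 12, ny = 10, fibrosis_fraction = 0)
  expect_error(
    run_simulation(g, protocol = stimulus_protocol(n_pulses = 1, period = 50,
                                                   amplitude = 4e7,
                                                   duration = 40),
                   numerics = numerics_config(dt_us = 10)),
    "non-finite|blow-up")
})

test_that("increasing Na-channel block never restores conduction", {
  g <- tissue_geometry(nx = 40, ny = 3, fibrosis_fraction = 0)
  conducted_at <- sapply(c(1, 0.6, 0.3, 0.12, 0.05), function(f) {
    p <- myocyte_parameters()
    p$g_Na <- p$g_Na * f
    run_simulation(g, protocol = stimulus_protocol(n_pulses = 1, period = 400),
                   numerics = numerics_config(dt_us = 10),
                   base_params = p)$conducted
  })
  expect_true(conducted_at[1])
  # monotone: once blocked, stays blocked as the factor shrinks
  expect_true(all(diff(as.integer(conducted_at)) <= 0))
  expect_false(conducted_at[5])
})
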