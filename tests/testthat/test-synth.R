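test_that("patch movie with no patches is offset plus noise, empty truth", {
  sim <- generate_patch_movie(small_patch_params(n_patches = 0L))
  expect_equal(nrow(sim$truth), 0L)
  m <- mean(sim$stack$data)
  expect_lt(abs(m - 100), 1)     # camera offset 100, zero-mean noise
})

test_that("rendered spot integrates to gain x molecules (PSF truncation < 2%)", {
  p <- small_patch_params(n_patches = 1L, read_noise_sd = 0,
                          bleach_rate = 0, illum_amplitude = 0)
  sim <- generate_patch_movie(p)
  tru <- sim$truth
  # frame closest to the Abp1 peak
  t_peak <- tru$t0_s + tru$accum_s
  f <- round(t_peak / p$frame_interval) + 1L
  frame <- sim$stack$data[f, 2, , ] - p$offset
  expected <- p$gain * actinquant:::triangle_kinetics(
    (f - 1) * p$frame_interval, tru$t0_s, tru$accum_s, tru$peak_abp1,
    tru$deacc_s)
  expect_equal(sum(frame), expected, tolerance = 0.02)
})

test_that("generators are seed-deterministic", {
  a <- generate_patch_movie(small_patch_params(seed = 9))
  b <- generate_patch_movie(small_patch_params(seed = 9))
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth, b$truth)
  c <- generate_patch_movie(small_patch_params(seed = 10))
  expect_false(identical(a$stack$data, c$stack$data))

  b1 <- generate_bead_movie(bead_sim_params(seed = 4))
  b2 <- generate_bead_movie(bead_sim_params(seed = 4))
  expect_identical(b1$stack$data, b2$stack$data)
})

test_that("bead kinematics: stationary and constant-speed displacement", {
  s0 <- generate_bead_movie(bead_sim_params(speed_um_min = 0, n_frames = 5,
                                            noise_sd = 0))
  expect_equal(diff(s0$truth$x_um), rep(0, 4))
  expect_equal(diff(s0$truth$y_um), rep(0, 4))
  # 1 um/min at 70 s intervals -> 7/6 um per frame
  s1 <- generate_bead_movie(bead_sim_params(speed_um_min = 1, n_frames = 10,
                                            noise_sd = 0))
  expect_equal(diff(s1$truth$x_um), rep(7 / 6, 9), tolerance = 1e-12)
  expect_error(generate_bead_movie(bead_sim_params(speed_um_min = 60)),
               "exits the field")
})

test_that("bead movie renders the requested bundles in the truth table", {
  sim <- generate_bead_movie(bead_sim_params(n_bundles = 2,
                                             bundle_spacing_um = 4,
                                             bundle_peaks = c(200, 300)))
  expect_equal(nrow(sim$bundles), 2L)
  expect_equal(diff(sim$bundles$position_um), 4)
})

test_that("pyrene trace: logistic plateau and analytic maximum slope", {
  p <- pyrene_sim_params(noise_sd = 0)
  tr <- generate_pyrene_trace(p)
  expect_equal(tail(tr$rfu, 1), p$plateau, tolerance = 1e-3)
  # oracle: maximum of dP/dt for the logistic is r * P_total / 4 at t_half
  dPdt <- diff(tr$polymer_nM) / diff(tr$time_s)
  expect_equal(max(dPdt), p$r * p$P_total / 4, tolerance = 1e-3)
  t_at <- tr$time_s[which.max(dPdt)]
  expect_equal(t_at, p$t_half, tolerance = 0.01 * p$t_half)
  # two seeds differ only in noise
  a <- generate_pyrene_trace(pyrene_sim_params(noise_sd = 5, seed = 1))
  b <- generate_pyrene_trace(pyrene_sim_params(noise_sd = 5, seed = 2))
  expect_false(identical(a$rfu, b$rfu))
  expect_identical(a$polymer_nM, b$polymer_nM)
})

test_that("depletion generator follows the quadratic binding model", {
  # L = 0 -> no binding
  d0 <- generate_depletion_data(depletion_sim_params(ligand_uM = 0))
  expect_equal(d0$fraction_bound, 0)
  # stoichiometric limit: K_D -> 0 with L >= R binds everything
  ds <- generate_depletion_data(
    depletion_sim_params(K_D = 0, receptor_total = 0.05,
                         ligand_uM = c(0.05, 0.1, 1)))
  expect_equal(ds$fraction_bound, rep(1, 3))
  # closed form at L = R = K_D = k: (3 - sqrt(5)) / 2
  dk <- generate_depletion_data(
    depletion_sim_params(K_D = 1, receptor_total = 1, ligand_uM = 1))
  expect_equal(dk$fraction_bound, (3 - sqrt(5)) / 2, tolerance = 1e-12)
  # noise is multiplicative and clipped to [0, 1]
  dn <- generate_depletion_data(
    depletion_sim_params(noise_sd = 0.5, seed = 3))
  expect_true(all(dn$fraction_bound >= 0 & dn$fraction_bound <= 1))
})

test_that("ground truth supports analytic metric expectations", {
  sim <- generate_patch_movie(small_patch_params(seed = 2))
  tru <- sim$truth
  expect_equal(tru$accum_rate_true, tru$peak_abp1 / tru$accum_s)
  expect_equal(tru$deacc_rate_true, -tru$peak_abp1 / tru$deacc_s)
  expect_equal(tru$las17_early, tru$las17_max_t_s < tru$t0_s)
  # origins respect the separation constraint
  if (nrow(tru) > 1) {
    dmat <- as.matrix(dist(tru[, c("x_um", "y_um")]))
    diag(dmat) <- Inf
    expect_gte(min(dmat), small_patch_params()$min_spacing_um)
  }
})
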