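test_that("fraction_bound is the depleted share of total receptor", {
  expect_equal(fraction_bound(50, 25), 0.5)
  expect_equal(fraction_bound(50, 50), 0)
  expect_equal(fraction_bound(50, 0), 1)
  expect_error(fraction_bound(0, 1), "> 0")
})

test_that("quadratic_fraction: limits, closed form, monotonicity", {
  expect_equal(quadratic_fraction(0, 0.05, 0.16), 0)
  expect_equal(quadratic_fraction(c(0.05, 0.2), 0.05, 0), c(1, 1))
  expect_equal(quadratic_fraction(1, 1, 1), (3 - sqrt(5)) / 2,
               tolerance = 1e-12)
  # monotone increasing in L, decreasing in K_D
  L <- seq(0.01, 2, length.out = 50)
  expect_true(all(diff(quadratic_fraction(L, 0.05, 0.16)) > 0))
  kds <- seq(0.01, 2, length.out = 50)
  expect_true(all(diff(quadratic_fraction(0.5, 0.05, kds)) < 0))
  # ligand-excess limit -> L / (L + K_D)
  expect_equal(quadratic_fraction(0.5, 1e-9, 0.16), 0.5 / (0.5 + 0.16),
               tolerance = 1e-6)
})

test_that("fit_kd recovers generating affinities and matches a grid oracle", {
  wt <- generate_depletion_data(depletion_design("wt_las17"))
  f <- fit_kd(wt, receptor_total = 0.05)
  expect_equal(f$K_D, 0.16, tolerance = 1e-3)
  myo <- generate_depletion_data(depletion_design("myo5"))
  expect_equal(fit_kd(myo, receptor_total = 0.05)$K_D, 0.13,
               tolerance = 1e-3)
  # brute-force grid oracle on noisy data
  noisy <- generate_depletion_data(
    depletion_sim_params(K_D = 0.16, noise_sd = 0.05, seed = 21))
  fn <- fit_kd(noisy, 0.05)
  grid <- exp(seq(log(1e-4), log(100), length.out = 10000))
  sse <- vapply(grid, function(k)
    sum((noisy$fraction_bound -
           quadratic_fraction(noisy$ligand_uM, 0.05, k))^2), numeric(1))
  expect_equal(fn$K_D, grid[which.min(sse)], tolerance = 0.01)
  expect_error(fit_kd(wt[1:3, ], 0.05), "at least 4")
})

test_that("fit_kd median error < 5% at 1% noise over 100 replicates", {
  p <- depletion_design("wt_las17")
  errs <- vapply(1:100, function(i) {
    p$noise_sd <- 0.01
    p$seed <- i
    fit_kd(generate_depletion_data(p), 0.05)$K_D / p$K_D - 1
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.05)
})

test_that("equilibration time: exponential approach plateaus near 3 tau", {
  t <- seq(5, 120, by = 5)
  sig <- 1 - exp(-t / 15)
  # oracle: within 5% of the final value from t = -tau ln(...) ~ 44.8 min
  expect_equal(as.numeric(equilibration_time(t, sig)), 45)
  const <- rep(3, 6)
  expect_equal(as.numeric(equilibration_time(t[1:6], const)), 5)
  expect_error(equilibration_time(c(5, 10), c(1, 2)), "at least 4")
  # non-monotone series flagged
  expect_warning(eq <- equilibration_time(t[1:8], c(1, 5, 2, 6, 3, 5, 5, 5)),
                 "non-monotone")
  expect_true(attr(eq, "nonmonotone"))
})

test_that("RFU-to-polymer conversion anchors baseline and plateau", {
  tr <- data.frame(time_s = 0:4, rfu = c(50, 275, 500, 725, 950))
  out <- convert_rfu_to_polymer(tr, baseline = 50, plateau = 950,
                                polymerizable_nM = 2900)
  expect_equal(out$polymer_nM, c(0, 725, 1450, 2175, 2900))
  expect_error(convert_rfu_to_polymer(tr, 950, 50, 2900), "plateau")
})

test_that("MPR: exact on lines, within 1% of the logistic maximum slope", {
  line <- data.frame(time_s = 0:20, rfu = 3 + 2.5 * (0:20))
  expect_equal(max_polymerization_rate(line, "rfu")$mpr, 2.5,
               tolerance = 1e-12)
  p <- pyrene_sim_params(noise_sd = 0)
  tr <- generate_pyrene_trace(p)
  m <- max_polymerization_rate(tr, "polymer_nM")
  expect_equal(m$mpr, p$r * p$P_total / 4, tolerance = 0.01)
  expect_equal(m$t_at_max, p$t_half, tolerance = 0.02 * p$t_half)
  down <- data.frame(time_s = 0:20, rfu = 100 - (0:20))
  expect_warning(md <- max_polymerization_rate(down, "rfu"),
                 "non-positive")
  expect_lte(md$mpr, 0)
  expect_error(max_polymerization_rate(line[1:3, ], "rfu", window = 5),
               "shorter")
})

test_that("titration fit recovers saturation parameters", {
  L <- c(0, 25, 75, 150, 300, 600, 1200, 2500)
  pts <- data.frame(las17_nM = L,
                    mpr_nM_per_s = 10 * L / (300 + L) + 1)
  f <- fit_mpr_titration(pts)
  expect_equal(f$Ymax, 10, tolerance = 1e-4)
  expect_equal(f$K_half, 300, tolerance = 1e-4)
  expect_equal(f$Yo, 1, tolerance = 1e-4)
  # substitution check: at L = K1/2, Y = Ymax/2 + Yo
  expect_equal(10 * 300 / (300 + 300) + 1, 10 / 2 + 1)
  # flat response flags unidentifiable K1/2
  flat <- data.frame(las17_nM = L, mpr_nM_per_s = rep(2, 8))
  expect_warning(ff <- fit_mpr_titration(flat), "unidentifiable")
  expect_lt(ff$Ymax, 1e-3)
})

test_that("percent activity: anchors and scale invariance", {
  expect_equal(percent_activity(5, 5, 1), 100)
  expect_equal(percent_activity(1, 5, 1), 0)
  expect_equal(percent_activity(1.56, 2.0, 1.0), 56)
  # invariance to common rescaling
  expect_equal(percent_activity(3.2, 6.1, 0.7),
               percent_activity(32, 61, 7))
  expect_error(percent_activity(1, 1, 2), "exceed")
})
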