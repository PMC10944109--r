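test_that("bead tracking recovers a known path within half a pixel", {
  sim <- generate_bead_movie(bead_sim_params(seed = 5, n_frames = 12,
                                             tail_amp = 0, noise_sd = 0))
  tr <- track_beads(sim$stack)
  expect_equal(length(unique(tr$track)), 1L)
  err_px <- sqrt((tr$x_um - sim$truth$x_um)^2 +
                   (tr$y_um - sim$truth$y_um)^2) / sim$stack$pixel_size
  expect_lt(max(err_px), 0.5)
  # stationary bead: zero net displacement
  s0 <- generate_bead_movie(bead_sim_params(seed = 5, n_frames = 6,
                                            speed_um_min = 0, tail_amp = 0,
                                            noise_sd = 0))
  tr0 <- track_beads(s0$stack)
  net <- sqrt(diff(range(tr0$x_um))^2 + diff(range(tr0$y_um))^2)
  expect_lt(net, 0.05)
})

test_that("two well-separated beads give two tracks", {
  p <- bead_sim_params(seed = 6, n_frames = 8, tail_amp = 0, noise_sd = 0)
  a <- generate_bead_movie(p)
  p2 <- p; p2$start_xy_um <- c(6, 10)
  b <- generate_bead_movie(p2)
  st <- a$stack
  st$data <- pmax(a$stack$data + b$stack$data - p$offset, 0)
  tr <- track_beads(st)
  expect_equal(length(unique(tr$track)), 2L)
})

test_that("bead exclusion rules: diameter, field bounds, crossing", {
  mk <- function(id, x, y) data.frame(track = id, frame = seq_along(x) - 1,
                                      x_um = x, y_um = y)
  field <- c(65, 50)
  tracks <- rbind(mk(1, seq(10, 20, 2), rep(10, 6)),     # fine, 3.0 um
                  mk(2, seq(10, 20, 2), rep(20, 6)),     # too large, 4.0 um
                  mk(3, seq(60, 70, 2), rep(30, 6)))     # leaves field
  f <- filter_beads(tracks, c(`1` = 3.0, `2` = 4.0, `3` = 3.0), field)
  expect_true(f$included[f$track == 1])
  expect_false(f$included[f$track == 2])
  expect_match(f$reason[f$track == 2], "3.8")
  expect_false(f$included[f$track == 3])
  expect_match(f$reason[f$track == 3], "field")
  # crossing tracks excluded
  cross <- rbind(mk(1, seq(10, 20, 2), rep(10, 6)),
                 mk(2, seq(20, 10, -2), rep(10.5, 6)))
  f <- filter_beads(cross, c(`1` = 3.0, `2` = 3.0), field)
  expect_false(any(f$included))
  expect_match(f$reason[1], "crossed")
})

test_that("bead velocity is exact on noiseless constant-speed tracks", {
  tr <- data.frame(frame = 0:19, x_um = 5 + (0:19) * 7 / 6, y_um = 10)
  v <- bead_velocity(tr, frame_interval = 70, smooth_window = 1)
  expect_equal(v$velocity_um_min, rep(1, 20), tolerance = 1e-12)
  v0 <- bead_velocity(data.frame(frame = 0:5, x_um = 3, y_um = 3), 70)
  expect_equal(v0$velocity_um_min, rep(0, 6))
  expect_error(bead_velocity(data.frame(frame = 0, x_um = 1, y_um = 1), 70),
               "2 frames")
  # recovery within 3% at 0.3 px position noise
  set.seed(9)
  trn <- data.frame(frame = 0:29, x_um = 6 + (0:29) * 7 / 6, y_um = 26)
  trn$x_um <- trn$x_um + rnorm(30, 0, 0.3 * 0.325)
  trn$y_um <- trn$y_um + rnorm(30, 0, 0.3 * 0.325)
  vn <- bead_velocity(trn, 70)
  expect_equal(mean(vn$velocity_um_min), 1, tolerance = 0.03)
})

test_that("line profiles find leading/trailing peaks around the bead", {
  # symmetric halo (no tail): leading ~ trailing, peak-to-peak ~ diameter
  sym <- generate_bead_movie(bead_sim_params(seed = 7, n_frames = 10,
                                             tail_amp = 0, noise_sd = 1))
  prof <- line_profile_analysis(sym$stack, sym$truth)
  expect_true(all(prof$ok))
  expect_equal(mean(prof$leading), mean(prof$trailing), tolerance = 0.05)
  expect_equal(mean(prof$peak_to_peak_um), 3.0, tolerance = 0.2)
  # comet tail raises the trailing peak above the leading one
  tail_ <- generate_bead_movie(bead_sim_params(seed = 7, n_frames = 10,
                                               noise_sd = 1))
  ptail <- line_profile_analysis(tail_$stack, tail_$truth)
  expect_true(all(ptail$trailing > ptail$leading))
})

test_that("relative polymerization rate = velocity x trailing intensity", {
  v <- data.frame(frame = 0:4, velocity_um_min = c(2, 2, 0, 1, 3))
  pr <- data.frame(frame = 0:4, leading = 50, trailing = c(100, 80, 60, 90, 100),
                   valley = 10, peak_to_peak_um = 3, peak_to_valley_um = 1.5,
                   ok = TRUE)
  rp <- relative_polymerization_rate(v, pr)
  expect_equal(rp$rel_poly_rate, c(200, 160, 0, 90, 300))
  # homogeneity: doubling intensity doubles the metric
  pr2 <- pr; pr2$trailing <- pr$trailing * 2
  expect_equal(relative_polymerization_rate(v, pr2)$rel_poly_rate,
               rp$rel_poly_rate * 2)
  expect_error(relative_polymerization_rate(v[1:3, ], pr), "same frames")
})

test_that("angular profiles bin the annulus correctly", {
  # uniform image: all 12 bins equal within 1%, counts tile the annulus
  st <- image_stack(array(100, c(3, 1, 120, 120)), 0.325, 70, "actin")
  # positions on exact pixel centres so the annulus tally is integral
  tr <- data.frame(frame = 0:2, x_um = 19.5 + (0:2) * 0.65, y_um = 19.5)
  ang <- angular_intensity(st, tr)
  expect_equal(nrow(ang), 12L)
  expect_lt(diff(range(ang$mean)) / mean(ang$mean), 0.01)
  # pixel count equals the annulus tally at the same (fractional) centres
  cnt <- sum(vapply(1:3, function(t) {
    cx <- tr$x_um[t] / 0.325 + 1
    cy <- tr$y_um[t] / 0.325 + 1
    dx <- outer(rep(1, 120), seq_len(120) - cx)
    dy <- outer(seq_len(120) - cy, rep(1, 120))
    dd <- sqrt(dx^2 + dy^2)
    sum(dd >= 4 & dd <= 15)
  }, numeric(1)))
  expect_equal(sum(ang$n_pixels), cnt)
  # offset linearity: adding b then subtracting b leaves means unchanged
  st2 <- st; st2$data <- st$data + 50
  ang2 <- angular_intensity(st2, tr)
  expect_equal(ang2$mean - 50, ang$mean, tolerance = 1e-12)

  # intensity only directly behind the bead peaks in the 180 degree bin
  d <- array(10, c(2, 1, 120, 120))
  for (t in 1:2) {
    cx <- (19.5 + (t - 1) * 0.65) / 0.325 + 1
    cy <- 19.5 / 0.325 + 1
    d[t, 1, round(cy), round(cx - 10)] <- 10000  # 10 px behind (motion +x)
  }
  stb <- image_stack(d, 0.325, 70, "actin")
  angb <- angular_intensity(stb, tr[1:2, ])
  expect_equal(angb$bin_start_deg[which.max(angb$mean)], 180)

  # annulus radii enforced in pixels: 3 px excluded, 10 px included
  d3 <- array(0, c(2, 1, 120, 120))
  for (t in 1:2) {
    cx <- (19.5 + (t - 1) * 0.65) / 0.325 + 1
    cy <- 19.5 / 0.325 + 1
    d3[t, 1, round(cy), round(cx + 3)] <- 500
  }
  st3 <- image_stack(d3, 0.325, 70, "actin")
  a3 <- angular_intensity(st3, tr[1:2, ])
  expect_equal(sum(a3$mean * a3$n_pixels), 0)   # 3 px pixel never counted
  expect_error(angular_intensity(st, tr, bin_deg = 25), "divide")
})

test_that("bundle peak finder matches the brute-force oracle", {
  # deterministic two-bump cases
  pos <- seq(0, 20, by = 0.1)
  two <- 10 * exp(-(pos - 5)^2 / 0.5) + 8 * exp(-(pos - 12)^2 / 0.5)
  bq <- bundle_quantification(data.frame(position_um = pos, intensity = two),
                              min_prominence = 1, min_width_um = 0.2,
                              min_distance_um = 1)
  expect_equal(bq$n_peaks, 2L)
  expect_equal(bq$peaks$position_um, c(5, 12), tolerance = 0.05)
  expect_equal(bq$max_intensity, max(two))
  # two bumps closer than min distance: keep the higher
  close_ <- 10 * exp(-(pos - 5)^2 / 0.5) + 8 * exp(-(pos - 5.6)^2 / 0.5)
  bq2 <- bundle_quantification(
    data.frame(position_um = pos, intensity = close_),
    min_prominence = 0.5, min_width_um = 0.2, min_distance_um = 2)
  expect_equal(bq2$n_peaks, 1L)
  expect_equal(bq2$peaks$position_um, pos[which.max(close_)])
  # flat profile: no peaks
  expect_equal(bundle_quantification(
    data.frame(position_um = pos, intensity = rep(3, length(pos))),
    min_prominence = 0.5)$n_peaks, 0L)
  expect_error(find_profile_peaks(numeric(0), numeric(0)), "empty")

  # random 200-point profiles against the oracle
  for (seed in 1:20) {
    set.seed(seed)
    y <- cumsum(rnorm(200))
    y <- y - min(y)
    x <- seq(0, 19.9, by = 0.1)
    got <- find_profile_peaks(x, y, min_prominence = 1.5,
                              min_width_um = 0.15, min_distance_um = 1,
                              window_um = 8)
    want <- oracle_find_peaks(x, y, min_prominence = 1.5,
                              min_width_um = 0.15, min_distance_um = 1,
                              window_um = 8)
    expect_equal(got$position_um, want$position_um,
                 info = paste("seed", seed))
  }
})

test_that("trajectory profiles recover rendered bundle peaks", {
  sim <- generate_bead_movie(bead_sim_params(seed = 11, n_bundles = 2,
                                             bundle_spacing_um = 5,
                                             bundle_peaks = c(220, 300)))
  prof <- trajectory_profile(sim$stack, sim$truth, frame = 29)
  # restrict to the comet-tail region behind the final bead position
  tail_region <- prof[prof$position_um < 20, ]
  bq <- bundle_quantification(tail_region, min_prominence = 50,
                              min_distance_um = 1)
  expect_equal(bq$n_peaks, 2L)
  expect_equal(bq$peaks$position_um, sim$bundles$position_um,
               tolerance = 0.05)
})
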