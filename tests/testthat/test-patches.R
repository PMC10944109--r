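spot_stack <- function(xy_um = list(c(3.0, 3.0)), totals = 4000,
                       nt = 1, ny = 96, nx = 96, noise = 0, offset = 0,
                       seed = 1, pixel = 0.065) {
  set.seed(seed)
  d <- array(0, c(nt, 1, ny, nx))
  for (t in seq_len(nt)) {
    img <- matrix(offset, ny, nx)
    for (i in seq_along(xy_um)) {
      img <- actinquant:::add_gaussian_spot(
        img, xy_um[[i]][1] / pixel + 1, xy_um[[i]][2] / pixel + 1,
        0.1 / pixel, totals[min(i, length(totals))])
    }
    if (noise > 0) img <- img + rnorm(ny * nx, 0, noise)
    d[t, 1, , ] <- pmax(img, 0)
  }
  image_stack(d, pixel, 1, "abp1")
}

test_that("a single bright spot is localized within half a pixel", {
  st <- spot_stack(noise = 10)   # peak pixel amplitude ~ 100, SNR ~ 10
  det <- detect_spots(st, "abp1")
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x - 3.0), 0.5 * st$pixel_size)
  expect_lt(abs(det$y - 3.0), 0.5 * st$pixel_size)
  # corrected intensity close to the rendered total
  expect_equal(det$corrected_intensity, 4000, tolerance = 0.1)
})

test_that("blank noise frames yield no detections at the default threshold", {
  set.seed(2)
  st <- image_stack(array(pmax(rnorm(96 * 96, 100, 5), 0), c(1, 1, 96, 96)),
                    0.065, 1, "abp1")
  det <- detect_spots(st, "abp1")
  expect_equal(nrow(det), 0L)
})

test_that("two spots 1 um apart are resolved as two detections", {
  st <- spot_stack(xy_um = list(c(2.5, 3.0), c(3.5, 3.0)),
                   totals = c(4000, 4000), noise = 5)
  det <- detect_spots(st, "abp1")
  expect_equal(nrow(det), 2L)
  expect_equal(sort(det$x), c(2.5, 3.5), tolerance = 0.05)
})

test_that("raising the quality threshold never increases detections", {
  sim <- generate_patch_movie(small_patch_params(seed = 8))
  st <- subtract_cytosol(sim$stack)
  counts <- vapply(c(2, 5, 10, 20), function(thr)
    nrow(detect_spots(st, "abp1", quality_threshold = thr)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("linking follows steps, splits long jumps, bridges 2-frame gaps", {
  step <- data.frame(t = 0:9, x = 1 + 0.1 * (0:9), y = 2, quality = 1,
                     raw_intensity = 1, corrected_intensity = 1)
  expect_equal(length(unique(link_spots(step)$track)), 1L)

  jump <- step
  jump$x[6:10] <- jump$x[6:10] + 1.0
  expect_equal(length(unique(link_spots(jump)$track)), 2L)

  gap <- step[-(5:6), ]              # 2 missing frames
  gap$x[gap$t >= 6] <- gap$x[gap$t >= 6] - 0.1  # reappears 0.3 um away
  linked <- link_spots(gap)
  expect_equal(length(unique(linked$track)), 1L)
  # 3 missing frames exceed max_frame_gap = 2
  gap3 <- step[-(5:7), ]
  expect_equal(length(unique(link_spots(gap3)$track)), 2L)
})

test_that("curation drops boundary-touching and crowded tracks", {
  mk <- function(id, frames, x, y = 2) {
    data.frame(t = frames, x = x, y = y, quality = 1, raw_intensity = 1,
               corrected_intensity = 1, track = id)
  }
  edge <- mk(1, 0:10, 1)                     # starts at frame 0
  tail_ <- mk(2, 40:49, 1)                   # ends at the last frame
  iso <- mk(3, 10:20, 3)
  out <- curate_tracks(rbind(edge, tail_, iso), n_frames = 50)
  expect_equal(unique(out$track), 3L)
  # two concurrent tracks 0.3 um apart are both dropped
  near1 <- mk(1, 10:20, 2.0)
  near2 <- mk(2, 12:18, 2.3)
  out <- curate_tracks(rbind(near1, near2, mk(3, 10:20, 4)), n_frames = 50)
  expect_equal(unique(out$track), 3L)
  # roi keeps only tracks starting inside the mask
  roi <- matrix(FALSE, 96, 96)
  roi[, 1:46] <- TRUE                        # x < ~3 um
  out <- curate_tracks(rbind(mk(1, 10:20, 2), mk(2, 10:20, 5)),
                       n_frames = 50, roi = roi, pixel_size = 0.065)
  expect_equal(unique(out$track), 1L)
})

test_that("channel pairing is one-to-one by distance with time compatibility", {
  mk <- function(id, frames, x, y = 2) {
    data.frame(t = frames, x = x, y = y, quality = 1, raw_intensity = 10,
               corrected_intensity = 10, track = id)
  }
  las <- mk(1, 5:15, 1.0)
  abp <- mk(1, 10:20, 1.1)
  ev <- pair_channels(las, abp, frame_interval = 1)
  expect_length(ev, 1L)
  # 2 um apart -> no event
  ev <- pair_channels(mk(1, 5:15, 1.0), mk(1, 10:20, 3.0), 1)
  expect_length(ev, 0L)
  expect_equal(attr(ev, "unpaired")$las17, 1L)
  # one Las17 near two Abp1 candidates pairs with the nearer
  abp2 <- rbind(mk(1, 10:20, 1.4), mk(2, 10:20, 1.1))
  ev <- pair_channels(las, abp2, 1)
  expect_length(ev, 1L)
  expect_equal(unique(ev[[1]]$abp1$track), 2L)
  # lifetimes separated by more than 10 s do not pair
  ev <- pair_channels(mk(1, 0:5, 1.0), mk(1, 20:30, 1.0), 1)
  expect_length(ev, 0L)
})

test_that("alignment puts t = 0 at the Abp1 maximum, earliest on ties", {
  mol <- c(1, 3, 6, 9, 12, 9, 6, 3)   # max at frame 4 (0-based)
  ev <- make_event(mol, rep(5, 8))
  expect_equal(ev$align_frame, 4L)
  expect_equal(ev$abp1$t_rel_s[5], 0)
  tie <- c(1, 5, 9, 9, 5, 1)          # tie at frames 2 and 3
  ev <- make_event(tie, rep(5, 6))
  expect_equal(ev$align_frame, 2L)
  # averaging aligned copies of one event reproduces the event
  ev1 <- make_event(mol, rep(5, 8))
  avg <- average_events(list(ev1, ev1, ev1), "abp1")
  expect_equal(avg$mean, mol)
  expect_equal(avg$sd, rep(0, 8))
})

test_that("molecule calibration maps control maxima to reference counts", {
  mol <- c(2, 8, 20, 8, 2)
  ev <- make_event(mol * 100, rep(50, 5))   # intensities, not molecules
  ev$abp1$molecules <- NULL; ev$las17$molecules <- NULL
  ctrl <- control_max_intensity(list(ev))
  calib <- calibration_constants(c(las17 = 120, abp1 = 600), ctrl)
  ev2 <- to_molecules(ev, calib)
  expect_equal(max(ev2$abp1$molecules), 600)
  expect_equal(max(ev2$las17$molecules), 120)
  expect_equal(ev2$abp1$molecules[1], 600 * mol[1] / max(mol))
  # zero intensity -> zero molecules
  ev$abp1$corrected_intensity[1] <- 0
  expect_equal(to_molecules(ev, calib)$abp1$molecules[1], 0)
  # intensity rescaling cancels when calibration is recomputed
  ev_gain <- ev
  ev_gain$abp1$corrected_intensity <- ev$abp1$corrected_intensity * 2
  ev_gain$las17$corrected_intensity <- ev$las17$corrected_intensity * 2
  calib2 <- calibration_constants(c(las17 = 120, abp1 = 600),
                                  control_max_intensity(list(ev_gain)))
  expect_equal(to_molecules(ev_gain, calib2)$abp1$molecules,
               to_molecules(ev, calib)$abp1$molecules)
  expect_error(calibration_constants(c(abp1 = 600), c(las17 = 1)), "las17")
})

test_that("metrics: rates, assembly time, displacement, strict threshold", {
  mol <- c(10, 20, 30, 40, 50, 30, 10)  # rise 10/frame, fall 20/frame
  ev <- make_event(mol, c(5, 5, 6, 5, 5, 5, 5))
  m <- compute_metrics(ev, frame_interval = 1)
  expect_equal(m$accum_rate_abp1, 10)
  expect_equal(m$deacc_rate_abp1, -20)
  expect_equal(m$assembly_time_s, 4)
  expect_equal(m$max_molecules_abp1, 50)

  disp_event <- function(d) {
    n <- 7
    xy <- cbind(1 + seq(0, d, length.out = n), rep(1, n))
    make_event(mol, rep(5, n), abp1_xy = xy)
  }
  expect_true(compute_metrics(disp_event(0.30), 1)$internalized)
  expect_false(compute_metrics(disp_event(0.10), 1)$internalized)
  # exactly at 0.25 um is NOT internalized (strictly greater than)
  expect_false(compute_metrics(disp_event(0.25), 1)$internalized)

  # Las17 peak before first Abp1 frame -> las17_early
  ev <- make_event(c(5, 10, 5), c(2, 9, 4, 2, 1),
                   abp1_t = 6:8, las17_t = 3:7)
  m <- compute_metrics(ev, 1)
  expect_true(m$las17_early)       # Las17 max at frame 4 < Abp1 first 6
  ev2 <- make_event(c(5, 10, 5), c(2, 4, 9, 4, 2),
                    abp1_t = 3:5, las17_t = 2:6)
  expect_false(compute_metrics(ev2, 1)$las17_early)

  # a phase with < 3 points leaves the rate NA and flags it
  short <- make_event(c(5, 10, 3, 1), rep(5, 4))  # accumulation has 2 pts
  m <- compute_metrics(short, 1)
  expect_true(is.na(m$accum_rate_abp1))
  expect_true(m$rate_undefined_abp1)
})

test_that("strain summary aggregates metrics and percentages", {
  mk_metric <- function(early, internal = TRUE) {
    data.frame(event = 1, max_molecules_las17 = 100,
               max_molecules_abp1 = 700, accum_rate_las17 = 10,
               accum_rate_abp1 = 90, deacc_rate_las17 = -8,
               deacc_rate_abp1 = -100, assembly_time_s = 8,
               max_displacement_um = 0.4, internalized = internal,
               las17_early = early, rate_undefined_las17 = FALSE,
               rate_undefined_abp1 = FALSE)
  }
  met <- do.call(rbind, lapply(seq_len(195), function(i)
    mk_metric(early = i <= 70)))
  s <- strain_summary(met)
  pct <- s$mean[s$metric == "percent_las17_early"]
  expect_equal(round(pct, 1), 35.9)
  expect_equal(s$mean[s$metric == "percent_internalized"], 100)
  # single event: SD 0 and flagged
  s1 <- strain_summary(mk_metric(TRUE))
  expect_true(all(s1$single_event))
  expect_equal(s1$sd[s1$metric == "max_molecules_abp1"], 0)
  expect_error(strain_summary(mk_metric(TRUE)[0, ]), "no events")
})

test_that("kymographs show vertical bands for stationary, sloped for moving", {
  px <- 0.065
  nt <- 10
  mk_stack <- function(move_um_frame = 0) {
    d <- array(0, c(nt, 1, 96, 96))
    for (t in 1:nt) {
      x <- 2 + (t - 1) * move_um_frame
      d[t, 1, , ] <- actinquant:::add_gaussian_spot(
        matrix(0, 96, 96), x / px + 1, 2 / px + 1, 0.1 / px, 1000)
    }
    image_stack(d, px, 1, "abp1")
  }
  mk_ev <- function(move_um_frame) {
    xs <- 2 + (0:(nt - 1)) * move_um_frame
    list(abp1 = data.frame(t = 0:(nt - 1), x = xs, y = 2,
                           corrected_intensity = 1000))
  }
  ky0 <- kymograph(mk_ev(0.1), mk_stack(0), channel = 1)
  band0 <- apply(ky0, 2, which.max)
  expect_equal(length(unique(band0)), 1L)
  ky1 <- kymograph(mk_ev(0.1), mk_stack(0.1), channel = 1)
  s_um <- attr(ky1, "s_um")
  peak_pos <- s_um[apply(ky1, 2, which.max)]
  fitted_slope <- coef(lm(peak_pos ~ seq_len(nt)))[[2]]
  expect_equal(fitted_slope, 0.1, tolerance = 0.1)
  # blank movie -> zero image
  blank <- image_stack(array(0, c(nt, 1, 96, 96)), px, 1, "abp1")
  expect_equal(max(kymograph(mk_ev(0.1), blank, channel = 1)), 0)
})
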