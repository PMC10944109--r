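# Shared fixtures and independent oracles for the test suite.

# Small, fast patch movie used by unit tests (full-size movies are
# exercised in the acceptance suite).
small_patch_params <- function(seed = 1L, n_patches = 6L, ...) {
  patch_sim_params(n_patches = n_patches, n_frames = 50L,
                   ny = 96L, nx = 96L, seed = seed, ...)
}

# Run the full patch pipeline (preprocess -> detect -> link -> curate ->
# pair -> align) on a simulated movie.
run_patch_pipeline <- function(sim, quality_threshold = 5) {
  st <- suppressWarnings({
    s <- correct_illumination(sim$stack)
    b <- correct_photobleaching(s)
    subtract_cytosol(b$stack)
  })
  fi <- sim$stack$frame_interval
  nf <- dim(sim$stack)[1]
  det_a <- detect_spots(st, "abp1", quality_threshold = quality_threshold)
  det_l <- detect_spots(st, "las17", quality_threshold = quality_threshold,
                        median_filter = TRUE)
  cu_a <- curate_tracks(link_spots(det_a), nf)
  cu_l <- curate_tracks(link_spots(det_l), nf)
  ev <- align_events(pair_channels(cu_l, cu_a, fi), fi)
  list(stack = st, events = ev, det_abp1 = det_a, det_las17 = det_l,
       tracks_abp1 = cu_a, tracks_las17 = cu_l)
}

# Match recovered events to ground-truth patches by mean Abp1 position;
# returns the truth row index per event.
match_events_to_truth <- function(events, truth) {
  vapply(events, function(ev) {
    which.min((truth$x_um - mean(ev$abp1$x))^2 +
                (truth$y_um - mean(ev$abp1$y))^2)
  }, integer(1))
}

# True Abp1 molecule count and position of every patch at time tt (the
# analytic forward model the generator renders).
truth_state_at <- function(truth, tt) {
  mol <- actinquant:::triangle_kinetics(tt, truth$t0_s, truth$accum_s,
                                        truth$peak_abp1, truth$deacc_s)
  t_max <- truth$t0_s + truth$accum_s
  frac <- pmin(pmax((tt - t_max) / truth$deacc_s, 0), 1)
  data.frame(x = truth$x_um + frac * truth$displacement_um * truth$dir_x,
             y = truth$y_um + frac * truth$displacement_um * truth$dir_y,
             mol = mol)
}

# Brute-force peak-finding oracle: enumerate every strict local maximum
# (plateaus at their centre), compute prominence by full left/right scans
# within the window, width at half prominence by interpolation, then apply
# the prominence/width/min-distance rules. Independent of the package's
# implementation path.
oracle_find_peaks <- function(position, intensity, min_prominence,
                              min_width_um, min_distance_um,
                              window_um = Inf) {
  n <- length(intensity)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (intensity[i] > intensity[i - 1L]) {
      j <- i
      while (j < n && intensity[j + 1L] == intensity[j]) j <- j + 1L
      if (j < n && intensity[j + 1L] < intensity[j])
        cand <- c(cand, (i + j) %/% 2L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(cand)) return(data.frame(position_um = numeric(0),
                                       intensity = numeric(0)))
  half <- window_um / 2
  prom <- vapply(cand, function(k) {
    lo <- if (is.finite(half)) which(position >= position[k] - half)[1] else 1L
    hi <- if (is.finite(half))
      tail(which(position <= position[k] + half), 1L) else n
    jl <- k
    lmin <- intensity[k]
    while (jl > lo && intensity[jl - 1L] <= intensity[k]) {
      jl <- jl - 1L
      lmin <- min(lmin, intensity[jl])
    }
    if (jl == lo) lmin <- min(intensity[lo:k])
    jr <- k
    rmin <- intensity[k]
    while (jr < hi && intensity[jr + 1L] <= intensity[k]) {
      jr <- jr + 1L
      rmin <- min(rmin, intensity[jr])
    }
    if (jr == hi) rmin <- min(intensity[k:hi])
    intensity[k] - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence & prom > 0
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand)) {
    width <- vapply(seq_along(cand), function(kk) {
      k <- cand[kk]
      level <- intensity[k] - prom[kk] / 2
      xl <- position[1]; xr <- position[n]
      j <- k
      while (j > 1L && intensity[j - 1L] > level) j <- j - 1L
      if (j > 1L) {
        f <- (intensity[j] - level) / (intensity[j] - intensity[j - 1L])
        xl <- position[j] - f * (position[j] - position[j - 1L])
      }
      j <- k
      while (j < n && intensity[j + 1L] > level) j <- j + 1L
      if (j < n) {
        f <- (intensity[j] - level) / (intensity[j] - intensity[j + 1L])
        xr <- position[j] + f * (position[j + 1L] - position[j])
      }
      xr - xl
    }, numeric(1))
    keep <- width >= min_width_um
    cand <- cand[keep]; prom <- prom[keep]
  }
  if (length(cand) > 1L && is.finite(min_distance_um)) {
    ord <- order(intensity[cand], decreasing = TRUE)
    kept <- integer(0)
    for (k in ord) {
      if (!length(kept) ||
          all(abs(position[cand[k]] - position[cand[kept]]) >=
              min_distance_um))
        kept <- c(kept, k)
    }
    cand <- sort(cand[kept])
  }
  data.frame(position_um = position[cand], intensity = intensity[cand])
}

# Minimal two-track synthetic event for metric unit tests: molecule traces
# given directly.
make_event <- function(abp1_mol, las17_mol, abp1_xy = NULL,
                       abp1_t = NULL, las17_t = NULL, frame_interval = 1) {
  if (is.null(abp1_t)) abp1_t <- seq_along(abp1_mol) - 1L
  if (is.null(las17_t)) las17_t <- seq_along(las17_mol) - 1L
  if (is.null(abp1_xy))
    abp1_xy <- cbind(rep(1, length(abp1_mol)), rep(1, length(abp1_mol)))
  ev <- list(
    id = 1L,
    abp1 = data.frame(t = abp1_t, x = abp1_xy[, 1], y = abp1_xy[, 2],
                      quality = 1, raw_intensity = abp1_mol,
                      corrected_intensity = abp1_mol,
                      molecules = abp1_mol),
    las17 = data.frame(t = las17_t, x = 1, y = 1, quality = 1,
                       raw_intensity = las17_mol,
                       corrected_intensity = las17_mol,
                       molecules = las17_mol))
  ev <- align_events(list(ev), frame_interval)[[1]]
  ev
}
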