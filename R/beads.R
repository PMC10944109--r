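#' Track beads in a motility movie
#'
#' Locates the bead in every frame as the intensity-weighted centroid of
#' the thresholded bright region (the fluorescent actin shell around the
#' bead is radially symmetric, so its centroid sits at the bead centre) and
#' assembles tracks by nearest-neighbour linking. Alternatively, tracker-
#' exported positions (frame, x, y CSV) can be consumed directly by the
#' downstream operators.
#'
#' @param stack single-channel [image_stack()].
#' @param threshold_frac threshold as a fraction of the frame's background-
#'   to-maximum range.
#' @param max_link_um frame-to-frame linking distance (um).
#' @param min_area_px minimum connected-component area to count as a bead.
#' @param min_peak_frac components whose brightest pixel falls below this
#'   fraction of the frame's background-to-maximum range are discarded
#'   (rejects comet-tail and bundle debris, which is dimmer than the bead
#'   shell).
#' @return data frame: `track`, `frame` (0-based), `x_um`, `y_um`.
#' @export
track_beads <- function(stack, threshold_frac = 0.6, max_link_um = 5,
                        min_area_px = 9L, min_peak_frac = 0.8) {
  validate_image_stack(stack)
  px <- stack$pixel_size
  dets <- list()
  for (t in seq_len(n_frames(stack))) {
    frame <- stack$data[t, 1L, , ]
    bg <- stats::median(frame)
    fmax <- max(frame)
    thr <- bg + threshold_frac * (fmax - bg)
    mask <- frame > thr
    if (!any(mask)) next
    lab <- EBImage::bwlabel(mask)
    labm <- as.matrix(lab)
    for (k in seq_len(max(labm))) {
      idx <- which(labm == k, arr.ind = TRUE)
      if (nrow(idx) < min_area_px) next
      if (max(frame[idx]) < bg + min_peak_frac * (fmax - bg)) next
      w <- frame[idx] - bg
      dets[[length(dets) + 1L]] <- data.frame(
        t = t - 1L,
        x = (sum((idx[, 2L] - 1) * w) / sum(w)) * px,
        y = (sum((idx[, 1L] - 1) * w) / sum(w)) * px)
    }
  }
  if (!length(dets)) stop("no beads found in any frame")
  det <- do.call(rbind, dets)
  det$quality <- 1
  linked <- link_spots(det, max_link_um = max_link_um,
                       gap_close_um = max_link_um, max_frame_gap = 1L)
  data.frame(track = linked$track, frame = linked$t,
             x_um = linked$x, y_um = linked$y)
}

#' Flag bead tracks for exclusion
#'
#' Applies the published exclusion rules: (a) the track crossed over
#' another bead (minimum inter-track distance at any shared frame below the
#' sum of the radii), (b) the bead diameter exceeds 3.8 um, (c) the
#' complete trajectory is not within the field of view (any position closer
#' than one radius to the field edge).
#'
#' @param tracks data frame from [track_beads()] with columns `track`,
#'   `frame`, `x_um`, `y_um`.
#' @param diameters_um named or ordered numeric vector of bead diameters,
#'   one per track id.
#' @param field_um `c(width, height)` of the field (um).
#' @param max_diameter_um exclusion diameter (um), default 3.8.
#' @return data frame: `track`, `included`, `reason` ("" when included).
#' @export
filter_beads <- function(tracks, diameters_um, field_um,
                         max_diameter_um = 3.8) {
  ids <- sort(unique(tracks$track))
  if (is.null(names(diameters_um))) names(diameters_um) <- ids
  reason <- stats::setNames(rep("", length(ids)), ids)
  for (a in seq_along(ids)) {
    ta <- tracks[tracks$track == ids[a], ]
    dia <- diameters_um[[as.character(ids[a])]]
    if (dia > max_diameter_um) {
      reason[a] <- paste0("diameter ", format(dia), " um > ",
                          max_diameter_um, " um")
      next
    }
    r <- dia / 2
    if (any(ta$x_um < r | ta$x_um > field_um[1] - r |
            ta$y_um < r | ta$y_um > field_um[2] - r)) {
      reason[a] <- "trajectory not fully within field of view"
      next
    }
    for (b in seq_along(ids)) {
      if (b == a) next
      tb <- tracks[tracks$track == ids[b], ]
      common <- intersect(ta$frame, tb$frame)
      if (!length(common)) next
      pa <- ta[match(common, ta$frame), ]
      pb <- tb[match(common, tb$frame), ]
      dmin <- min(sqrt((pa$x_um - pb$x_um)^2 + (pa$y_um - pb$y_um)^2))
      if (dmin < r + diameters_um[[as.character(ids[b])]] / 2) {
        reason[a] <- paste0("crossed bead track ", ids[b])
        break
      }
    }
  }
  data.frame(track = ids, included = reason == "", reason = unname(reason))
}

#' Bead velocity series
#'
#' Central-difference displacement per frame interval converted to um/min,
#' with one-sided differences at the track ends and optional boxcar
#' smoothing. Exact on noiseless constant-velocity tracks.
#'
#' @param track data frame with `frame`, `x_um`, `y_um` for one bead.
#' @param frame_interval seconds per frame.
#' @param smooth_window boxcar window in frames (odd; 1 = none).
#' @return data frame: `frame`, `velocity_um_min`.
#' @export
bead_velocity <- function(track, frame_interval, smooth_window = 3L) {
  n <- nrow(track)
  if (n < 2L) stop("velocity needs at least 2 frames")
  if (anyDuplicated(track$frame))
    stop("duplicated frames: pass a single bead track")
  o <- order(track$frame)
  x <- track$x_um[o]; y <- track$y_um[o]; f <- track$frame[o]
  v <- numeric(n)
  for (i in seq_len(n)) {
    i0 <- max(1L, i - 1L); i1 <- min(n, i + 1L)
    dt <- (f[i1] - f[i0]) * frame_interval
    v[i] <- sqrt((x[i1] - x[i0])^2 + (y[i1] - y[i0])^2) / dt * 60
  }
  if (smooth_window > 1L) {
    half <- smooth_window %/% 2L
    v <- vapply(seq_len(n), function(i)
      mean(v[max(1L, i - half):min(n, i + half)]), numeric(1))
  }
  data.frame(frame = f, velocity_um_min = v)
}

#' Line-profile analysis along the motion axis
#'
#' Samples the intensity along the axis of motion through the bead centre
#' at every frame and identifies the two local maxima bracketing the bead
#' (the leading and trailing edges) and the local minimum between them (the
#' bead centre). Records the three intensities plus peak-to-peak and
#' peak-to-valley distances. Frames where two bracketing maxima cannot be
#' found are flagged (`ok = FALSE`).
#'
#' @param stack single-channel [image_stack()].
#' @param track bead positions (`frame`, `x_um`, `y_um`).
#' @param half_length_um half-length of the sampled profile (um).
#' @param min_speed_um_min below this speed the per-frame motion direction
#'   falls back to the whole-track net displacement.
#' @return data frame per frame: `frame`, `leading`, `trailing`, `valley`,
#'   `peak_to_peak_um`, `peak_to_valley_um`, `ok`.
#' @export
line_profile_analysis <- function(stack, track, half_length_um = 6,
                                  min_speed_um_min = 0.05) {
  validate_image_stack(stack)
  px <- stack$pixel_size
  o <- order(track$frame)
  track <- track[o, ]
  n <- nrow(track)
  dirs <- motion_directions(track, stack$frame_interval, min_speed_um_min)
  s <- seq(-half_length_um, half_length_um, by = px / 2)
  out <- vector("list", n)
  d <- dim(stack$data)
  w_um <- (d[4L] - 1) * px; h_um <- (d[3L] - 1) * px
  for (i in seq_len(n)) {
    t <- track$frame[i] + 1L
    xs <- track$x_um[i] + s * dirs$hx[i]
    ys <- track$y_um[i] + s * dirs$hy[i]
    inside <- xs >= 0 & xs <= w_um & ys >= 0 & ys <= h_um
    prof <- rep(NA_real_, length(s))
    prof[inside] <- bilinear_sample(stack$data[t, 1L, , ],
                                    xs[inside] / px + 1, ys[inside] / px + 1)
    rec <- profile_peaks_around_centre(s, prof)
    rec$frame <- track$frame[i]
    out[[i]] <- rec
  }
  do.call(rbind, out)[, c("frame", "leading", "trailing", "valley",
                          "peak_to_peak_um", "peak_to_valley_um", "ok")]
}

# Per-frame motion direction from a 3-frame displacement, falling back to
# the whole-track net displacement at negligible speed.
motion_directions <- function(track, frame_interval, min_speed_um_min) {
  n <- nrow(track)
  net_dx <- track$x_um[n] - track$x_um[1]
  net_dy <- track$y_um[n] - track$y_um[1]
  net_n <- sqrt(net_dx^2 + net_dy^2)
  if (net_n < 1e-12) { net_dx <- 1; net_dy <- 0 } else {
    net_dx <- net_dx / net_n; net_dy <- net_dy / net_n
  }
  hx <- numeric(n); hy <- numeric(n)
  for (i in seq_len(n)) {
    i0 <- max(1L, i - 1L); i1 <- min(n, i + 1L)
    dx <- track$x_um[i1] - track$x_um[i0]
    dy <- track$y_um[i1] - track$y_um[i0]
    dt_min <- (track$frame[i1] - track$frame[i0]) * frame_interval / 60
    sp <- if (dt_min > 0) sqrt(dx^2 + dy^2) / dt_min else 0
    if (sp < min_speed_um_min) { hx[i] <- net_dx; hy[i] <- net_dy } else {
      nn <- sqrt(dx^2 + dy^2); hx[i] <- dx / nn; hy[i] <- dy / nn
    }
  }
  list(hx = hx, hy = hy)
}

# Leading/trailing maxima bracketing the central minimum of a profile whose
# positive s-axis points along the motion.
profile_peaks_around_centre <- function(s, prof) {
  bad <- data.frame(leading = NA_real_, trailing = NA_real_,
                    valley = NA_real_, peak_to_peak_um = NA_real_,
                    peak_to_valley_um = NA_real_, ok = FALSE)
  if (all(is.na(prof))) return(bad)
  i <- which(!is.na(prof))
  loc <- i[-c(1, length(i))]
  ismax <- prof[loc] > prof[loc - 1L] & prof[loc] >= prof[loc + 1L]
  maxima <- loc[ismax]
  lead_c <- maxima[s[maxima] > 0]
  trail_c <- maxima[s[maxima] < 0]
  if (!length(lead_c) || !length(trail_c)) return(bad)
  lead <- lead_c[which.max(prof[lead_c])]
  trail <- trail_c[which.max(prof[trail_c])]
  between <- trail:lead
  valley <- between[which.min(prof[between])]
  data.frame(leading = prof[lead], trailing = prof[trail],
             valley = prof[valley],
             peak_to_peak_um = s[lead] - s[trail],
             peak_to_valley_um = s[lead] - s[valley], ok = TRUE)
}

#' Relative actin polymerization rate at the bead surface
#'
#' Per frame, the bead velocity multiplied by the maximum actin intensity
#' at the bead surface, operationalized as the trailing-edge peak of the
#' line profile (where the maximum always occurs in these networks). The
#' metric is homogeneous of degree one in image intensity, so it is
#' comparable only within a common imaging calibration.
#'
#' @param velocity data frame from [bead_velocity()].
#' @param profiles data frame from [line_profile_analysis()].
#' @return data frame: `frame`, `rel_poly_rate` (a.u. um/min).
#' @export
relative_polymerization_rate <- function(velocity, profiles) {
  common <- intersect(velocity$frame, profiles$frame)
  if (length(common) != nrow(velocity) || length(common) != nrow(profiles))
    stop("velocity and profiles must cover the same frames")
  v <- velocity[match(common, velocity$frame), ]
  p <- profiles[match(common, profiles$frame), ]
  data.frame(frame = common,
             rel_poly_rate = v$velocity_um_min * p$trailing)
}

#' Angular intensity distribution around a moving bead
#'
#' Measures fluorescence within an annulus (inner and outer radii in
#' pixels, defaults 4 and 15 — excluding the bead and keeping only the
#' fluorescence immediately around it) at each bead position, assigning
#' pixels to angular bins relative to the direction of motion (0 degrees =
#' direction of motion; bins of `bin_deg` tile 360 exactly, edges at
#' 0, 30, 60, ...). Returns the mean and SD of intensity per bin over all
#' pixels and frames in the range.
#'
#' @param stack single-channel [image_stack()].
#' @param track bead positions (`frame`, `x_um`, `y_um`).
#' @param r_in_px,r_out_px annulus radii in pixels.
#' @param bin_deg angular bin width (must divide 360).
#' @param frames optional 0-based frame subset.
#' @param min_speed_um_min fallback threshold for the motion direction.
#' @return data frame: `bin_start_deg`, `bin_mid_deg`, `mean`, `sd`,
#'   `n_pixels`.
#' @export
angular_intensity <- function(stack, track, r_in_px = 4, r_out_px = 15,
                              bin_deg = 30, frames = NULL,
                              min_speed_um_min = 0.05) {
  validate_image_stack(stack)
  if (360 %% bin_deg != 0) stop("bin width must divide 360 degrees")
  nbin <- as.integer(360 / bin_deg)
  px <- stack$pixel_size
  o <- order(track$frame)
  track <- track[o, ]
  if (!is.null(frames)) {
    keep <- track$frame %in% frames
    dirs_all <- motion_directions(track, stack$frame_interval,
                                  min_speed_um_min)
    dirs <- list(hx = dirs_all$hx[keep], hy = dirs_all$hy[keep])
    track <- track[keep, ]
  } else {
    dirs <- motion_directions(track, stack$frame_interval, min_speed_um_min)
  }
  d <- dim(stack$data)
  acc_n <- integer(nbin)
  acc_s <- numeric(nbin)
  acc_s2 <- numeric(nbin)
  for (i in seq_len(nrow(track))) {
    t <- track$frame[i] + 1L
    cx <- track$x_um[i] / px + 1  # pixel coordinates of the bead centre
    cy <- track$y_um[i] / px + 1
    rr <- max(1L, floor(cy - r_out_px - 1)):min(d[3L], ceiling(cy + r_out_px + 1))
    cc <- max(1L, floor(cx - r_out_px - 1)):min(d[4L], ceiling(cx + r_out_px + 1))
    sub <- stack$data[t, 1L, rr, cc]
    dy <- matrix(rr - cy, length(rr), length(cc))
    dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
    dist <- sqrt(dx^2 + dy^2)
    in_ann <- dist >= r_in_px & dist <= r_out_px
    if (!any(in_ann)) next
    # angle of the pixel offset relative to the motion direction
    ang <- atan2(dy[in_ann], dx[in_ann]) -
      atan2(dirs$hy[i], dirs$hx[i])
    ang <- (ang * 180 / pi) %% 360
    bin <- pmin(floor(ang / bin_deg) + 1L, nbin)
    vals <- sub[in_ann]
    for (b in unique(bin)) {
      v <- vals[bin == b]
      acc_n[b] <- acc_n[b] + length(v)
      acc_s[b] <- acc_s[b] + sum(v)
      acc_s2[b] <- acc_s2[b] + sum(v^2)
    }
  }
  mean_b <- ifelse(acc_n > 0, acc_s / acc_n, NA_real_)
  var_b <- ifelse(acc_n > 1, (acc_s2 - acc_n * mean_b^2) / (acc_n - 1), 0)
  data.frame(bin_start_deg = (seq_len(nbin) - 1L) * bin_deg,
             bin_mid_deg = (seq_len(nbin) - 0.5) * bin_deg,
             mean = mean_b, sd = sqrt(pmax(var_b, 0)), n_pixels = acc_n)
}
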