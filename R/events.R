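#' Pair Las17 and Abp1 trajectories into endocytic events
#'
#' Tracks from the two channels are paired when their time-averaged
#' positions lie within `max_distance_um` and their lifetimes overlap or
#' abut within `max_time_gap_s`. Assignment is one-to-one by increasing
#' distance; unpaired tracks from either channel are reported in the
#' `unpaired` attribute so the pairing rule's effect stays auditable.
#'
#' @param las17_tracks,abp1_tracks curated track data frames
#'   (from [curate_tracks()]).
#' @param frame_interval seconds per frame.
#' @param max_distance_um maximum distance between mean positions.
#' @param max_time_gap_s maximum temporal gap between lifetimes.
#' @return list of events, each `list(id, las17, abp1)` with the per-track
#'   spot data frames; attribute `unpaired` lists leftover track ids per
#'   channel.
#' @export
pair_channels <- function(las17_tracks, abp1_tracks, frame_interval,
                          max_distance_um = 0.5, max_time_gap_s = 10) {
  summ <- function(tr) {
    ids <- unique(tr$track)
    do.call(rbind, lapply(ids, function(id) {
      rows <- tr[tr$track == id, ]
      data.frame(id = id, x = mean(rows$x), y = mean(rows$y),
                 t0 = min(rows$t) * frame_interval,
                 t1 = max(rows$t) * frame_interval)
    }))
  }
  sl <- if (nrow(las17_tracks)) summ(las17_tracks) else NULL
  sa <- if (nrow(abp1_tracks)) summ(abp1_tracks) else NULL
  events <- list()
  paired_l <- integer(0); paired_a <- integer(0)
  if (!is.null(sl) && !is.null(sa)) {
    dmat <- sqrt(outer(sl$x, sa$x, `-`)^2 + outer(sl$y, sa$y, `-`)^2)
    # temporal compatibility: overlap, or gap no larger than max_time_gap_s
    gap <- outer(sl$t0, sa$t1, `-`)
    gap2 <- outer(-sl$t1, -sa$t0, `-`)
    compatible <- pmax(gap, gap2) <= max_time_gap_s
    dmat[!compatible] <- Inf
    m <- greedy_match(dmat, max_distance_um)
    if (nrow(m)) {
      for (k in seq_len(nrow(m))) {
        lid <- sl$id[m$i[k]]; aid <- sa$id[m$j[k]]
        events[[length(events) + 1L]] <- list(
          id = length(events) + 1L,
          las17 = las17_tracks[las17_tracks$track == lid, , drop = FALSE],
          abp1 = abp1_tracks[abp1_tracks$track == aid, , drop = FALSE])
        paired_l <- c(paired_l, lid); paired_a <- c(paired_a, aid)
      }
    }
  }
  attr(events, "unpaired") <- list(
    las17 = setdiff(if (is.null(sl)) integer(0) else sl$id, paired_l),
    abp1 = setdiff(if (is.null(sa)) integer(0) else sa$id, paired_a))
  events
}

#' Align events on the Abp1 intensity maximum
#'
#' Sets `t = 0` at the frame of maximum Abp1 corrected intensity (earliest
#' frame on ties) and attaches a relative time axis `t_rel_s` to both
#' channels, so that molecule-versus-time traces from different events can
#' be averaged on a common axis.
#'
#' @param events list of events from [pair_channels()].
#' @param frame_interval seconds per frame.
#' @return the events with `t_rel_s` columns and an `align_frame` element.
#' @export
align_events <- function(events, frame_interval) {
  lapply(events, function(ev) {
    ab <- ev$abp1
    if (!nrow(ab) || all(ab$corrected_intensity <= 0))
      stop("event ", ev$id, ": Abp1 trace is empty or all zero")
    f0 <- ab$t[which.max(ab$corrected_intensity)]
    ev$align_frame <- f0
    ev$abp1$t_rel_s <- (ab$t - f0) * frame_interval
    ev$las17$t_rel_s <- (ev$las17$t - f0) * frame_interval
    ev
  })
}

#' Calibration constants for fluorescence-to-molecule conversion
#'
#' Holds, per channel, the literature reference molecule count and the
#' control-strain average maximum corrected fluorescence computed with the
#' same pipeline settings. Molecule counts follow as
#' `molecules = intensity * reference_count / control_max_intensity`.
#'
#' @param reference_counts named numeric vector (e.g.
#'   `c(las17 = ..., abp1 = ...)`) of literature average maximum molecule
#'   counts.
#' @param control_max_intensity named numeric vector of control-strain
#'   average maximum corrected intensities for the same channels.
#' @return list of class `calibration_constants`.
#' @export
calibration_constants <- function(reference_counts, control_max_intensity) {
  stopifnot(length(reference_counts) > 0,
            all(reference_counts > 0), all(control_max_intensity > 0))
  miss <- setdiff(names(reference_counts), names(control_max_intensity))
  miss <- c(miss, setdiff(names(control_max_intensity),
                          names(reference_counts)))
  if (length(miss))
    stop("calibration missing channel(s): ", paste(miss, collapse = ", "))
  structure(list(reference_counts = reference_counts,
                 control_max_intensity = control_max_intensity),
            class = "calibration_constants")
}

#' Average maximum corrected intensity of control-strain events
#'
#' @param events aligned control-strain events.
#' @return named vector with the mean per-event maximum corrected intensity
#'   for each channel.
#' @export
control_max_intensity <- function(events) {
  per_ev <- vapply(events, function(ev)
    c(las17 = max(ev$las17$corrected_intensity),
      abp1 = max(ev$abp1$corrected_intensity)), numeric(2))
  rowMeans(per_ev)
}

#' Convert event fluorescence to molecule counts
#'
#' @param event a single aligned event.
#' @param calib a [calibration_constants()] object.
#' @return the event with a `molecules` column per channel.
#' @export
to_molecules <- function(event, calib) {
  stopifnot(inherits(calib, "calibration_constants"))
  for (ch in c("las17", "abp1")) {
    if (!ch %in% names(calib$reference_counts))
      stop("calibration missing channel: ", ch)
    ratio <- calib$reference_counts[[ch]] /
      calib$control_max_intensity[[ch]]
    event[[ch]]$molecules <- event[[ch]]$corrected_intensity * ratio
  }
  event
}

#' Per-event patch metrics
#'
#' Computes, per channel, the maximum molecule count and the accumulation
#' and deaccumulation rates (least-squares slope of molecules versus time
#' over all points from first appearance through the maximum, and from the
#' maximum through the last recorded frame with measurable intensity);
#' the Abp1 assembly time (time of maximum minus time of first
#' appearance); the maximum displacement of the Abp1 track from its first
#' detected position; the internalization flag (strictly more than
#' `internalization_um` from the origin); and the Las17-early flag (the
#' Las17 molecule maximum precedes the first frame of detectable Abp1
#' signal). Ties at a maximum resolve to the earliest frame. A phase with
#' fewer than 3 points leaves its rate `NA` and raises the corresponding
#' flag column.
#'
#' @param event an aligned, calibrated event (see [to_molecules()]).
#' @param frame_interval seconds per frame.
#' @param internalization_um internalization threshold (um), default 0.25.
#' @return one-row data frame of metrics.
#' @export
compute_metrics <- function(event, frame_interval,
                            internalization_um = 0.25) {
  value_col <- function(tr)
    if ("molecules" %in% names(tr)) tr$molecules else tr$corrected_intensity
  phase_slopes <- function(tr) {
    v <- value_col(tr)
    tt <- tr$t * frame_interval
    imax <- which.max(v)          # earliest maximal frame
    up <- seq_len(imax)
    down <- imax:length(v)
    slope <- function(ii) {
      if (length(ii) < 3L) return(NA_real_)
      tc <- tt[ii] - mean(tt[ii])
      sum(tc * v[ii]) / sum(tc^2)
    }
    list(max = v[imax], imax = imax,
         accum = slope(up), deacc = slope(down),
         t_first = tt[1], t_max = tt[imax])
  }
  la <- phase_slopes(event$las17)
  ab <- phase_slopes(event$abp1)
  ab_pos <- event$abp1
  disp <- sqrt((ab_pos$x - ab_pos$x[1])^2 + (ab_pos$y - ab_pos$y[1])^2)
  max_disp <- max(disp)
  las17_max_frame <- event$las17$t[la$imax]
  abp1_first_frame <- min(event$abp1$t)
  data.frame(
    event = if (!is.null(event$id)) event$id else NA_integer_,
    max_molecules_las17 = la$max,
    max_molecules_abp1 = ab$max,
    accum_rate_las17 = la$accum,
    accum_rate_abp1 = ab$accum,
    deacc_rate_las17 = la$deacc,
    deacc_rate_abp1 = ab$deacc,
    assembly_time_s = ab$t_max - ab$t_first,
    max_displacement_um = max_disp,
    internalized = max_disp > internalization_um,
    las17_early = las17_max_frame < abp1_first_frame,
    rate_undefined_las17 = is.na(la$accum) || is.na(la$deacc),
    rate_undefined_abp1 = is.na(ab$accum) || is.na(ab$deacc))
}

#' Strain-level summary of patch metrics
#'
#' Arithmetic mean, standard deviation and n for every numeric metric,
#' plus the percentage of internalized and of Las17-early events over the
#' scored events. A single-event summary reports SD 0 with the
#' `single_event` flag set.
#'
#' @param metrics data frame of per-event metrics
#'   (rows from [compute_metrics()]).
#' @return data frame: `metric`, `mean`, `sd`, `n`, `single_event`.
#' @export
strain_summary <- function(metrics) {
  if (!nrow(metrics)) stop("no events to summarize")
  num_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric,
                                            logical(1))], "event")
  rows <- lapply(num_cols, function(cn) {
    v <- metrics[[cn]]
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(metric = cn,
               mean = if (n) mean(v) else NA_real_,
               sd = if (n > 1L) stats::sd(v) else 0,
               n = n, single_event = n == 1L)
  })
  pct <- function(flag, name) {
    v <- metrics[[flag]]
    v <- v[!is.na(v)]
    data.frame(metric = name, mean = 100 * mean(v), sd = NA_real_,
               n = length(v), single_event = length(v) == 1L)
  }
  out <- do.call(rbind, c(rows, list(
    pct("internalized", "percent_internalized"),
    pct("las17_early", "percent_las17_early"))))
  rownames(out) <- NULL
  out
}

#' Average aligned molecule traces across events
#'
#' Events aligned by [align_events()] share a relative time axis; this
#' averages the molecule (or corrected-intensity) traces over events at
#' each relative time point. Averaging N aligned copies of one event
#' reproduces that event.
#'
#' @param events aligned (and usually calibrated) events.
#' @param channel `"las17"` or `"abp1"`.
#' @return data frame: `t_rel_s`, `mean`, `sd`, `n`.
#' @export
average_events <- function(events, channel = c("abp1", "las17")) {
  channel <- match.arg(channel)
  traces <- lapply(events, function(ev) {
    tr <- ev[[channel]]
    v <- if ("molecules" %in% names(tr)) tr$molecules else
      tr$corrected_intensity
    data.frame(t_rel_s = tr$t_rel_s, value = v)
  })
  all_t <- sort(unique(unlist(lapply(traces, `[[`, "t_rel_s"))))
  vals <- vapply(traces, function(tr)
    tr$value[match(all_t, tr$t_rel_s)], numeric(length(all_t)))
  vals <- matrix(vals, nrow = length(all_t))
  data.frame(
    t_rel_s = all_t,
    mean = apply(vals, 1L, function(r) mean(r, na.rm = TRUE)),
    sd = apply(vals, 1L, function(r) {
      r <- r[!is.na(r)]
      if (length(r) > 1L) stats::sd(r) else 0
    }),
    n = apply(vals, 1L, function(r) sum(!is.na(r))))
}

#' Kymograph of an endocytic event
#'
#' Samples the intensity along the inward axis through the event origin at
#' every frame (bilinear interpolation), producing a distance x time image.
#' The axis runs along the event's net displacement direction; a
#' stationary event falls back to the +x axis.
#'
#' @param event an event with Abp1 positions.
#' @param stack the [image_stack()] the event was tracked in.
#' @param channel channel name or index to sample.
#' @param s_range_um signed sampling range along the axis relative to the
#'   origin (um).
#' @return matrix distance x time; attribute `s_um` holds the distance
#'   axis.
#' @export
kymograph <- function(event, stack, channel = "abp1",
                      s_range_um = c(-0.5, 1.5)) {
  validate_image_stack(stack)
  ci <- resolve_channel(stack, channel)
  ab <- event$abp1
  ox <- ab$x[1]; oy <- ab$y[1]
  dx <- ab$x[nrow(ab)] - ox; dy <- ab$y[nrow(ab)] - oy
  nrm <- sqrt(dx^2 + dy^2)
  if (nrm < 1e-9) { dx <- 1; dy <- 0 } else { dx <- dx / nrm; dy <- dy / nrm }
  px <- stack$pixel_size
  s <- seq(s_range_um[1], s_range_um[2], by = px)
  xs <- ox + s * dx; ys <- oy + s * dy
  d <- dim(stack$data)
  w_um <- (d[4L] - 1) * px; h_um <- (d[3L] - 1) * px
  if (any(xs < 0 | xs > w_um | ys < 0 | ys > h_um))
    stop("kymograph axis leaves the field of view")
  out <- matrix(0, length(s), d[1L])
  for (t in seq_len(d[1L]))
    out[, t] <- bilinear_sample(stack$data[t, ci, , ], xs / px + 1,
                                ys / px + 1)
  attr(out, "s_um") <- s
  out
}

# Bilinear interpolation of matrix m at fractional (row=y, col=x) positions
bilinear_sample <- function(m, col, row) {
  ny <- nrow(m); nx <- ncol(m)
  c0 <- pmin(pmax(floor(col), 1L), nx - 1L)
  r0 <- pmin(pmax(floor(row), 1L), ny - 1L)
  fc <- col - c0; fr <- row - r0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}
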