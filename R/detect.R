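#' Detect diffraction-limited spots by Laplacian-of-Gaussian filtering
#'
#' Blob detection following the published settings: LoG filtering with
#' `sigma = diameter / (2 sqrt(2))`, an optional 3x3 median prefilter (used
#' on the Las17 channel), and a quality threshold. The quality score is the
#' scale-normalized LoG response divided by a robust (MAD-based) estimate
#' of the response noise, so the default threshold of 5 means "5 sigma
#' above background texture" — a calibration of the published
#' detector-scaled threshold, not a numerical equivalence.
#'
#' For every detection the summed intensity within the blob radius is
#' recorded raw and background-corrected (local annulus median). Positions
#' are refined to sub-pixel precision by an intensity-weighted centroid and
#' reported in micrometres; frames are 0-based.
#'
#' @param stack a (preprocessed) [image_stack()].
#' @param channel channel name or index.
#' @param diameter_um estimated blob diameter (um), default 0.5.
#' @param quality_threshold minimum quality score, default 5.
#' @param median_filter apply a 3x3 median prefilter before the LoG.
#' @return data frame: `t` (0-based frame), `x`, `y` (um), `quality`,
#'   `raw_intensity`, `corrected_intensity`.
#' @export
detect_spots <- function(stack, channel, diameter_um = 0.5,
                         quality_threshold = 5, median_filter = FALSE) {
  validate_image_stack(stack)
  ci <- resolve_channel(stack, channel)
  stopifnot(diameter_um > 0)
  px <- stack$pixel_size
  sigma_px <- diameter_um / (2 * sqrt(2)) / px
  r_px <- (diameter_um / 2) / px
  kern <- log_kernel(sigma_px)
  res <- vector("list", n_frames(stack))
  for (t in seq_len(n_frames(stack))) {
    frame <- stack$data[t, ci, , ]
    work <- if (median_filter) median3x3(frame) else frame
    resp <- as.matrix(EBImage::filter2(work, kern))
    sd_rob <- stats::mad(resp)
    if (sd_rob <= 0) sd_rob <- stats::sd(resp)
    if (!isTRUE(sd_rob > 0)) next
    peaks <- local_maxima(resp, margin = ceiling(r_px) + 1L)
    if (!nrow(peaks)) next
    q <- resp[cbind(peaks$row, peaks$col)] / sd_rob
    keep <- q >= quality_threshold
    if (!any(keep)) next
    peaks <- peaks[keep, , drop = FALSE]
    q <- q[keep]
    out <- lapply(seq_len(nrow(peaks)), function(i) {
      meas <- measure_spot(frame, peaks$row[i], peaks$col[i], r_px)
      data.frame(t = t - 1L,
                 x = (meas$col - 1) * px, y = (meas$row - 1) * px,
                 quality = q[i],
                 raw_intensity = meas$raw,
                 corrected_intensity = meas$corrected)
    })
    res[[t]] <- do.call(rbind, out)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(t = integer(0), x = numeric(0), y = numeric(0),
                      quality = numeric(0), raw_intensity = numeric(0),
                      corrected_intensity = numeric(0))
  out
}

# Scale-normalized, zero-mean LoG kernel (bright blobs -> positive response)
log_kernel <- function(sigma_px, truncate = 4) {
  r <- max(2L, ceiling(truncate * sigma_px))
  xs <- -r:r
  g1 <- exp(-xs^2 / (2 * sigma_px^2))
  G <- outer(g1, g1)
  R2 <- outer(xs^2, xs^2, `+`)
  k <- -sigma_px^2 * (R2 - 2 * sigma_px^2) / sigma_px^4 * G
  k - mean(k)
}

# Exact 3x3 median via the 19-exchange median-of-9 selection network
# (vectorized over all pixels; replicate-padded borders).
median3x3 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  padded <- matrix(0, ny + 2L, nx + 2L)
  padded[2:(ny + 1L), 2:(nx + 1L)] <- m
  padded[1L, ] <- padded[2L, ]; padded[ny + 2L, ] <- padded[ny + 1L, ]
  padded[, 1L] <- padded[, 2L]; padded[, nx + 2L] <- padded[, nx + 1L]
  v <- vector("list", 9L)
  k <- 1L
  for (dx in 0:2) for (dy in 0:2) {
    v[[k]] <- as.vector(padded[(1L + dy):(ny + dy), (1L + dx):(nx + dx)])
    k <- k + 1L
  }
  swap <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  swap(2, 3); swap(5, 6); swap(8, 9)
  swap(1, 2); swap(4, 5); swap(7, 8)
  swap(2, 3); swap(5, 6); swap(8, 9)
  swap(1, 4); swap(6, 9); swap(5, 8)
  swap(4, 7); swap(2, 5); swap(3, 6)
  swap(5, 8); swap(5, 3); swap(7, 5)
  swap(5, 3)
  matrix(v[[5]], ny, nx)
}

# Strict 8-neighbour local maxima away from the border.
local_maxima <- function(m, margin = 2L) {
  ny <- nrow(m); nx <- ncol(m)
  if (ny < 2L * margin + 1L || nx < 2L * margin + 1L)
    return(data.frame(row = integer(0), col = integer(0)))
  core <- (margin + 1L):(ny - margin)
  corec <- (margin + 1L):(nx - margin)
  is_max <- matrix(TRUE, length(core), length(corec))
  centre <- m[core, corec]
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    is_max <- is_max & (centre > m[core + dy, corec + dx])
  }
  idx <- which(is_max, arr.ind = TRUE)
  data.frame(row = core[idx[, 1L]], col = corec[idx[, 2L]])
}

# Sub-pixel centroid + disk photometry with annulus background.
measure_spot <- function(frame, row, col, r_px) {
  ny <- nrow(frame); nx <- ncol(frame)
  r_out <- r_px + 2
  rr <- max(1L, floor(row - r_out)):min(ny, ceiling(row + r_out))
  cc <- max(1L, floor(col - r_out)):min(nx, ceiling(col + r_out))
  sub <- frame[rr, cc, drop = FALSE]
  dy <- matrix(rr - row, length(rr), length(cc))
  dx <- matrix(cc - col, length(rr), length(cc), byrow = TRUE)
  d <- sqrt(dy^2 + dx^2)
  in_disk <- d <= r_px
  in_ann <- d > r_px & d <= r_out
  bg <- if (any(in_ann)) stats::median(sub[in_ann]) else 0
  w <- pmax(sub - bg, 0) * in_disk
  sw <- sum(w)
  crow <- if (sw > 0) row + sum(dy * w) / sw else row
  ccol <- if (sw > 0) col + sum(dx * w) / sw else col
  raw <- sum(sub[in_disk])
  list(row = crow, col = ccol, raw = raw,
       corrected = raw - bg * sum(in_disk))
}

#' Link spot detections into trajectories
#'
#' Greedy nearest-neighbour frame-to-frame linking within a maximum link
#' distance, followed by gap closing: a track end may be joined to a later
#' track start across at most `max_frame_gap` missing frames when the two
#' positions lie within the gap-closing distance. Defaults follow the
#' published tracking settings (0.5 um, 0.5 um, 2).
#'
#' @param detections data frame from [detect_spots()] (any extra columns
#'   are carried along).
#' @param max_link_um frame-to-frame linking distance (um).
#' @param gap_close_um gap-closing distance (um).
#' @param max_frame_gap maximum number of consecutive missing frames a gap
#'   may bridge.
#' @return the detections with a `track` id column, ordered by track and
#'   frame.
#' @export
link_spots <- function(detections, max_link_um = 0.5, gap_close_um = 0.5,
                       max_frame_gap = 2L) {
  stopifnot(all(c("t", "x", "y") %in% names(detections)),
            max_link_um > 0, gap_close_um > 0, max_frame_gap >= 0L)
  n <- nrow(detections)
  if (n == 0L) {
    detections$track <- integer(0)
    return(detections)
  }
  o <- order(detections$t)
  det <- detections[o, , drop = FALSE]
  track_of <- integer(n)
  next_id <- 1L
  frames <- sort(unique(det$t))
  prev_idx <- integer(0)
  for (f in frames) {
    cur_idx <- which(det$t == f)
    active <- prev_idx[det$t[prev_idx] == f - 1L]
    if (length(active) && length(cur_idx)) {
      dmat <- outer(det$x[active], det$x[cur_idx], `-`)^2 +
        outer(det$y[active], det$y[cur_idx], `-`)^2
      assigned <- greedy_match(sqrt(dmat), max_link_um)
      for (k in seq_len(nrow(assigned)))
        track_of[cur_idx[assigned$j[k]]] <- track_of[active[assigned$i[k]]]
    }
    for (i in cur_idx) {
      if (track_of[i] == 0L) {
        track_of[i] <- next_id
        next_id <- next_id + 1L
      }
    }
    prev_idx <- cur_idx
  }
  det$track <- track_of
  det <- close_gaps(det, gap_close_um, max_frame_gap)
  det[order(det$track, det$t), , drop = FALSE]
}

# Greedy one-to-one assignment by ascending distance under a cutoff.
greedy_match <- function(dmat, cutoff) {
  cand <- which(dmat <= cutoff, arr.ind = TRUE)
  res <- data.frame(i = integer(0), j = integer(0))
  if (!nrow(cand)) return(res)
  cand <- cand[order(dmat[cand]), , drop = FALSE]
  used_i <- logical(nrow(dmat)); used_j <- logical(ncol(dmat))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE; used_j[j] <- TRUE
      res <- rbind(res, data.frame(i = i, j = j))
    }
  }
  res
}

close_gaps <- function(det, gap_close_um, max_frame_gap) {
  if (max_frame_gap < 1L) return(det)
  repeat {
    ids <- unique(det$track)
    segs <- do.call(rbind, lapply(ids, function(id) {
      rows <- det[det$track == id, , drop = FALSE]
      i0 <- which.min(rows$t); i1 <- which.max(rows$t)
      data.frame(id = id,
                 t0 = rows$t[i0], t1 = rows$t[i1],
                 x0 = rows$x[i0], y0 = rows$y[i0],
                 x1 = rows$x[i1], y1 = rows$y[i1])
    }))
    cand <- NULL
    for (a in seq_len(nrow(segs))) {
      gap <- segs$t0 - segs$t1[a] - 1L
      ok <- which(gap >= 1L & gap <= max_frame_gap & segs$id != segs$id[a])
      if (!length(ok)) next
      dd <- sqrt((segs$x0[ok] - segs$x1[a])^2 + (segs$y0[ok] - segs$y1[a])^2)
      sel <- dd <= gap_close_um
      if (any(sel))
        cand <- rbind(cand, data.frame(from = segs$id[a],
                                       to = segs$id[ok[sel]],
                                       d = dd[sel]))
    }
    if (is.null(cand) || !nrow(cand)) break
    cand <- cand[order(cand$d), , drop = FALSE]
    used_from <- character(0); used_to <- character(0)
    merged <- FALSE
    for (k in seq_len(nrow(cand))) {
      f <- cand$from[k]; to <- cand$to[k]
      if (f %in% used_from || to %in% used_to) next
      det$track[det$track == to] <- f
      used_from <- c(used_from, f); used_to <- c(used_to, to)
      merged <- TRUE
    }
    if (!merged) break
  }
  det$track <- match(det$track, unique(det$track))
  det
}

#' Curate linked tracks to analyzable endocytic events
#'
#' Applies the published curation criteria: (1) the entire lifetime must be
#' recorded (tracks touching the first or last frame are dropped); (2) the
#' patch must be well separated from other patches (any two tracks whose
#' concurrent positions ever come closer than `separation_um` are both
#' dropped); (3) optionally, the patch must originate inside a supplied
#' region-of-interest mask (e.g. the equatorial cortex).
#'
#' @param tracks data frame from [link_spots()].
#' @param n_frames total frame count of the movie.
#' @param separation_um minimum separation between concurrent tracks (um).
#' @param roi optional logical matrix (Y x X) — tracks whose first position
#'   falls on a `FALSE` pixel are dropped.
#' @param pixel_size um/pixel, required when `roi` is given.
#' @return the curated tracks (same columns).
#' @export
curate_tracks <- function(tracks, n_frames, separation_um = 0.5,
                          roi = NULL, pixel_size = NULL) {
  if (!nrow(tracks)) return(tracks)
  ids <- unique(tracks$track)
  first_t <- vapply(ids, function(id) min(tracks$t[tracks$track == id]), 0)
  last_t <- vapply(ids, function(id) max(tracks$t[tracks$track == id]), 0)
  keep <- first_t > 0L & last_t < n_frames - 1L
  # criterion 2: pairwise concurrent proximity
  drop_sep <- rep(FALSE, length(ids))
  for (a in seq_along(ids)) {
    ta <- tracks[tracks$track == ids[a], ]
    for (b in seq_along(ids)) {
      if (b <= a) next
      tb <- tracks[tracks$track == ids[b], ]
      common <- intersect(ta$t, tb$t)
      if (!length(common)) next
      pa <- ta[match(common, ta$t), ]
      pb <- tb[match(common, tb$t), ]
      if (min(sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2)) < separation_um) {
        drop_sep[a] <- TRUE; drop_sep[b] <- TRUE
      }
    }
  }
  keep <- keep & !drop_sep
  if (!is.null(roi)) {
    if (is.null(pixel_size))
      stop("pixel_size is required with an roi mask")
    inside <- vapply(seq_along(ids), function(a) {
      ta <- tracks[tracks$track == ids[a], ]
      i0 <- which.min(ta$t)
      r <- round(ta$y[i0] / pixel_size) + 1L
      c <- round(ta$x[i0] / pixel_size) + 1L
      r >= 1L && r <= nrow(roi) && c >= 1L && c <= ncol(roi) &&
        isTRUE(roi[r, c])
    }, logical(1))
    keep <- keep & inside
  }
  tracks[tracks$track %in% ids[keep], , drop = FALSE]
}
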