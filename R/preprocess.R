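#' Correct uneven illumination
#'
#' Estimates a smooth multiplicative illumination field per channel by a
#' robust (Huber) polynomial-surface fit to the temporal median frame,
#' normalizes the field to mean 1, and divides every frame by it. A flat
#' stack passes through unchanged; a multiplicative linear gradient is
#' removed to well below a tenth of its amplitude. The stack mean is
#' preserved up to the normalization.
#'
#' @param stack an [image_stack()].
#' @param degree polynomial degree of the surface (default 2).
#' @return the corrected `image_stack`, with the per-channel fields in
#'   attribute `illumination`.
#' @export
correct_illumination <- function(stack, degree = 2L) {
  validate_image_stack(stack)
  d <- dim(stack$data)
  fields <- vector("list", d[2L])
  out <- stack
  for (ch in seq_len(d[2L])) {
    med <- apply(stack$data[, ch, , , drop = FALSE], c(3, 4), stats::median)
    # A multiplicative illumination model needs an appreciable diffuse
    # background; on background-free (e.g. already background-subtracted)
    # stacks the correction is skipped (field = 1), which also keeps the
    # correction idempotent.
    if (!has_background(med)) {
      field <- matrix(1, d[3L], d[4L])
    } else {
      field <- fit_poly_surface(med, degree)
      if (mean(field) <= 0 || min(field) <= 0.2 * mean(field)) {
        field <- matrix(1, d[3L], d[4L])
      } else {
        field <- field / mean(field)
      }
    }
    fields[[ch]] <- field
    for (t in seq_len(d[1L]))
      out$data[t, ch, , ] <- stack$data[t, ch, , ] / field
  }
  attr(out, "illumination") <- fields
  out
}

# A stack carries a diffuse background worth modelling when the median of
# its temporal-median frame clearly exceeds that frame's spatial noise
# scale; background-subtracted stacks (mostly zeros) fail this.
has_background <- function(med_frame) {
  stats::median(med_frame) > 3 * stats::mad(med_frame)
}

# Polynomial surface fit to a matrix; ordinary least squares when the
# residual scale is degenerate (exact surface), Huber-robust otherwise so
# that bright spots do not bias the background estimate.
fit_poly_surface <- function(m, degree = 2L) {
  ny <- nrow(m); nx <- ncol(m)
  xs <- (matrix(seq_len(nx), ny, nx, byrow = TRUE) - 1) / max(nx - 1, 1)
  ys <- (matrix(seq_len(ny), ny, nx) - 1) / max(ny - 1, 1)
  df <- data.frame(z = as.vector(m), x = as.vector(xs), y = as.vector(ys))
  form <- if (degree >= 2L) {
    z ~ x + y + I(x^2) + I(y^2) + I(x * y)
  } else {
    z ~ x + y
  }
  fit <- stats::lm(form, data = df)
  scale <- stats::mad(stats::residuals(fit))
  if (scale > 1e-9 * max(mean(abs(df$z)), 1e-12))
    fit <- suppressWarnings(MASS::rlm(form, data = df, maxit = 100))
  matrix(stats::predict(fit, df), ny, nx)
}

#' Fit and correct global photobleaching
#'
#' Fits the per-frame bulk intensity of each channel (the per-frame
#' median, which tracks the diffuse background and is insensitive to the
#' sparse bright puncta whose kinetics are the signal of interest) to a
#' mono-exponential decay `offset + amplitude * exp(-rate * t)` and
#' divides the above-offset signal of every frame by `exp(-rate * t)`,
#' flattening the per-frame bulk intensity over time. If the fit fails or
#' the decay rate pins at a bound the correction for that channel is
#' skipped with a warning.
#'
#' @param stack an [image_stack()] with at least 5 frames.
#' @param max_rate upper bound on the decay rate (1/s).
#' @return list with `stack` (corrected) and `model` (data frame per
#'   channel: `channel`, `amplitude`, `rate`, `offset`, `corrected`).
#' @export
correct_photobleaching <- function(stack, max_rate = 1) {
  validate_image_stack(stack)
  d <- dim(stack$data)
  if (d[1L] < 5L) stop("photobleach fit needs at least 5 frames")
  t_s <- (seq_len(d[1L]) - 1) * stack$frame_interval
  out <- stack
  rows <- vector("list", d[2L])
  for (ch in seq_len(d[2L])) {
    m <- apply(stack$data[, ch, , , drop = FALSE], 1, stats::median)
    med_frame <- apply(stack$data[, ch, , , drop = FALSE], c(3, 4),
                       stats::median)
    t_total <- max(t_s[length(t_s)], 1)
    rng <- max(m) - min(m)
    lin_slope <- stats::coef(stats::lm(m ~ t_s))[[2]]
    ok <- FALSE
    amp <- 0; rate <- 0; off <- mean(m)
    if (!has_background(med_frame) || lin_slope >= 0 ||
        rng <= 1e-12 * max(abs(m))) {
      # background-free stack or no net decay: nothing to correct
      ok <- TRUE
    } else {
      best <- NULL
      for (r0 in c(0.5, 2, 10) / t_total) {
        fit <- tryCatch(
          minpack.lm::nlsLM(m ~ offset + amplitude * exp(-rate * t_s),
                            start = list(offset = min(m), amplitude = rng,
                                         rate = r0),
                            lower = c(0, 0, 0),
                            upper = c(Inf, Inf, max_rate),
                            control = minpack.lm::nls.lm.control(maxiter = 200)),
          error = function(e) NULL)
        if (is.null(fit)) next
        sse <- sum(stats::residuals(fit)^2)
        if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
      }
      if (!is.null(best)) {
        co <- stats::coef(best$fit)
        amp <- co[["amplitude"]]; rate <- co[["rate"]]; off <- co[["offset"]]
        if (rate >= max_rate * 0.999) {
          warning("bleach rate pinned at bound for channel ",
                  stack$channel_names[ch], "; correction skipped")
        } else {
          ok <- TRUE
        }
      } else {
        warning("bleach fit failed for channel ", stack$channel_names[ch],
                "; correction skipped")
      }
    }
    if (ok && rate > 0) {
      for (t in seq_len(d[1L])) {
        decay <- exp(-rate * t_s[t])
        out$data[t, ch, , ] <-
          off + (stack$data[t, ch, , ] - off) / decay
      }
      out$data[out$data < 0] <- 0
    }
    rows[[ch]] <- data.frame(channel = stack$channel_names[ch],
                             amplitude = amp, rate = rate, offset = off,
                             corrected = ok)
  }
  list(stack = validate_image_stack(out), model = do.call(rbind, rows))
}

#' Subtract the diffuse cytosolic background
#'
#' Estimates a per-pixel local background for every frame with a median
#' filter whose radius is much larger than the spot diameter (default
#' 2.5 um, ten times the 0.25 um spot radius) and subtracts it, clipping
#' negatives to zero. Diffraction-limited spots survive with their
#' integrated intensity preserved to within a few percent.
#'
#' @param stack an [image_stack()].
#' @param radius_um background median-filter radius (um); must exceed twice
#'   the spot radius.
#' @param spot_radius_um nominal spot radius used only for the sanity check.
#' @return background-subtracted `image_stack`.
#' @export
subtract_cytosol <- function(stack, radius_um = 2.5,
                             spot_radius_um = 0.25) {
  validate_image_stack(stack)
  if (radius_um <= 2 * spot_radius_um)
    stop("background radius must be much larger than the spot radius")
  r_px <- max(2L, as.integer(round(radius_um / stack$pixel_size)))
  d <- dim(stack$data)
  out <- stack
  for (t in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      frame <- stack$data[t, ch, , ]
      # frames with no appreciable diffuse background (e.g. already
      # subtracted) pass through, keeping the correction idempotent
      if (max(frame) > 0 && !has_background(frame)) next
      bg <- median_background(frame, r_px)
      out$data[t, ch, , ] <- pmax(frame - bg, 0)
    }
  }
  out
}

# Large-radius median background: a running median with windows truncated
# at the image border (no padding bias), evaluated on a block-downsampled
# grid for speed and bilinearly interpolated back to full resolution. The
# background is smooth by assumption, so downsampling loses nothing, and
# the block median over many blocks stays robust to bright spots.
median_background <- function(frame, r_px) {
  mx <- max(frame)
  if (mx <= 0) return(matrix(0, nrow(frame), ncol(frame)))
  ny <- nrow(frame); nx <- ncol(frame)
  r_px <- min(r_px, (min(ny, nx) - 1L) %/% 2L - 1L)
  k <- max(1L, r_px %/% 8L)              # block edge in pixels
  nby <- ceiling(ny / k); nbx <- ceiling(nx / k)
  blocks <- matrix(0, nby, nbx)
  for (by in seq_len(nby)) {
    rows <- ((by - 1L) * k + 1L):min(by * k, ny)
    for (bx in seq_len(nbx)) {
      cols <- ((bx - 1L) * k + 1L):min(bx * k, nx)
      blocks[by, bx] <- mean(frame[rows, cols])
    }
  }
  rb <- max(1L, as.integer(round(r_px / k)))
  bg_blocks <- matrix(0, nby, nbx)
  for (by in seq_len(nby)) {
    ry <- max(1L, by - rb):min(nby, by + rb)
    for (bx in seq_len(nbx)) {
      rx <- max(1L, bx - rb):min(nbx, bx + rb)
      bg_blocks[by, bx] <- stats::median(blocks[ry, rx])
    }
  }
  # bilinear interpolation from block centres back to pixel resolution
  cy <- ((seq_len(nby) - 0.5) * k + 0.5)
  cx <- ((seq_len(nbx) - 0.5) * k + 0.5)
  py <- pmin(pmax(seq_len(ny), cy[1]), cy[nby])
  pxs <- pmin(pmax(seq_len(nx), cx[1]), cx[nbx])
  iy <- findInterval(py, cy, all.inside = TRUE)
  ix <- findInterval(pxs, cx, all.inside = TRUE)
  fy <- (py - cy[iy]) / (cy[iy + 1L] - cy[iy])
  fx <- (pxs - cx[ix]) / (cx[ix + 1L] - cx[ix])
  top <- bg_blocks[iy, ix] * (1 - fx[col(matrix(0, ny, nx))]) +
    bg_blocks[iy, ix + 1L] * fx[col(matrix(0, ny, nx))]
  bot <- bg_blocks[iy + 1L, ix] * (1 - fx[col(matrix(0, ny, nx))]) +
    bg_blocks[iy + 1L, ix + 1L] * fx[col(matrix(0, ny, nx))]
  top * (1 - fy[row(top)]) + bot * fy[row(bot)]
}
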