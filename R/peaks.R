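#' Find peaks in a 1-d intensity profile
#'
#' Local-maximum detection with the selection rules used for filament-
#' bundle quantification: a candidate must exceed a minimum topographic
#' prominence (evaluated within a window around the peak), a minimum width
#' (measured at half prominence, by linear interpolation), and surviving
#' peaks closer together than a minimum distance are suppressed in favour
#' of the higher one. Plateau maxima are reported at their centre.
#'
#' @param position positions along the profile (um), strictly increasing.
#' @param intensity intensity values, same length.
#' @param min_prominence minimum prominence; `NA` defaults to 3x the MAD of
#'   the profile.
#' @param min_width_um minimum width at half prominence (um); `NA` defaults
#'   to 2 sample spacings.
#' @param min_distance_um minimum distance between retained peaks (um).
#' @param window_um window (full width, um) within which prominence bases
#'   are searched; `Inf` uses the whole profile.
#' @return data frame: `position_um`, `intensity`, `prominence`,
#'   `width_um`, ordered by position.
#' @export
find_profile_peaks <- function(position, intensity,
                               min_prominence = NA, min_width_um = NA,
                               min_distance_um = 1.0, window_um = Inf) {
  stopifnot(length(position) == length(intensity))
  n <- length(intensity)
  if (n == 0L) stop("empty profile")
  if (n < 3L)
    return(data.frame(position_um = numeric(0), intensity = numeric(0),
                      prominence = numeric(0), width_um = numeric(0)))
  if (is.unsorted(position, strictly = TRUE))
    stop("positions must be strictly increasing")
  spacing <- stats::median(diff(position))
  if (is.na(min_prominence))
    min_prominence <- 3 * stats::mad(intensity)
  if (is.na(min_width_um)) min_width_um <- 2 * spacing
  cand <- plateau_maxima(intensity)
  if (!length(cand))
    return(data.frame(position_um = numeric(0), intensity = numeric(0),
                      prominence = numeric(0), width_um = numeric(0)))
  prom <- vapply(cand, function(i)
    peak_prominence(position, intensity, i, window_um), numeric(1))
  keep <- prom >= min_prominence & prom > 0
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand)) {
    width <- vapply(seq_along(cand), function(k)
      peak_width(position, intensity, cand[k], prom[k]), numeric(1))
    keep <- width >= min_width_um
    cand <- cand[keep]; prom <- prom[keep]; width <- width[keep]
  } else {
    width <- numeric(0)
  }
  # min-distance suppression: keep higher peaks first
  if (length(cand) > 1L && is.finite(min_distance_um)) {
    ord <- order(intensity[cand], decreasing = TRUE)
    kept <- integer(0)
    for (k in ord) {
      if (!length(kept) ||
          all(abs(position[cand[k]] - position[cand[kept]]) >=
              min_distance_um))
        kept <- c(kept, k)
    }
    kept <- sort(kept)
    cand <- cand[kept]; prom <- prom[kept]; width <- width[kept]
  }
  data.frame(position_um = position[cand], intensity = intensity[cand],
             prominence = prom, width_um = width)
}

# Indices of local maxima; a flat plateau bounded by lower values counts
# once, at its centre sample.
plateau_maxima <- function(x) {
  n <- length(x)
  d <- diff(x)
  out <- integer(0)
  i <- 1L
  while (i < n) {
    if (d[i] > 0) {
      j <- i + 1L
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j == n || x[j + 1L] < x[j])
        out <- c(out, (i + 1L + j) %/% 2L)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  out
}

# Topographic prominence of peak i, with bases searched within window_um.
peak_prominence <- function(position, x, i, window_um = Inf) {
  n <- length(x)
  half <- window_um / 2
  lo <- if (is.finite(half)) which(position >= position[i] - half)[1] else 1L
  hi <- if (is.finite(half))
    utils::tail(which(position <= position[i] + half), 1L) else n
  # walk left until a strictly higher sample (or window edge)
  left_min <- x[i]
  j <- i - 1L
  while (j >= lo && x[j] <= x[i]) {
    left_min <- min(left_min, x[j])
    j <- j - 1L
  }
  if (j < lo) left_min <- min(x[lo:i])
  right_min <- x[i]
  j <- i + 1L
  while (j <= hi && x[j] <= x[i]) {
    right_min <- min(right_min, x[j])
    j <- j + 1L
  }
  if (j > hi) right_min <- min(x[i:hi])
  x[i] - max(left_min, right_min)
}

# Width at half prominence by linear interpolation of the crossings.
peak_width <- function(position, x, i, prom) {
  level <- x[i] - prom / 2
  n <- length(x)
  xl <- position[1]; xr <- position[n]
  j <- i
  while (j > 1L && x[j - 1L] > level) j <- j - 1L
  if (j > 1L) {
    f <- (x[j] - level) / (x[j] - x[j - 1L])
    xl <- position[j] - f * (position[j] - position[j - 1L])
  }
  j <- i
  while (j < n && x[j + 1L] > level) j <- j + 1L
  if (j < n) {
    f <- (x[j] - level) / (x[j] - x[j + 1L])
    xr <- position[j] + f * (position[j + 1L] - position[j])
  }
  xr - xl
}

#' Quantify filament bundles along a line profile
#'
#' Runs [find_profile_peaks()] on an intensity profile drawn along (or
#' adjacent to) a bead trajectory — either sampled from a movie or
#' hand-annotated and imported as CSV (`position_um`, `intensity`) — and
#' summarizes the bundle count and the maximum bundle peak intensity.
#'
#' @param profile data frame with `position_um` and `intensity`.
#' @inheritParams find_profile_peaks
#' @return list: `peaks` (data frame), `n_peaks`, `max_intensity`
#'   (`NA` when no peak passes the rules).
#' @export
bundle_quantification <- function(profile, min_prominence = NA,
                                  min_width_um = NA, min_distance_um = 1.0,
                                  window_um = Inf) {
  stopifnot(all(c("position_um", "intensity") %in% names(profile)))
  peaks <- find_profile_peaks(profile$position_um, profile$intensity,
                              min_prominence = min_prominence,
                              min_width_um = min_width_um,
                              min_distance_um = min_distance_um,
                              window_um = window_um)
  list(peaks = peaks, n_peaks = nrow(peaks),
       max_intensity = if (nrow(peaks)) max(peaks$intensity) else NA_real_)
}

#' Sample an intensity profile along a bead trajectory
#'
#' Samples the movie intensity along the straight line through the
#' trajectory (optionally offset perpendicular to it, as for hand-drawn
#' profiles adjacent to a comet tail) in a chosen frame.
#'
#' @param stack single-channel [image_stack()].
#' @param track bead positions (`frame`, `x_um`, `y_um`).
#' @param frame 0-based frame to sample.
#' @param offset_um perpendicular offset of the profile line (um).
#' @param step_um sampling step (um); default half a pixel.
#' @return data frame `position_um` (distance from trajectory start),
#'   `intensity`.
#' @export
trajectory_profile <- function(stack, track, frame, offset_um = 0,
                               step_um = NULL) {
  validate_image_stack(stack)
  px <- stack$pixel_size
  if (is.null(step_um)) step_um <- px / 2
  o <- order(track$frame)
  track <- track[o, ]
  n <- nrow(track)
  hx <- track$x_um[n] - track$x_um[1]
  hy <- track$y_um[n] - track$y_um[1]
  nrm <- sqrt(hx^2 + hy^2)
  if (nrm < 1e-9) stop("trajectory has no net displacement")
  hx <- hx / nrm; hy <- hy / nrm
  s <- seq(0, nrm, by = step_um)
  xs <- track$x_um[1] + s * hx - offset_um * hy
  ys <- track$y_um[1] + s * hy + offset_um * hx
  d <- dim(stack$data)
  w_um <- (d[4L] - 1) * px; h_um <- (d[3L] - 1) * px
  inside <- xs >= 0 & xs <= w_um & ys >= 0 & ys <= h_um
  data.frame(position_um = s[inside],
             intensity = bilinear_sample(stack$data[frame + 1L, 1L, , ],
                                         xs[inside] / px + 1,
                                         ys[inside] / px + 1))
}
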