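#' ImageStack: a time-lapse fluorescence stack with acquisition metadata
#'
#' The central image container of the package: a 4-d intensity array ordered
#' time x channel x row x column, together with the pixel pitch (micrometres
#' per pixel) and the inter-frame interval (seconds). Intensities are in
#' arbitrary fluorescence units and must be finite and non-negative.
#'
#' Coordinate convention (fixed across the package): frames are 0-based in
#' spot records, positions are in micrometres with the origin at the centre
#' of pixel (1,1); `x` runs along columns, `y` along rows, so
#' `x = (col - 1) * pixel_size`.
#'
#' @param data numeric array, `T x C x Y x X`. A 3-d array is promoted to a
#'   single-channel stack, a matrix to a single-frame single-channel stack.
#' @param pixel_size pixel pitch in micrometres (> 0).
#' @param frame_interval time between frames in seconds (> 0).
#' @param channel_names character vector, one label per channel.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size, frame_interval,
                        channel_names = NULL) {
  if (is.matrix(data)) dim(data) <- c(1L, 1L, dim(data))
  if (length(dim(data)) == 3L) {
    d <- dim(data)
    dim(data) <- c(d[1L], 1L, d[2L], d[3L])
  }
  if (length(dim(data)) != 4L)
    stop("`data` must be a T x C x Y x X array")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[2L]))
  x <- structure(
    list(data = data, pixel_size = pixel_size,
         frame_interval = frame_interval,
         channel_names = as.character(channel_names)),
    class = "image_stack")
  validate_image_stack(x)
}

#' @rdname image_stack
#' @param x an `image_stack`.
#' @export
validate_image_stack <- function(x) {
  stopifnot(inherits(x, "image_stack"))
  if (!is.numeric(x$pixel_size) || length(x$pixel_size) != 1L ||
      !is.finite(x$pixel_size) || x$pixel_size <= 0)
    stop("pixel_size must be a single positive number (um/pixel)")
  if (!is.numeric(x$frame_interval) || length(x$frame_interval) != 1L ||
      !is.finite(x$frame_interval) || x$frame_interval <= 0)
    stop("frame_interval must be a single positive number (s)")
  if (length(x$channel_names) != dim(x$data)[2L])
    stop("length(channel_names) must equal the channel axis length")
  if (anyNA(x$data) || any(!is.finite(x$data)))
    stop("intensities must be finite")
  if (any(x$data < 0))
    stop("intensities must be >= 0")
  x
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d frames x %d channels x %d x %d px | %.4g um/px, %.4g s/frame\n",
    d[1], d[2], d[3], d[4], x$pixel_size, x$frame_interval))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[1L]
n_channels <- function(stack) dim(stack$data)[2L]

#' Extract one frame of one channel as a Y x X matrix
#'
#' @param stack an `image_stack`.
#' @param t 1-based frame index.
#' @param channel channel name or 1-based index.
#' @return numeric matrix (rows = y, columns = x).
#' @export
get_frame <- function(stack, t, channel = 1L) {
  ci <- resolve_channel(stack, channel)
  stack$data[t, ci, , , drop = TRUE]
}

resolve_channel <- function(stack, channel) {
  if (is.character(channel)) {
    ci <- match(channel, stack$channel_names)
    if (is.na(ci)) stop("channel not found: ", channel)
    ci
  } else {
    ci <- as.integer(channel)
    if (ci < 1L || ci > n_channels(stack)) stop("channel index out of range")
    ci
  }
}

# ---- TIFF I/O --------------------------------------------------------------

#' Write an image stack to a multi-page 32-bit float TIFF
#'
#' Pages are ordered frame-major (frame 1 channel 1, frame 1 channel 2, ...).
#' Because baseline TIFF carries neither the pixel pitch nor the frame
#' interval in a portable way, acquisition metadata (dimensions, pixel_size,
#' frame_interval, channel_names, intensity scale) is written to a JSON
#' sidecar at `<path>.json`; [read_stack()] restores the stack losslessly to
#' single-float precision from the pair.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  validate_image_stack(stack)
  d <- dim(stack$data)
  scale <- max(stack$data, 1)
  pages <- vector("list", d[1L] * d[2L])
  k <- 1L
  for (t in seq_len(d[1L])) {
    for (c in seq_len(d[2L])) {
      pages[[k]] <- stack$data[t, c, , ] / scale
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(n_frames = d[1L], n_channels = d[2L],
               height = d[3L], width = d[4L],
               pixel_size = stack$pixel_size,
               frame_interval = stack$frame_interval,
               channel_names = as.list(stack$channel_names),
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' Metadata comes from the JSON sidecar when present; otherwise
#' `pixel_size` and `frame_interval` (and, for multi-channel stacks,
#' `n_channels`) must be supplied, or the read fails.
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval,channel_names,n_channels metadata
#'   overrides used when no sidecar is present.
#' @return an `image_stack`.
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL,
                       channel_names = NULL, n_channels = NULL) {
  if (!file.exists(path)) stop("cannot read stack: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
  side <- paste0(path, ".json")
  scale <- 1
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size
    if (is.null(frame_interval)) frame_interval <- meta$frame_interval
    if (is.null(channel_names)) channel_names <- meta$channel_names
    if (is.null(n_channels)) n_channels <- meta$n_channels
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
  }
  if (is.null(pixel_size) || is.null(frame_interval))
    stop("stack metadata missing: supply pixel_size and frame_interval ",
         "(no JSON sidecar found at ", side, ")")
  if (is.null(n_channels)) {
    n_channels <- if (!is.null(channel_names)) length(channel_names) else 1L
  }
  n_channels <- as.integer(n_channels)
  if (length(pages) %% n_channels != 0L)
    stop("page count ", length(pages),
         " is not a multiple of n_channels = ", n_channels)
  nt <- length(pages) %/% n_channels
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  data <- array(0, c(nt, n_channels, h, w))
  k <- 1L
  for (t in seq_len(nt)) {
    for (c in seq_len(n_channels)) {
      data[t, c, , ] <- pages[[k]] * scale
      k <- k + 1L
    }
  }
  image_stack(data, pixel_size, frame_interval, channel_names)
}
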