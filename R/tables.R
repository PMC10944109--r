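#' Typed CSV tables
#'
#' All tabular exchange in the pipeline goes through plain UTF-8 CSV with a
#' single header row, '.' decimal separator and one record per row.
#' [write_table()] writes a data frame at full double precision (values
#' round-trip through [read_table()] to better than 1e-9 relative error);
#' [read_table()] optionally enforces a column schema and fails naming any
#' missing column.
#'
#' @param records a data frame (homogeneous records).
#' @param path CSV path.
#' @return `path` invisibly (write) or a data frame (read).
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) stop("`records` must be a data frame")
  utils::write.csv(format_full_precision(records), path,
                   row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

format_full_precision <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), stringsAsFactors = FALSE, check.names = FALSE,
  col.names = names(df))
}

#' @rdname write_table
#' @param required_columns character vector; the read errors if any is
#'   absent from the file header.
#' @export
read_table <- function(path, required_columns = NULL) {
  if (!file.exists(path)) stop("cannot read table: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!is.null(required_columns)) {
    missing <- setdiff(required_columns, names(df))
    if (length(missing))
      stop("table ", path, " is missing required column(s): ",
           paste(missing, collapse = ", "))
  }
  df
}

# ---- Run configuration -----------------------------------------------------

#' Default run configuration
#'
#' One nested list holding every tunable of every stage, with defaults that
#' follow the published acquisition and analysis settings where those are
#' stated (detection blob diameter 0.5 um, quality threshold 5, median
#' prefilter on the Las17 channel only; linking max distance 0.5 um,
#' gap-closing distance 0.5 um, max frame gap 2; internalization threshold
#' 0.25 um; bead exclusion diameter 3.8 um; annulus radii 4 and 15 px with
#' 30 degree bins; bead movies at 70 s intervals). Values the source
#' methods leave open (pixel pitch, patch-movie frame interval, pairing
#' rule, peak-finder settings) are explicit configuration, never hard-coded
#' downstream.
#'
#' @return a named list; round-trips losslessly through
#'   [write_run_config()] / [read_run_config()].
#' @export
default_run_config <- function() {
  list(
    patch_movie = list(
      pixel_size_um = 0.065,       # 100x objective, sCMOS
      frame_interval_s = 1.0,
      channel_names = c("las17", "abp1")
    ),
    bead_movie = list(
      pixel_size_um = 0.325,       # 20x objective
      frame_interval_s = 70.0,
      channel_names = "actin"
    ),
    preprocess = list(
      illumination_poly_degree = 2L,
      bleach_min_frames = 5L,
      cytosol_radius_um = 2.5      # 10x the 0.25 um spot radius
    ),
    detection = list(
      diameter_um = 0.5,
      quality_threshold = 5,
      median_filter_channels = "las17"
    ),
    linking = list(
      max_link_um = 0.5,
      gap_close_um = 0.5,
      max_frame_gap = 2L
    ),
    curation = list(
      separation_um = 0.5
    ),
    pairing = list(
      max_distance_um = 0.5,
      max_time_gap_s = 10
    ),
    metrics = list(
      internalization_um = 0.25
    ),
    beads = list(
      max_diameter_um = 3.8,
      velocity_window_frames = 3L,
      annulus_r_in_px = 4,
      annulus_r_out_px = 15,
      angular_bin_deg = 30,
      min_speed_um_min = 0.05
    ),
    peaks = list(
      min_prominence = NA_real_,   # NA -> 3x profile MAD
      min_width_um = NA_real_,     # NA -> 2 px
      min_distance_um = 1.0,
      prominence_window_um = Inf
    ),
    biochem = list(
      receptor_total_uM = 0.05,
      kd_bounds_uM = c(1e-6, 1e3),
      kd_starts_uM = c(0.01, 0.1, 1),
      mpr_window_points = 5L
    ),
    seed = 1L
  )
}

#' Read / write run configuration as YAML
#'
#' @param config a configuration list as from [default_run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 17L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path)
  yaml::read_yaml(path)
}
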