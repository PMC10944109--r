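#!/usr/bin/env Rscript
# Aggregate the stage outputs into a single report directory with a
# manifest, and draw the headline figures (molecules-versus-time, bead
# velocity, angular polar profile) when ggplot2 is available.
#
# Reads  results/{patches,beads,biochem}/*.csv
# Writes results/report/*.csv, results/report/manifest.json,
#        scratch/figures/*.png

suppressMessages(library(actinquant))

out <- "results/report"
read_if <- function(path) if (file.exists(path)) read_table(path) else NULL

gather <- function(dir, prefix) {
  files <- list.files(dir, pattern = paste0("^", prefix, ".*\\.csv$"),
                      full.names = TRUE)
  if (!length(files)) return(NULL)
  do.call(rbind, lapply(files, function(f) {
    df <- read_table(f)
    df$source <- sub("\\.csv$", "", basename(f))
    df
  }))
}

outputs <- list(
  strain_summary = read_if("results/patches/strain_summary.csv"),
  patch_metrics = rbind(read_if("results/patches/metrics_control.csv"),
                        read_if("results/patches/metrics_site_mutant.csv")),
  comparison_accum_rate = read_if("results/patches/comparison_accum_rate.csv"),
  bead_velocity = gather("results/beads", "velocity"),
  bead_relpoly = gather("results/beads", "relpoly"),
  bead_angular = gather("results/beads", "angular"),
  bead_bundles = gather("results/beads", "bundles"),
  binding_fits = read_if("results/biochem/binding_fits.csv"),
  mpr_titration = read_if("results/biochem/mpr.csv"),
  titration_fit = read_if("results/biochem/titration_fit.csv"),
  percent_activity = read_if("results/biochem/percent_activity.csv"))

manifest <- build_report(outputs, out, config = default_run_config(),
                         seed = 1L)
message("manifest: ", manifest)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  figdir <- "scratch/figures"
  dir.create(figdir, recursive = TRUE, showWarnings = FALSE)
  avg <- rbind(
    transform(read_table("results/patches/avg_abp1_trace_control.csv"),
              strain = "control"),
    transform(read_table("results/patches/avg_abp1_trace_site_mutant.csv"),
              strain = "site_mutant"))
  ggsave(file.path(figdir, "avg_abp1_molecules.png"),
         ggplot(avg, aes(t_rel_s, mean, colour = strain)) +
           geom_line() +
           geom_ribbon(aes(ymin = mean - sd, ymax = mean + sd,
                           fill = strain), alpha = 0.2, colour = NA) +
           labs(x = "time from Abp1 maximum (s)",
                y = "Abp1 molecules (mean +/- SD)") +
           theme_classic(),
         width = 5, height = 3.5, dpi = 150)
  if (!is.null(outputs$bead_velocity)) {
    ggsave(file.path(figdir, "bead_velocity.png"),
           ggplot(outputs$bead_velocity,
                  aes(frame * 70 / 60, velocity_um_min, colour = source)) +
             geom_line() +
             labs(x = "reaction time (min)", y = "velocity (um/min)") +
             theme_classic(),
           width = 5, height = 3.5, dpi = 150)
  }
  if (!is.null(outputs$bead_angular)) {
    ggsave(file.path(figdir, "angular_intensity.png"),
           ggplot(outputs$bead_angular,
                  aes(bin_mid_deg, mean, colour = source)) +
             geom_line() + coord_polar(start = -pi / 2, direction = -1) +
             labs(x = "angle from direction of motion (deg)",
                  y = "mean intensity (a.u.)") +
             theme_classic(),
           width = 5, height = 4.5, dpi = 150)
  }
  message("figures under ", figdir)
}
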