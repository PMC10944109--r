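#!/usr/bin/env Rscript
# Simulate every data class the pipeline analyses, with known ground truth.
#
# Conditions emulated (synthetic throughout):
#   patches/control        -- wild-type-like endocytosis: ~783 Abp1 molecules
#                             at peak, 97% internalization, 35.9% Las17-early
#   patches/site_mutant    -- an activator-binding-site-defective phenotype:
#                             slower Abp1 accumulation, more Las17, reduced
#                             internalization
#   beads/*                -- comet-tail motility at 1 um/min (control) and a
#                             slower, more bundled mutant-like condition
#   pyrene titration       -- logistic polymerization traces over an
#                             activator titration
#   depletion titrations   -- fraction-bound data at the published WT-Las17
#                             and Myo5 designs
#
# Image stacks (binary TIFF) go to scratch/, truth tables (CSV) to results/.

suppressMessages(library(actinquant))

seed <- 1L
res <- "results/simulated"
scr <- "scratch/simulated"
dir.create(res, recursive = TRUE, showWarnings = FALSE)
dir.create(scr, recursive = TRUE, showWarnings = FALSE)

message("-- patch movies")
patch_conditions <- list(
  control = patch_sim_params(seed = seed),
  control_calib = patch_sim_params(seed = seed + 100L),
  site_mutant = patch_sim_params(
    seed = seed + 200L,
    accum_range_s = c(12, 18),          # slower actin assembly
    peak_las17_mean = 320,              # Las17 over-accumulates
    p_internalized = 0.55)              # internalization defect
)
for (nm in names(patch_conditions)) {
  sim <- generate_patch_movie(patch_conditions[[nm]])
  write_stack(sim$stack, file.path(scr, paste0("patches_", nm, ".tif")))
  write_table(sim$truth, file.path(res, paste0("patches_", nm, "_truth.csv")))
  message("  ", nm, ": ", nrow(sim$truth), " patches, ",
          round(100 * mean(sim$truth$internalized)), "% internalized (truth)")
}

message("-- bead movies")
bead_conditions <- list(
  control = bead_sim_params(seed = seed, speed_um_min = 1.0,
                            n_bundles = 2, bundle_peaks = c(180, 210)),
  site_mutant = bead_sim_params(seed = seed + 1L, speed_um_min = 0.5,
                                tail_amp = 90,
                                n_bundles = 3,
                                bundle_peaks = c(300, 360, 330))
)
for (nm in names(bead_conditions)) {
  sim <- generate_bead_movie(bead_conditions[[nm]])
  write_stack(sim$stack, file.path(scr, paste0("beads_", nm, ".tif")))
  write_table(sim$truth, file.path(res, paste0("beads_", nm, "_truth.csv")))
  write_table(sim$bundles,
              file.path(res, paste0("beads_", nm, "_bundles_truth.csv")))
  message("  ", nm, ": speed ", bead_conditions[[nm]]$speed_um_min,
          " um/min, ", nrow(sim$bundles), " bundles")
}

message("-- pyrene traces (activator titration)")
# MPR rises hyperbolically with activator; emulate by scaling the logistic
# rate with a saturation curve (K1/2 300 nM, basal rate included)
las17_nM <- c(0, 75, 150, 300, 600, 1200, 2500)
mpr_target <- 0.4 + 7.0 * las17_nM / (300 + las17_nM)  # nM/s at each point
traces <- lapply(seq_along(las17_nM), function(i) {
  r <- 4 * mpr_target[i] / 2900
  t_half <- 250 + 1200 / (1 + las17_nM[i] / 100)
  t_max <- t_half + 7 / r            # every trace reaches its plateau
  p <- pyrene_sim_params(r = r, t_half = t_half,
                         noise_sd = 2, seed = seed + i,
                         dt = max(2, round(t_max / 1500)), t_max = t_max)
  tr <- generate_pyrene_trace(p)
  tr$las17_nM <- las17_nM[i]
  tr
})
write_table(do.call(rbind, traces), file.path(res, "pyrene_traces.csv"))
write_table(data.frame(las17_nM = las17_nM, mpr_true_nM_per_s = mpr_target),
            file.path(res, "pyrene_truth.csv"))

message("-- depletion titrations")
for (nm in c("wt_las17", "myo5")) {
  d <- depletion_design(nm)
  d$noise_sd <- 0.01
  d$seed <- seed
  write_table(generate_depletion_data(d),
              file.path(res, paste0("depletion_", nm, ".csv")))
}
message("done; truth tables under ", res, ", stacks under ", scr)
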