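Package: actinquant
Title: Quantitative Analysis of Arp2/3-Nucleated Actin Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying branched actin network assembly driven by
    Arp2/3 complex and its WASP-family activators. Covers single-particle
    tracking of endocytic actin patches in two-channel live-cell movies
    (spot detection, linking, curation, channel pairing, trajectory
    alignment, fluorescence-to-molecule calibration, accumulation and
    internalization metrics), actin comet-tail bead-motility quantification
    (bead tracking, velocity, surface polymerization rate, angular intensity
    profiles, filament-bundle peak detection), and the accompanying
    biochemistry (tight-binding quadratic ligand-depletion fits for K_D,
    pyrene-actin maximum polymerization rates, saturation fits, percent
    activity). A seed-deterministic synthetic-data generator emulates each
    data class so every analysis stage is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    MASS,
    jsonlite,
    minpack.lm,
    multcomp,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
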