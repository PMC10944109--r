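---
title: "Quantifying Arp2/3-driven actin networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Arp2/3-driven actin networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`actinquant` quantifies three experimental readouts of branched actin
network assembly by Arp2/3 complex and its WASP-family activators (in
budding yeast: Las17, with Myo5 and Abp1 as further nucleation-promoting
factors):

1. **Endocytic patch dynamics** in two-channel live-cell movies
   (mNG-Las17 / Abp1-TagRFP-T): spot detection, linking, curation,
   channel pairing, alignment, fluorescence-to-molecule calibration, and
   per-event kinetic and internalization metrics.
2. **Reconstituted bead motility**: comet-tail-propelled bead tracking,
   velocity, the relative actin polymerization rate at the bead surface,
   angular intensity distributions around the bead, and filament-bundle
   peak quantification.
3. **Solution biochemistry**: fraction-bound titrations fit with the
   quadratic tight-binding (ligand-depletion) equation, pyrene-actin
   maximum polymerization rates (MPR), the MPR saturation fit, and
   percent activity of mutant complexes.

A synthetic-data generator produces each data class with exact ground
truth, making every analysis stage a recovery experiment. This vignette
records the models, the parameters that matter, and the design decisions
made where the methods were genuinely open.

# The biochemical models

## Quadratic tight-binding (ligand depletion)

In the supernatant-depletion assay, activator-coated beads at total
ligand (dimer) concentration $L$ deplete the Arp2/3 complex (total $R$)
from solution. Because $R$ (50 nM) is comparable to $K_D$, free-ligand
approximations fail and the bound fraction follows the exact quadratic
solution of the binding equilibrium:

$$\frac{[LR]}{[R]} \;=\; \frac{L + R + K_D - \sqrt{(L + R + K_D)^2 - 4LR}}{2R}.$$

`quadratic_fraction()` evaluates this (guarding the analytically
non-negative discriminant against rounding), and `fit_kd()` estimates
$K_D$ by nonlinear least squares with **R fixed at its known design
concentration** — a deliberate choice: the receptor total is a pipetted
quantity, and freeing it would absorb titration noise into a parameter
that is not actually unknown. The fit is multi-started at
$K_D \in \{0.01, 0.1, 1\}$ µM within bounds $[10^{-6}, 10^3]$ µM, keeping
the best sum of squares; a fit pinned at a bound is flagged. The two
reference designs (`depletion_design()`) are 8 log-spaced dimer
concentrations, 16 nM–2.06 µM at affinity 0.16 µM (wild-type LZ-Las17)
and 25 nM–1.6 µM at 0.13 µM (LZ-Myo5-CA), both with 50 nM complex.

The measured quantity itself is `fraction_bound()`:
$F_b = (\theta^0 - \text{supernatant})/\theta^0$, clipped to $[0,1]$.

## Maximum polymerization rate

Pyrene-actin fluorescence is anchored linearly between a baseline (no
polymer) and a plateau (fully polymerized pool) to convert RFU to nM
polymer (`convert_rfu_to_polymer()`); the conversion constants of the
original instrument are not recoverable, so baseline/plateau anchoring is
the package's convention, with the plateau defaulting to the mean of the
final 5% of the trace (the trace must therefore reach saturation). The
MPR is the maximum over time of the local least-squares slope in a
sliding window (`max_polymerization_rate()`, default 5 points). The
5-point default balances noise against curvature bias at typical cuvette
sampling; it is configurable because finely-sampled traces benefit from
wider windows (the analysis drivers use 21 points at ~1500 samples per
trace). The synthetic oracle is a logistic polymer curve
$P(t) = P_\text{total}/(1 + e^{-r(t - t_{1/2})})$, whose maximum slope is
analytically $rP_\text{total}/4$ at $t_{1/2}$; the estimator is required
to land within 1% of it on noiseless data.

Saturation of the MPR with activator follows
$Y = Y_\text{max}\,[\text{Las17}]/(K_{1/2} + [\text{Las17}]) + Y_o$
(`fit_mpr_titration()`, non-negative bounds, multi-start on $K_{1/2}$),
and mutant activity is
$\%\text{activity} = (MPR_\text{mut} - MPR_\text{actin}) /
(MPR_\text{WT} - MPR_\text{actin}) \times 100$
(`percent_activity()`), which is invariant to any common rescaling of the
three rates.

# The patch pipeline

## Preprocessing

Order is fixed: illumination → photobleaching → cytosolic background.

* **Illumination** (`correct_illumination()`): a smooth multiplicative
  field is estimated from the temporal median frame by a Huber-robust
  quadratic polynomial surface, normalized to mean 1, and divided out.
  A polynomial surface was chosen over FFT-based Gaussian smoothing
  because circular boundary handling corrupts exactly the common case of
  a lateral gradient; the quadratic captures lamp/objective vignetting
  without boundary artifacts.
* **Photobleaching** (`correct_photobleaching()`): the per-frame
  *median* intensity (the diffuse bulk, insensitive to sparse bright
  puncta whose kinetics are the signal of interest) is fit to
  $o + a e^{-kt}$; above-offset signal is divided by $e^{-kt}$. Failed
  fits or rates pinned at the bound skip the correction with a warning.
* **Cytosol** (`subtract_cytosol()`): a per-pixel local background —
  a running median with windows truncated at the image border, evaluated
  on a block-downsampled grid and bilinearly upsampled — is subtracted
  and negatives are clipped. The default radius, 2.5 µm, is ten times
  the 0.25 µm spot radius, so diffraction-limited spots pass through with
  their integrated intensity preserved to within a few percent.

All three corrections skip inputs with no appreciable diffuse background
(median of the temporal-median frame below three times its spatial MAD).
This makes the pipeline idempotent — applying it twice changes the output
by well under 1% — and is the honest behaviour on already-corrected data.

## Detection, linking, curation

`detect_spots()` is Laplacian-of-Gaussian blob detection with
$\sigma = d/(2\sqrt{2})$ for the 0.5 µm estimated blob diameter, an
optional 3×3 median prefilter (used for the Las17 channel, which is
dimmer and noisier), strict 8-neighbour maxima, sub-pixel refinement by
intensity-weighted centroid, and disk photometry with an annulus-median
background. The **quality score** is the scale-normalized LoG response
divided by a robust (MAD) estimate of the response noise; the default
threshold of 5 therefore reads "five sigma above background texture".
This is a *calibration* of the published detector-scaled threshold of 5,
not a numerical equivalence — the original score lives in another
implementation's units. Raising the threshold can only remove
detections (a tested monotonicity property).

`link_spots()` is greedy nearest-neighbour frame-to-frame linking (0.5 µm
maximum), followed by gap closing across at most 2 missing frames within
0.5 µm — the published tracking settings. `curate_tracks()` applies the
published selection criteria: complete lifetime inside the movie, minimum
0.5 µm separation from any concurrent track (the published criterion
states "well separated" without a distance; 0.5 µm, one blob diameter, is
the package default), and an optional region-of-interest mask standing in
for the manual equatorial-cortex selection.

## Pairing, alignment, molecules, metrics

The pairing rule is not stated in the source methods, so it is an
explicit, auditable package choice: tracks pair one-to-one by increasing
distance between time-averaged positions, within 0.5 µm, with lifetimes
overlapping or abutting within 10 s; unpaired tracks are reported
(`pair_channels()`). Events are aligned with $t = 0$ at the frame of
maximum Abp1 corrected intensity, earliest frame on ties
(`align_events()`), which lets molecule-versus-time traces be averaged
across events.

`to_molecules()` multiplies corrected intensity by the ratio of a
literature reference count to the control-strain average maximum
corrected intensity, per channel, computed with the same pipeline
settings. The reference counts are inputs, not package constants. The
ratio construction makes the calibration invariant to camera gain — a
tested property.

`compute_metrics()` implements the published per-event quantities:
accumulation and deaccumulation rates as the least-squares slope over
*all* points from first appearance to the maximum and from the maximum to
the last measurable frame (deaccumulation rates are therefore negative);
assembly time as time of maximum minus time of first appearance (Abp1);
maximum displacement from the first detected Abp1 position; and the
internalization flag, *strictly* greater than 0.25 µm (an event at
exactly 0.25 µm is not internalized). The Las17-early flag needed two
operationalizations the source leaves informal: "Las17 begins to
deaccumulate" is the argmax of the Las17 molecule trace, and "actin
assembly detected" is the first frame of detectable Abp1 signal (above
the detection threshold). A phase with fewer than three points leaves
its rate `NA` with a flag.

# The bead pipeline

Beads are located per frame as the intensity-weighted centroid of the
thresholded bright region (the fluorescent actin shell is radially
symmetric about the bead centre), with components dimmer than 80% of the
frame's dynamic range rejected as tail/bundle debris; tracker-exported
position tables are accepted interchangeably. Exclusion rules follow the
published criteria: crossing another bead (closest approach under the sum
of radii), diameter above 3.8 µm, or a trajectory not fully inside the
field (`filter_beads()`).

Velocity is central-difference displacement converted to µm/min with
optional 3-frame boxcar smoothing — whether the published per-time-point
velocity was instantaneous or window-averaged is unstated, so the window
is configuration. The line profile along the motion axis yields leading
and trailing peaks bracketing the central valley; the **relative
polymerization rate** is velocity × trailing-peak intensity, the trailing
peak being where the actin maximum sits at the rear bead surface. The
metric is homogeneous in image intensity (gain-dependent), so it is
comparable only within one imaging calibration.

`angular_intensity()` measures pixels whose centre falls within an
annulus of 4–15 *pixels* (radii deliberately kept in pixels, as
published, with the pixel size stored so µm equivalents are reportable)
around the bead, binned every 30° relative to the per-frame motion
direction (3-frame displacement; whole-track direction below
0.05 µm/min). Bins tile 360° exactly with edges at 0°, 30°, …; the bin
*means* are offset-linear and uniform on flat images, and the bin pixel
counts tile the annulus — both tested invariants.

`find_profile_peaks()` / `bundle_quantification()` implement the
peak-selection rules for filament bundles: topographic prominence
evaluated within a window, width at half prominence by linear
interpolation, and minimum-distance suppression keeping the higher peak.
Defaults (prominence 3× profile MAD, width ≥ 2 samples, distance 1 µm)
are configuration, since the published analysis exposes them as free
parameters. The implementation is verified against a brute-force oracle
(enumerate all local maxima, apply the rules by exhaustive scans) on
random profiles.

# Group comparisons

`anova_dunnett()` reproduces the statistical treatment used throughout:
ordinary one-way ANOVA with Dunnett many-to-one comparisons against the
designated control. Dunnett critical values come from the multivariate-t
distribution of the simultaneous contrasts, evaluated by randomized
quasi-Monte Carlo; a seed argument makes the adjusted p values
reproducible. Unadjusted per-comparison p values are reported alongside
and can never exceed the adjusted ones (tested).

# The synthetic generator: what it emulates, and what it does not

`generate_patch_movie()` renders patches as pixel-integrated Gaussians
whose integrated intensity is gain × molecules(t), with **piecewise-linear
triangle kinetics** (accumulate → peak → deaccumulate). Triangle
kinetics were chosen deliberately: the analysis measures rates as
straight-line slopes, so generator and analyzer share an exact
expectation (accumulation rate = peak / accumulation duration), making
recovery tests sharp. Internalized patches translate toward the cell
interior by their drawn displacement during deaccumulation; Las17 stays
at its origin, as at the membrane. A global exponential bleach, a static
linear illumination gradient, camera offset and Gaussian read noise
complete the forward model.

Default study conditions: 75 frames at 1 s (the inter-frame interval of
the live-cell acquisitions is not stated; 1 s is configuration),
0.065 µm/px, PSF σ 0.1 µm, 24 patches per movie, Abp1 peaks around 783
molecules (the control-strain average maximum), Las17 peaks around 250
molecules (an order-of-magnitude literature-scale choice; the source
prints no Las17 count), 97% internalization with displacement
U(0.35, 0.60) µm against U(0.03, 0.12) µm for failed events, and 35.9%
Las17-early events. Camera gain 2 a.u./molecule with read noise 3 a.u.
puts the Abp1 peak-pixel SNR near 20 and the Las17 channel near 5 —
deliberately asymmetric, as in the real two-fluorophore data. Molecule
count noise at endocytic sites is not characterized in the source;
these are placeholders stated once and not tuned.

What the generator does **not** emulate: cytosolic autofluorescence pools,
patch splitting/merging, z-drift, rolling-shutter artifacts, non-Gaussian
camera noise, or mechanistic actin kinetics (the pyrene logistic is a
phenomenological stand-in chosen for its analytic maximum slope). Passing
recovery tests therefore demonstrates correctness of the measurement
chain under controlled conditions, not robustness to every real-data
pathology.

`generate_bead_movie()` renders an actin shell at the bead surface, an
exponential comet tail behind it, and optional transverse bundle streaks
that appear once the bead has passed; 0.325 µm/px and 70 s intervals
match the published acquisition, and 1 µm/min is the late-reaction
steady-state speed. `generate_depletion_data()` uses the quadratic
binding model itself as the forward model with multiplicative noise —
so a K~D~ refit is a true round trip through the published equation.

# Numerical choices and degenerate inputs

* Positions are µm everywhere, origin at the centre of pixel (1,1),
  frames 0-based in spot tables; pixel units appear only inside
  detection internals and the annulus radii (kept in px as published).
* TIFF stacks are written as 32-bit float pages with a JSON metadata
  sidecar (pixel size, frame interval, channel names, intensity scale);
  round trips are exact to single precision. CSV/YAML round-trip at
  full double precision (better than 1e-9 relative).
* Ties at any maximum (alignment frame, phase boundaries) resolve to the
  earliest frame. Plateau maxima in profiles count once, at their
  centre.
* Degenerate inputs fail loudly: all-zero Abp1 traces cannot be aligned;
  single-frame tracks have no velocity; flat titrations flag an
  unidentifiable $K_{1/2}$; monotone-decreasing traces flag a
  non-positive MPR; non-monotone equilibration series are flagged.
* Problem sizes in the test suite (24-patch 128×128×75 movies, 100
  K~D~ replicates, 25 random peak profiles) were chosen so each property
  reflects the default study conditions while the whole suite stays
  desk-scale.

# Known limitations

* The fluorescence-to-molecule calibration is only as good as the
  literature reference counts supplied; the package treats them as
  opaque inputs.
* The bead tracker assumes the bead shell is the brightest structure;
  movies whose bundles rival the shell need tracker-exported positions
  (accepted by every downstream operator).
* The Las17-early operationalization depends on the detection threshold
  through "first detectable Abp1 frame"; the reported percentage should
  always be read together with the detection settings.
* Velocity at track ends uses one-sided differences, which doubles the
  noise variance of those two samples.
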