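---
title: "Quantitative retinal phenotyping with retphen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative retinal phenotyping with retphen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retphen)
```

# Scope

`retphen` quantifies the slow, rod-driven retinal degeneration phenotype of
mutant mice from four kinds of raw data: cone-arrestin-stained whole-mount
mosaics (automated cone counting), outer-nuclear-layer (ONL) row counts on
sections (survival and intraretinal variation), two-channel RPE tiles
stained for the tight-junction protein ZO-1 (barrier integrity), and
flash electroretinograms (function).  Every stage is paired with a
synthetic-data generator that produces ground-truthed inputs, so the whole
pipeline can be validated quantitatively without any microscope or
recording rig.

# Automated cone counting

## The chain

A counting field is a calibrated intensity grid (`FieldImage`), by default
223.8 × 167.6 µm at 0.32 µm/px.  `countField()` applies, in order:

1. **Binarization** — Otsu's threshold by default.  The method is
   parameter-free and well suited to the strongly bimodal histograms of
   arrestin-stained fields; a fixed threshold is used as fallback when the
   histogram is degenerate (blank field) and is available explicitly for
   calibrated rigs.
2. **Small-component filter** — connected components smaller than 2% of
   the average cone area are discarded as debris.  The average is
   self-calibrated per image (mean component area of the same mask, before
   filtering); a calibrated nominal area can be supplied instead.  The
   per-image choice keeps the rule scale-free across magnifications.
3. **Downsampling** — nearest-neighbour to `round(0.3 × dim)`.
   Nearest-neighbour sampling preserves binarity, and the sampling grid
   spans the full extent so border contacts survive.
4. **Watershed splitting** — touching inner segments merge into single
   components; marker-controlled watershed on a distance-transform height
   map separates them.
5. **Border exclusion** — components intersecting the right or bottom
   border are dropped, so cells straddling field edges are counted exactly
   once across adjacent fields.  Exclusion runs last, after watershed; a
   merged component that touches the border is excluded whole.

## Numerical choices that matter

*Watershed height map.*  At a 0.3 downsampling factor a cone profile is
only ~2.3 px in radius, and the distance transform of the coarse mask is
quantized to at most 3 levels — regional maxima of touching pairs become
indistinguishable and almost no pair splits.  The height map is therefore
the Euclidean distance transform of the *full-resolution* mask, sampled at
the downsampled grid.  The order of operations is unchanged (counting
still happens on the downsampled mask) but sub-pixel geometry survives:
for touching pairs at 1.1–1.5 radii separation the max-to-saddle gap is
1.3–2.6 full-resolution pixels, cleanly above the split tolerance.

*Split tolerance.*  0.5 distance units — half a pixel.  Below this,
maxima are indistinguishable from boundary-discretization ripple on a
single disk; above ~1.3 genuine pairs stop splitting.  Marker separation
is 0.6 × the nominal cone radius in downsampled pixels.

*Border bookkeeping.*  A component can graze the last row between sampled
columns; border contact is therefore also projected from the
full-resolution mask onto the downsampled labels, making the exclusion
exact rather than sampling-phase dependent.

*Coordinates.*  Row-major, row 1 at top; "right border" is the last
column, "bottom border" the last row.

## Validation statistic

`compareCounts()` reports the Pearson correlation between manual and
automated counts, per-image relative errors `(manual − automated) /
manual`, and accuracy `1 − mean(|error|)`.  On the standard synthetic
batch (50 fields, ~12,000 cones/mm², 10% touching pairs, noise SD 5% of
the blob peak) the chain reaches ≈97–98% accuracy; the residual error is
dominated by the most heavily overlapping pairs (separation near 1.1
radii), which merge into one profile that even careful manual counting
would disambiguate only from texture cues the generator does not model.

# Morphometry

Per-field density is `count / field area`; a retina's total is the mean
of its 16 per-field densities times the measured retinal area.  The
16-field scheme places fields at ±{0.2, 0.4, 0.6, 0.8} of the disk radius
along the two principal meridians — a concrete reading of "regularly
spaced from far periphery to the optic nerve head"; retinal area is an
input, measured on low-magnification images upstream.

All dispersion statistics use the sample standard deviation (n − 1): group
sizes here are typically 4 mice, where the sample estimator is the only
defensible default.  The coefficient of variation is reported in percent
(100 × SD/mean).  For ONL tables, the CV is computed per retina across
that retina's fields (all 12 images — 4 eccentricities × 3 sections —
weighted equally; the averaging order across eccentricities vs sections is
not fixed by the protocol, and equal weighting is the neutral choice),
then averaged over retinas per group.

# RPE ZO-1 quantification

Lipofuscin-like autofluorescent granules emit through both the green and
red filters, whereas the Alexa-488 ZO-1 signal is confined to green.
Pixels with red intensity above 8 a.u. (interpreted on the 8-bit 0–255
export scale; configurable) are discarded, and the mean green intensity of
the retained pixels is the tile's score.  The mean is taken over *all*
retained pixels, not junction pixels only — segmenting junctions would
import a second algorithm with its own failure modes into a measurement
meant to be a plain intensity readout.  Saturated retained pixels are
counted but flagged (saturation clips the true signal and biases the mean
downward, so means from saturated tiles are indicative, not absolute).
Z-stacks are collapsed by maximum projection before masking (mean
projection available); the acquisition protocol quantified single
intensity values from thin stacks, and projection is the simplest faithful
reduction.

Group output is mean ± SEM of per-tile masked means plus a fold change
(reference mean / test mean), e.g. ≈3.3 for junction intensities 17.14 vs
5.2 a.u.

# ERG feature extraction

Conventions: corneal-positive voltage upward; the a-wave is the
negative-going deflection after the flash; all features are baseline
referenced (mean of the pre-onset window), making them invariant to
constant offsets.

* **a-wave** — magnitude of the baseline-referenced voltage at a fixed
  7 ms after stimulus onset, linearly interpolated between samples.  The
  reading is taken on the OP-suppressed slow wave: a zero-phase 50 Hz
  low-pass (just under the 60 Hz OP band edge) removes oscillatory
  potentials and noise from what would otherwise be a single-sample read;
  zero-phase filtering leaves latencies unbiased.
* **b-wave** — the a-trough is the minimum of the smoothed trace within
  50 ms of onset (a window bracketing rodent a-wave latencies at all
  intensities used); the b-peak is the smoothed maximum after the trough.
  Amplitude is trough-to-peak; peak time is referenced to onset.  Traces
  with no negative deflection are measured from baseline, with a warning.
* **Oscillatory potentials** — a fifth-order Butterworth band-pass,
  60–300 Hz (the band conventional for mouse OPs; configurable), applied
  forward and backward for zero phase (effective order doubles; a
  single-pass mode gives strict fifth-order response where phase is not a
  concern).  OP1–OP4 are the first four positive peaks of the filtered
  trace between the a-trough and the b-peak, measured from the filter's
  zero line.  Two peak-classification rules reflect how filtered traces
  actually look: peaks under 5% of the dominant peak are residual ripple,
  and peaks *preceding* the dominant OP that fall under 25% of it are
  rejected as slow-wave remnant — the a-wave transient is broadband, so
  its filtered residue forms small early peaks that are not OPs.
* **Series analysis** — features are aggregated per (group, condition,
  flash) cell as mean ± SEM, averaging within cells before any group
  statistics.  Flash grids step 0.6 log units up to 377.2 cd·s/m²
  (13 scotopic, 8 photopic flashes; the photopic series rides a
  rod-saturating 30 cd/m² background).  The printed protocol ranges are
  not exactly commensurate with the step size, so the grids are anchored
  at the brightest flash.
* The "peak time" tabulated per flash intensity is interpreted as the
  b-wave peak latency from stimulus onset; this reading is a convention of
  this implementation, not asserted beyond it.
* Repetition handling: traces may be pre-averaged upstream or supplied as
  raw repeats and averaged per cell here; both enter the same cells.

# The synthetic-data generators

Each generator emulates the statistical structure a stage assumes, records
exact ground truth, and is bit-reproducible given (parameters, seed).

*Cone mosaics.*  Cones are 2D Gaussian-profile disks (nominal radius
2.5 µm, peak 200/255, hard support at one radius) matching the appearance
of arrestin-stained inner segments at 0.32 µm/px (the pixel size is a
choice — acquisition metadata rarely travels with published fields — and
is configurable).  Placement is rejection sampling with a 2.2-radius
minimum separation; a designated fraction of cones is placed in touching
pairs at 1.1–1.5 radii, so their profiles merge into single components.
The truth records which rendered footprints reach the right/bottom border.
Additive Gaussian noise is clipped to [0, 255] — the simplest model that
stresses thresholding.

*Whole retinas.*  Exactly N cone positions on a disk (default 15 mm²,
a typical adult mouse retina), uniform or with a linear centre-to-periphery
density decline, as the oracle for the 16-field estimator.

*RPE tiles.*  The junction mesh is the boundary set of a nearest-seed
tessellation of random points (~2 px line width, default 4 cells per
100 × 100 px block), which statistically mimics the RPE tight-junction
lattice; round puncta (radius 2 px) are written into both channels at
identical coordinates, emulating autofluorescence.

*ERG traces.*  The slow wave is built from two smooth gamma-shaped lobes
band-limited below the OP passband, the oscillatory component as a
120 Hz carrier under a smooth spline envelope passing through the four
designed peak amplitudes.  Causality (zero baseline before onset) and
band-limitation are mathematically incompatible for a trough only 7 ms
after onset, so a residual broadband onset transient is unavoidable; the
generator cancels its band-passed ring in the OP epoch and calibrates the
two lobe scalars — a linear 2 × 2 system solved by a few fixed-point
rounds — so that, under the package's measurement conventions, the a-read
at 7 ms and the trough-to-peak excursion equal the design exactly.  The
raw trace minimum consequently approximates −a within a few percent
while extracted features match the design to ≲1%.

*ONL tables.*  Per-mouse, per-field row counts from a normal distribution
with the specified mean and CV, resampled to stay positive, cycling
through the four standard eccentricities.

What the generators deliberately do **not** model: optics (PSF, depth
attenuation), spatially correlated noise, staining gradients, mosaic
regularity statistics, lipofuscin spectra (only its two-channel
signature), eye-to-eye anatomical variation.  Passing tests therefore
demonstrate algorithmic correctness against known truth under controlled
conditions — not performance on any particular microscope's output.

# Statistics

Comparisons follow the protocol: a Shapiro–Wilk normality gate at
α = 0.05 (appropriate for n = 4-scale groups; failure warns but does not
block), then a two-tailed two-sample t-test with a 95% CI on the mean
difference.  Welch's unequal-variance form is the default — robust at
tiny n — with a pooled-variance option.  Stars follow the inclusive
boundaries: `***` p ≤ 0.001, `**` p ≤ 0.01, `*` p ≤ 0.05, else `ns`.
No multiple-testing correction is applied; reports flag when more than
five comparisons are run.  Tests operate at the mouse level by default
(images within a mouse are averaged first); image-level testing would
overstate the effective n.

# Pipeline, determinism and problem sizes

`runPipeline()` ties the stages together on synthetic inputs: mosaic
generation and counting, per-retina totals, ONL tables and CVs, RPE tiles
with fold change, ERG series, and the statistical report.  All randomness
derives from one root seed through fixed per-stage offsets, so identical
configurations give bit-identical output bundles; every output file
carries the MD5 hash of the configuration that produced it.

The validation suite runs at sizes chosen to exercise each claim while
staying desk-scale: 50 full-size fields for counting accuracy, 200
whole-retina replicates for estimator bias, 50 noisy tiles for the
masking property, 20 noiseless traces for ERG recovery, 10,000-draw
permutation tests for the t-test cross-check, and reduced field/tile
sizes inside the end-to-end determinism run.

# Known limitations

* Counting accuracy degrades for overlap tighter than ~1.1 radii, where
  two inner segments render as one quasi-circular profile; the 95%
  figure applies at realistic densities and touching rates.
* The red-channel cutoff assumes an 8-bit export scale; data acquired at
  other bit depths must be rescaled or the cutoff adjusted.
* ZO-1 quantification with saturated reference tiles underestimates fold
  changes (flagged, not corrected).
* ERG feature extraction assumes stimulus-locked, uniformly sampled
  traces with ≥10 ms of pre-onset baseline.
* Intensity-response curve fitting, cone-subtype classification, mosaic
  regularity indices and topographic density maps are out of scope.
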