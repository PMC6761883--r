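# retphen

Quantitative retinal phenotyping for mouse models of slow photoreceptor
degeneration (retinitis pigmentosa-type phenotypes), built for studies
that combine whole-mount cone counting, outer-nuclear-layer (ONL)
morphometry, retinal pigment epithelium (RPE) tight-junction
quantification and electroretinography (ERG) in one workflow.

## What it computes

**Automated cone counting.** Cone-arrestin-stained whole-mount fields are
binarized (Otsu), connected components with area < 2% of the mean cone
area are discarded, the mask is downsampled by a factor 0.3,
marker-controlled watershed on the distance transform splits touching
inner segments, and components intersecting the right or bottom border
are excluded so cells are counted once across tiled fields. Validation
against reference counts reports the Pearson correlation, the relative
error per image E = (M − A)/M, and accuracy = 1 − mean(|E|).

**Morphometry.** Per-field densities (cones/mm²), whole-retina totals
extrapolated from 16 fields along the two principal meridians
(total = mean density × retinal area), group means ± SEM, and the
coefficient of variation CV = 100·σ/μ as an index of intraretinal
patchiness of degeneration.

**RPE ZO-1 quantification.** Mean green-channel fluorescence of
two-channel tiles after rejecting autofluorescence: pixels with red
intensity > 8 a.u. (8-bit scale) are discarded because lipofuscin-like
granules emit in both channels while specific ZO-1/Alexa-488 staining is
green-only. Group summaries and fold change between groups.

**ERG features.** Baseline-referenced a-wave amplitude at 7 ms after
stimulus onset, b-wave amplitude from the a-trough to the b-peak with its
latency, and oscillatory potentials OP1–OP4 isolated by a fifth-order
Butterworth band-pass (60–300 Hz, zero-phase) with peak amplitudes read
between the a-trough and the b-peak. Scotopic and photopic series are
aggregated per flash intensity as mean ± SEM.

**Statistics.** Shapiro–Wilk normality gate, two-tailed (Welch) t-test
with 95% CI, and star annotation (`***` p ≤ 0.001, `**` p ≤ 0.01,
`*` p ≤ 0.05).

**Synthetic data.** Every stage has a paired generator producing
ground-truthed inputs — cone mosaics with touching cells and noise,
disk-shaped whole retinas, two-channel RPE tiles with a polygonal
junction mesh and dual-channel puncta, stimulus-locked ERG traces, and
ONL row tables — so the full pipeline is testable with no external data.

## Worked example

```r
library(retphen)

# a ground-truthed synthetic counting field: 223.8 x 167.6 um at
# ~12,000 cones/mm2, 10% touching pairs, noise SD 5% of blob peak
f <- generateConeMosaic(12000, seed = 1, touchingFraction = 0.1, noiseSd = 10)
f$truth
#> MosaicTruth: 450 blobs placed, 432 countable, 18 on right/bottom border (radius 2.50 um)

countField(f$image)
#> CountResult: 420 cones (16 small components filtered, 18 border components excluded)
#>   binarize=otsu areaFraction=0.02 downsample=0.3
```

The automated count (420) is within 2.8% of the 432 countable cones; the
18 border blobs flagged by the generator are exactly the 18 components
the chain excluded. On the standard 50-field batch the mean accuracy is
≈ 97.7%.

```r
tr <- generateERGTrace(ERGTruth(150, 400, c(40, 30, 20, 10), 120, 0.077),
                       fs = 5000, noiseSd = 0)
ergFeatures(tr)
#> ERGFeatures: a-wave 150.9 uV (at 7 ms), b-wave 400.8 uV at 0.0768 s
#>   OP1-OP4 (uV): 37.1, 31.6, 19.2, 10.5
```

All designed amplitudes are recovered within 2% (a, b) and 10% (OPs)
through the 60–300 Hz filter. `runPipeline(pipelineConfig(seed = 7), "out/")`
runs every stage end to end on synthetic inputs and writes a
deterministic report bundle; see the methods vignette
(`vignettes/retphen-methods.Rmd`) for models, parameter rationale and
limitations.

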