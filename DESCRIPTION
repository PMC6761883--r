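Package: retphen
Title: Quantitative Retinal Phenotyping from Microscopy and Electroretinography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantification tools for mouse retinal degeneration phenotyping:
    automated cone counting on whole-mount mosaic images (binarization,
    small-component filtering, downsampling, watershed splitting of touching
    cells, border exclusion), whole-retina cone totals extrapolated from
    meridian field sampling, outer-nuclear-layer row statistics with
    coefficients of variation, ZO-1 tight-junction fluorescence quantification
    in retinal pigment epithelium tiles with autofluorescence rejection via a
    red-channel cutoff, and electroretinogram feature extraction including
    Butterworth-filtered oscillatory potentials. A synthetic-data module
    generates ground-truthed images, tables and traces so every stage can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    signal,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'cone-counter.R'
    'erg.R'
    'io.R'
    'morphometry.R'
    'pipeline.R'
    'retphen-package.R'
    'rpe-zo1.R'
    'stats-report.R'
    'synthetic-mosaic.R'
    'synthetic-erg.R'
    'synthetic-onl.R'
    'synthetic-rpe.R'
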