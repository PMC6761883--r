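#' @import methods
NULL

#' FieldImage: one calibrated counting field
#'
#' A single-channel 2D intensity grid (arbitrary units on an 8-bit 0--255
#' scale) representing one counting field of a whole-mount or RPE
#' preparation, together with its pixel calibration and sampling metadata.
#' Rows index the image vertically (row 1 at the top), columns horizontally;
#' the "right border" is the last column and the "bottom border" the last
#' row.
#'
#' @slot pixels numeric matrix of intensities.
#' @slot pxUm pixel edge length in micrometres (> 0).
#' @slot fieldId,retinaId character identifiers (may be empty).
#' @slot eccentricityIndex integer position 1--8 along a meridian
#'   (NA when not applicable).
#' @slot meridian one of \code{"dorso-ventral"}, \code{"naso-temporal"} or
#'   \code{""}.
#'
#' @exportClass FieldImage
setClass("FieldImage",
  representation(
    pixels = "matrix",
    pxUm = "numeric",
    fieldId = "character",
    retinaId = "character",
    eccentricityIndex = "integer",
    meridian = "character"
  ),
  prototype(
    pxUm = 0.32, fieldId = "", retinaId = "",
    eccentricityIndex = NA_integer_, meridian = ""
  )
)

setValidity("FieldImage", function(object) {
  msg <- NULL
  if (length(object@pixels) == 0L || any(dim(object@pixels) == 0L))
    msg <- c(msg, "'pixels' must be a non-empty matrix")
  if (!is.numeric(object@pixels))
    msg <- c(msg, "'pixels' must be numeric")
  if (length(object@pxUm) != 1L || is.na(object@pxUm) || object@pxUm <= 0)
    msg <- c(msg, "'pxUm' must be a single positive number")
  if (!object@meridian %in% c("", "dorso-ventral", "naso-temporal"))
    msg <- c(msg, "'meridian' must be '', 'dorso-ventral' or 'naso-temporal'")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FieldImage
#'
#' @param pixels numeric matrix of intensities (a.u., 0--255 scale).
#' @param pxUm pixel edge length in micrometres.
#' @param fieldId,retinaId optional identifiers.
#' @param eccentricityIndex optional integer 1--8.
#' @param meridian optional meridian label.
#' @return A \linkS4class{FieldImage}.
#' @examples
#' img <- FieldImage(matrix(0, 50, 60), pxUm = 0.32)
#' dim(pixels(img))
#' @export
FieldImage <- function(pixels, pxUm = 0.32, fieldId = "", retinaId = "",
                       eccentricityIndex = NA_integer_, meridian = "") {
  new("FieldImage", pixels = pixels, pxUm = pxUm, fieldId = fieldId,
      retinaId = retinaId, eccentricityIndex = as.integer(eccentricityIndex),
      meridian = meridian)
}

#' MosaicTruth: ground truth for a synthetic cone mosaic
#'
#' Records the exact placement of every synthetic cone in a field, which
#' blobs intersect the right or bottom field border (and are therefore
#' excluded from counting by convention), and the resulting countable total.
#'
#' @slot positionsUm n x 2 matrix of (row_um, col_um) cone centres.
#' @slot radiusUm nominal inner-segment radius (micrometres).
#' @slot borderFlag logical vector, TRUE where the blob intersects the right
#'   or bottom border.
#' @slot nTotal number of countable (non-border) cones.
#' @slot nExcludable number of border-intersecting cones.
#'
#' @exportClass MosaicTruth
setClass("MosaicTruth",
  representation(
    positionsUm = "matrix",
    radiusUm = "numeric",
    borderFlag = "logical",
    nTotal = "integer",
    nExcludable = "integer"
  )
)

setValidity("MosaicTruth", function(object) {
  msg <- NULL
  if (nrow(object@positionsUm) != length(object@borderFlag))
    msg <- c(msg, "one border flag per position required")
  if (object@nTotal < 0L) msg <- c(msg, "'nTotal' must be >= 0")
  if (object@nExcludable > nrow(object@positionsUm))
    msg <- c(msg, "'nExcludable' cannot exceed the number of placed blobs")
  if (object@nTotal + object@nExcludable != nrow(object@positionsUm))
    msg <- c(msg, "nTotal + nExcludable must equal the number of placed blobs")
  if (is.null(msg)) TRUE else msg
})

#' WholeRetinaTruth: ground truth for a synthetic whole retina
#'
#' Cone centre coordinates over a disk-shaped retina of known area; the
#' oracle for the 16-field meridian sampling estimator.
#'
#' @slot positionsMm n x 2 matrix of (x_mm, y_mm) centres, origin at the
#'   optic nerve head.
#' @slot areaMm2 retinal area in mm^2.
#' @slot gradient linear centre-to-periphery density decline (0 = uniform).
#'
#' @exportClass WholeRetinaTruth
setClass("WholeRetinaTruth",
  representation(
    positionsMm = "matrix",
    areaMm2 = "numeric",
    gradient = "numeric"
  )
)

setValidity("WholeRetinaTruth", function(object) {
  msg <- NULL
  if (object@areaMm2 <= 0) msg <- c(msg, "'areaMm2' must be positive")
  if (object@gradient < 0) msg <- c(msg, "'gradient' must be >= 0")
  R <- sqrt(object@areaMm2 / pi)
  if (nrow(object@positionsMm) > 0) {
    r <- sqrt(rowSums(object@positionsMm^2))
    if (any(r > R + 1e-9)) msg <- c(msg, "positions must lie within the disk")
  }
  if (is.null(msg)) TRUE else msg
})

#' CountResult: output of the automated cone-counting chain
#'
#' Bookkeeping for one field run through the full chain: binarize ->
#' small-component filter -> downsample -> watershed split -> right/bottom
#' border exclusion -> count.
#'
#' @slot nCones final count of retained components.
#' @slot nRemovedSmall components removed by the area filter.
#' @slot nRemovedBorder components removed by border exclusion.
#' @slot componentAreasPx areas (in downsampled pixels) of post-watershed
#'   components, before border exclusion.
#' @slot params list echoing the configuration used
#'   (binarizeMethod, areaFraction, downsampleFactor, ...).
#'
#' @exportClass CountResult
setClass("CountResult",
  representation(
    nCones = "integer",
    nRemovedSmall = "integer",
    nRemovedBorder = "integer",
    componentAreasPx = "integer",
    params = "list"
  )
)

setValidity("CountResult", function(object) {
  msg <- NULL
  if (object@nCones < 0L) msg <- c(msg, "'nCones' must be >= 0")
  if (object@nCones + object@nRemovedBorder != length(object@componentAreasPx))
    msg <- c(msg, "nCones + nRemovedBorder must equal the number of post-watershed components")
  if (is.null(msg)) TRUE else msg
})

#' ComparisonStats: manual-vs-automated count validation
#'
#' @slot pearsonR Pearson correlation between per-image manual and
#'   automated counts (NA when a vector is constant).
#' @slot errors per-image relative errors (manual - automated) / manual.
#' @slot accuracy 1 - mean(|errors|).
#'
#' @exportClass ComparisonStats
setClass("ComparisonStats",
  representation(pearsonR = "numeric", errors = "numeric",
                 accuracy = "numeric")
)

setValidity("ComparisonStats", function(object) {
  msg <- NULL
  if (!is.na(object@pearsonR) &&
      (object@pearsonR < -1 - 1e-12 || object@pearsonR > 1 + 1e-12))
    msg <- c(msg, "'pearsonR' must lie in [-1, 1]")
  if (abs(object@accuracy - (1 - mean(abs(object@errors)))) > 1e-9)
    msg <- c(msg, "'accuracy' must equal 1 - mean(|errors|)")
  if (is.null(msg)) TRUE else msg
})

#' TwoChannelTile: a two-channel RPE image tile
#'
#' Congruent green (ZO-1 staining) and red (autofluorescence reporter)
#' intensity grids on an 8-bit scale.
#'
#' @slot green,red numeric matrices of identical dimensions.
#'
#' @exportClass TwoChannelTile
setClass("TwoChannelTile",
  representation(green = "matrix", red = "matrix")
)

setValidity("TwoChannelTile", function(object) {
  msg <- NULL
  if (!identical(dim(object@green), dim(object@red)))
    msg <- c(msg, "'green' and 'red' must have identical dimensions")
  if (length(object@green) == 0L)
    msg <- c(msg, "channels must be non-empty")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TwoChannelTile
#' @param green,red numeric matrices of identical dimensions.
#' @return A \linkS4class{TwoChannelTile}.
#' @export
TwoChannelTile <- function(green, red) new("TwoChannelTile", green = green, red = red)

#' RPETileTruth: ground truth for a synthetic RPE tile
#'
#' @slot junctionIntensity mean green intensity on junction pixels (a.u.).
#' @slot junctionIdx linear pixel indices of the junction mesh.
#' @slot punctaIdx linear pixel indices carrying autofluorescent puncta
#'   (present in both channels at the same coordinates).
#' @slot cellCount number of polygonal cells in the mesh.
#'
#' @exportClass RPETileTruth
setClass("RPETileTruth",
  representation(
    junctionIntensity = "numeric",
    junctionIdx = "integer",
    punctaIdx = "integer",
    cellCount = "integer"
  )
)

setValidity("RPETileTruth", function(object) {
  if (object@junctionIntensity < 0 || object@junctionIntensity > 255)
    "junctionIntensity must lie in [0, 255]" else TRUE
})

#' ZOQuant: masked-mean ZO-1 quantification of one tile
#'
#' @slot meanGreenMasked mean green intensity over retained pixels (a.u.).
#' @slot maskedFraction proportion of pixels discarded by the red-channel
#'   cutoff.
#' @slot redCutoff the cutoff applied (a.u.).
#' @slot saturationFraction fraction of retained pixels at the top of the
#'   bit range (saturation biases the mean downward; flagged, not removed).
#'
#' @exportClass ZOQuant
setClass("ZOQuant",
  representation(
    meanGreenMasked = "numeric",
    maskedFraction = "numeric",
    redCutoff = "numeric",
    saturationFraction = "numeric"
  )
)

setValidity("ZOQuant", function(object) {
  if (object@maskedFraction < 0 || object@maskedFraction > 1)
    "maskedFraction must lie in [0, 1]" else TRUE
})

#' ERGTruth: design parameters of a synthetic ERG response
#'
#' @slot aAmp a-wave trough magnitude (uV, >= 0).
#' @slot bAmp a-trough-to-b-peak excursion (uV, >= 0).
#' @slot opAmps four oscillatory-potential peak amplitudes OP1--OP4 (uV).
#' @slot opFreq OP carrier frequency (Hz).
#' @slot bPeakTime latency of the b-wave peak from stimulus onset (s).
#'
#' @exportClass ERGTruth
setClass("ERGTruth",
  representation(
    aAmp = "numeric", bAmp = "numeric", opAmps = "numeric",
    opFreq = "numeric", bPeakTime = "numeric"
  )
)

setValidity("ERGTruth", function(object) {
  msg <- NULL
  if (any(c(object@aAmp, object@bAmp, object@opAmps) < 0))
    msg <- c(msg, "all amplitudes must be >= 0")
  if (length(object@opAmps) != 4L) msg <- c(msg, "'opAmps' must have length 4")
  if (object@bPeakTime <= 0) msg <- c(msg, "'bPeakTime' must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Construct an ERGTruth
#'
#' @param aAmp,bAmp a-wave and b-wave amplitudes (uV); \code{bAmp} is the
#'   a-trough-to-b-peak excursion and must be >= \code{aAmp} (the b-peak
#'   rises above baseline) unless both are 0.
#' @param opAmps numeric(4), OP1--OP4 peak amplitudes (uV).
#' @param opFreq OP carrier frequency (Hz).
#' @param bPeakTime b-peak latency from onset (s).
#' @return An \linkS4class{ERGTruth}.
#' @export
ERGTruth <- function(aAmp = 150, bAmp = 400, opAmps = c(40, 30, 20, 10),
                     opFreq = 120, bPeakTime = 0.077) {
  if (bAmp < aAmp)
    stop("'bAmp' (trough-to-peak) must be >= 'aAmp' so the b-peak lies above baseline")
  new("ERGTruth", aAmp = aAmp, bAmp = bAmp, opAmps = opAmps,
      opFreq = opFreq, bPeakTime = bPeakTime)
}

#' ERGTrace: a stimulus-locked ERG voltage time series
#'
#' @slot t time samples (s), uniformly spaced.
#' @slot v voltage samples (uV), corneal-positive upward.
#' @slot onset stimulus onset time (s), within the record.
#' @slot flash flash intensity (cd*s/m^2).
#' @slot condition \code{"scotopic"} or \code{"photopic"}.
#' @slot background steady background luminance (cd/m^2; 0 for scotopic,
#'   30 for photopic).
#'
#' @exportClass ERGTrace
setClass("ERGTrace",
  representation(
    t = "numeric", v = "numeric", onset = "numeric",
    flash = "numeric", condition = "character", background = "numeric"
  ),
  prototype(flash = NA_real_, condition = "scotopic", background = 0)
)

setValidity("ERGTrace", function(object) {
  msg <- NULL
  if (length(object@t) != length(object@v))
    msg <- c(msg, "'t' and 'v' must have equal length")
  if (length(object@t) >= 2) {
    dt <- diff(object@t)
    if (any(abs(dt - dt[1]) > 1e-9 * max(dt[1], 1e-12)))
      msg <- c(msg, "'t' must be uniformly sampled")
  }
  if (object@onset < object@t[1] || object@onset > object@t[length(object@t)])
    msg <- c(msg, "'onset' must lie within the record")
  if (!object@condition %in% c("scotopic", "photopic"))
    msg <- c(msg, "'condition' must be 'scotopic' or 'photopic'")
  if (is.null(msg)) TRUE else msg
})

#' Construct an ERGTrace
#' @param t,v time (s) and voltage (uV) samples of equal length.
#' @param onset stimulus onset time (s).
#' @param flash flash intensity (cd*s/m^2).
#' @param condition "scotopic" or "photopic".
#' @param background background luminance (cd/m^2).
#' @return An \linkS4class{ERGTrace}.
#' @export
ERGTrace <- function(t, v, onset, flash = NA_real_, condition = "scotopic",
                     background = if (condition == "photopic") 30 else 0) {
  new("ERGTrace", t = t, v = v, onset = onset, flash = flash,
      condition = condition, background = background)
}

#' ERGFeatures: amplitudes and latencies extracted from one trace
#'
#' @slot aAmpUv baseline-referenced a-wave magnitude at onset + 7 ms (uV).
#' @slot bAmpUv a-trough-to-b-peak excursion (uV).
#' @slot bPeakTimeS b-peak latency from onset (s).
#' @slot opAmpsUv OP1--OP4 peak amplitudes from the band-passed trace (uV);
#'   NA marks absent peaks.
#'
#' @exportClass ERGFeatures
setClass("ERGFeatures",
  representation(
    aAmpUv = "numeric", bAmpUv = "numeric",
    bPeakTimeS = "numeric", opAmpsUv = "numeric"
  )
)

setValidity("ERGFeatures", function(object) {
  msg <- NULL
  if (!is.na(object@bAmpUv) && object@bAmpUv < 0)
    msg <- c(msg, "'bAmpUv' must be >= 0")
  if (length(object@opAmpsUv) != 4L)
    msg <- c(msg, "'opAmpsUv' must have length 4")
  if (is.null(msg)) TRUE else msg
})

#' RetinaSample: the 16-field meridian sampling of one retina
#'
#' @slot retinaId identifier.
#' @slot fields data.frame with columns meridian, eccentricityIndex (1--8),
#'   count, fieldAreaMm2.
#' @slot retinaAreaMm2 measured retinal area (mm^2).
#'
#' @exportClass RetinaSample
setClass("RetinaSample",
  representation(
    retinaId = "character",
    fields = "data.frame",
    retinaAreaMm2 = "numeric"
  )
)

setValidity("RetinaSample", function(object) {
  msg <- NULL
  nf <- nrow(object@fields)
  if (nf < 1L || nf > 16L) msg <- c(msg, "between 1 and 16 fields required")
  need <- c("meridian", "eccentricityIndex", "count", "fieldAreaMm2")
  if (!all(need %in% names(object@fields)))
    msg <- c(msg, paste("fields must have columns", paste(need, collapse = ", ")))
  else if (any(object@fields$fieldAreaMm2 <= 0))
    msg <- c(msg, "field areas must be positive")
  if (object@retinaAreaMm2 <= 0) msg <- c(msg, "'retinaAreaMm2' must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Construct a RetinaSample
#' @param retinaId identifier.
#' @param fields data.frame with columns meridian, eccentricityIndex, count,
#'   fieldAreaMm2 (1--16 rows).
#' @param retinaAreaMm2 retinal area in mm^2.
#' @return A \linkS4class{RetinaSample}.
#' @export
RetinaSample <- function(retinaId, fields, retinaAreaMm2) {
  new("RetinaSample", retinaId = retinaId, fields = fields,
      retinaAreaMm2 = retinaAreaMm2)
}

#' GroupSummary: mean, SEM and coefficient of variation of a group
#'
#' @slot groupName group label.
#' @slot n number of units (mice or retinas).
#' @slot mean group mean.
#' @slot sem standard error of the mean, sd/sqrt(n) (sample sd, n-1).
#' @slot cvPercent 100 * sd / mean.
#'
#' @exportClass GroupSummary
setClass("GroupSummary",
  representation(
    groupName = "character", n = "integer",
    mean = "numeric", sem = "numeric", cvPercent = "numeric"
  )
)

setValidity("GroupSummary", function(object) {
  msg <- NULL
  if (!is.na(object@sem) && object@sem < 0) msg <- c(msg, "'sem' must be >= 0")
  if (!is.na(object@cvPercent) && object@cvPercent < 0)
    msg <- c(msg, "'cvPercent' must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' TestResult: a two-tailed t-test with normality gate and star annotation
#'
#' @slot statistic t statistic.
#' @slot p two-tailed p-value.
#' @slot ci95 95% confidence interval for the difference of means.
#' @slot normalityP Shapiro-Wilk p-value per group (NA when not assessable).
#' @slot normalityPassed logical per group.
#' @slot stars one of "ns", "*", "**", "***".
#'
#' @exportClass TestResult
setClass("TestResult",
  representation(
    statistic = "numeric", p = "numeric", ci95 = "numeric",
    normalityP = "numeric", normalityPassed = "logical", stars = "character"
  )
)

setValidity("TestResult", function(object) {
  msg <- NULL
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    msg <- c(msg, "'p' must lie in [0, 1]")
  if (!object@stars %in% c("ns", "*", "**", "***"))
    msg <- c(msg, "'stars' must be one of ns, *, **, ***")
  if (is.null(msg)) TRUE else msg
})
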