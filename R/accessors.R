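#' @include AllGenerics.R
NULL

#' Accessors for FieldImage
#'
#' \code{pixels} returns the intensity matrix; \code{pxUm} the pixel edge
#' length in micrometres.
#'
#' @param x a \linkS4class{FieldImage}.
#' @return matrix or numeric scalar.
#' @rdname FieldImage-accessors
#' @aliases pixels pxUm
#' @export
setMethod("pixels", "FieldImage", function(x) x@pixels)

#' @rdname FieldImage-accessors
#' @export
setMethod("pxUm", "FieldImage", function(x) x@pxUm)

#' Accessors for CountResult
#'
#' @param x a \linkS4class{CountResult}.
#' @return integer scalar or vector, or list for \code{countParams}.
#' @rdname CountResult-accessors
#' @aliases nCones nRemovedSmall nRemovedBorder componentAreasPx countParams
#' @export
setMethod("nCones", "CountResult", function(x) x@nCones)

#' @rdname CountResult-accessors
#' @export
setMethod("nRemovedSmall", "CountResult", function(x) x@nRemovedSmall)

#' @rdname CountResult-accessors
#' @export
setMethod("nRemovedBorder", "CountResult", function(x) x@nRemovedBorder)

#' @rdname CountResult-accessors
#' @export
setMethod("componentAreasPx", "CountResult", function(x) x@componentAreasPx)

#' @rdname CountResult-accessors
#' @export
setMethod("countParams", "CountResult", function(x) x@params)

#' Accessors for TwoChannelTile
#'
#' @param x a \linkS4class{TwoChannelTile}.
#' @return intensity matrix.
#' @rdname TwoChannelTile-accessors
#' @aliases greenChannel redChannel
#' @export
setMethod("greenChannel", "TwoChannelTile", function(x) x@green)

#' @rdname TwoChannelTile-accessors
#' @export
setMethod("redChannel", "TwoChannelTile", function(x) x@red)

#' Accessors for ERGTrace
#'
#' \code{samplingRate} is derived from the uniform time grid (Hz).
#'
#' @param x an \linkS4class{ERGTrace}.
#' @return numeric vector or scalar.
#' @rdname ERGTrace-accessors
#' @aliases voltages times stimulusOnset samplingRate
#' @export
setMethod("voltages", "ERGTrace", function(x) x@v)

#' @rdname ERGTrace-accessors
#' @export
setMethod("times", "ERGTrace", function(x) x@t)

#' @rdname ERGTrace-accessors
#' @export
setMethod("stimulusOnset", "ERGTrace", function(x) x@onset)

#' @rdname ERGTrace-accessors
#' @export
setMethod("samplingRate", "ERGTrace", function(x) 1 / (x@t[2] - x@t[1]))

#' Accessors for GroupSummary
#'
#' @param x a \linkS4class{GroupSummary}.
#' @return numeric scalar.
#' @rdname GroupSummary-accessors
#' @aliases groupMean groupSem cvPercent
#' @export
setMethod("groupMean", "GroupSummary", function(x) x@mean)

#' @rdname GroupSummary-accessors
#' @export
setMethod("groupSem", "GroupSummary", function(x) x@sem)

#' @rdname GroupSummary-accessors
#' @export
setMethod("cvPercent", "GroupSummary", function(x) x@cvPercent)

setMethod("show", "FieldImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FieldImage: %d x %d px (%.1f x %.1f um at %.3g um/px)\n",
              d[1], d[2], d[1] * object@pxUm, d[2] * object@pxUm, object@pxUm))
  if (nzchar(object@fieldId))
    cat(sprintf("  field '%s' retina '%s' %s ecc %s\n", object@fieldId,
                object@retinaId, object@meridian, object@eccentricityIndex))
  cat(sprintf("  intensity range [%.1f, %.1f]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "CountResult", function(object) {
  cat(sprintf("CountResult: %d cones (%d small components filtered, %d border components excluded)\n",
              object@nCones, object@nRemovedSmall, object@nRemovedBorder))
  p <- object@params
  cat(sprintf("  binarize=%s areaFraction=%.3g downsample=%.2g\n",
              p$binarizeMethod, p$areaFraction, p$downsampleFactor))
})

setMethod("show", "MosaicTruth", function(object) {
  cat(sprintf("MosaicTruth: %d blobs placed, %d countable, %d on right/bottom border (radius %.2f um)\n",
              nrow(object@positionsUm), object@nTotal, object@nExcludable,
              object@radiusUm))
})

setMethod("show", "TwoChannelTile", function(object) {
  d <- dim(object@green)
  cat(sprintf("TwoChannelTile: %d x %d px, green range [%.1f, %.1f], red range [%.1f, %.1f]\n",
              d[1], d[2], min(object@green), max(object@green),
              min(object@red), max(object@red)))
})

setMethod("show", "ZOQuant", function(object) {
  cat(sprintf("ZOQuant: masked green mean %.3f a.u. (%.1f%% pixels masked at red cutoff %g)\n",
              object@meanGreenMasked, 100 * object@maskedFraction,
              object@redCutoff))
  if (object@saturationFraction > 0)
    cat(sprintf("  warning: %.2f%% retained pixels saturated (mean biased downward)\n",
                100 * object@saturationFraction))
})

setMethod("show", "ERGTrace", function(object) {
  cat(sprintf("ERGTrace: %d samples at %.0f Hz, %s, flash %.4g cd*s/m2, onset %.3f s\n",
              length(object@v), samplingRate(object), object@condition,
              object@flash, object@onset))
})

setMethod("show", "ERGFeatures", function(object) {
  cat(sprintf("ERGFeatures: a-wave %.1f uV (at 7 ms), b-wave %.1f uV at %.4f s\n",
              object@aAmpUv, object@bAmpUv, object@bPeakTimeS))
  cat("  OP1-OP4 (uV):", paste(sprintf("%.1f", object@opAmpsUv), collapse = ", "), "\n")
})

setMethod("show", "GroupSummary", function(object) {
  cat(sprintf("GroupSummary '%s': n=%d, mean %.4g +/- %.3g (SEM), CV %.3g%%\n",
              object@groupName, object@n, object@mean, object@sem,
              object@cvPercent))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult: t = %.4g, p = %.4g (%s), 95%% CI [%.4g, %.4g]\n",
              object@statistic, object@p, object@stars,
              object@ci95[1], object@ci95[2]))
  cat(sprintf("  normality (Shapiro-Wilk p): %s\n",
              paste(sprintf("%.3g", object@normalityP), collapse = ", ")))
})

setMethod("show", "RetinaSample", function(object) {
  cat(sprintf("RetinaSample '%s': %d fields, retina area %.2f mm2\n",
              object@retinaId, nrow(object@fields), object@retinaAreaMm2))
})

setMethod("show", "WholeRetinaTruth", function(object) {
  cat(sprintf("WholeRetinaTruth: %d cones over %.2f mm2 disk (gradient %.2f)\n",
              nrow(object@positionsMm), object@areaMm2, object@gradient))
})

setMethod("show", "ERGTruth", function(object) {
  cat(sprintf("ERGTruth: a %.0f uV, b %.0f uV at %.4f s, OPs %s uV at %.0f Hz\n",
              object@aAmp, object@bAmp, object@bPeakTime,
              paste(object@opAmps, collapse = "/"), object@opFreq))
})
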