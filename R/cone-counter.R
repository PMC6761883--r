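#' @include AllClasses.R
NULL

asMatrix <- function(x) {
  if (methods::is(x, "Image")) EBImage::imageData(x) else unclass(x)
}

#' Binarize a counting field
#'
#' Thresholds a field image into a foreground mask.  The default Otsu
#' method is parameter-free and suited to the bimodal histograms of
#' fluorescence mosaics; a fixed threshold is available for degenerate or
#' calibrated inputs.
#'
#' @param image a \linkS4class{FieldImage} or numeric matrix (a.u., 0--255).
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param fixedThreshold threshold in a.u.; required when
#'   \code{method = "fixed"}.
#' @return logical matrix, TRUE where intensity exceeds the threshold; the
#'   threshold used is attached as attribute \code{"threshold"}.
#' @examples
#' m <- matrix(c(20, 20, 200, 200), 2, 2)
#' binarizeField(m)
#' @export
binarizeField <- function(image, method = c("otsu", "fixed"),
                          fixedThreshold = NULL) {
  method <- match.arg(method)
  px <- if (methods::is(image, "FieldImage")) pixels(image) else image
  if (method == "fixed") {
    if (is.null(fixedThreshold))
      stop("'fixedThreshold' is required when method = 'fixed'")
    thr <- fixedThreshold
  } else {
    if (stats::var(as.vector(px)) == 0)
      stop("degenerate image: zero variance, Otsu threshold undefined")
    thr <- 255 * EBImage::otsu(EBImage::Image(px / 255), range = c(0, 1))
  }
  mask <- px > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Remove connected components smaller than a fraction of the mean cone area
#'
#' Components with area below \code{fraction} times the average cone area
#' are treated as debris and discarded (default fraction 0.02).  When no
#' calibrated area is supplied the average is self-calibrated per image as
#' the mean connected-component area of the input mask, computed before any
#' filtering.
#'
#' @param mask logical matrix (foreground mask).
#' @param meanConeAreaPx calibrated mean cone area in pixels; \code{NULL}
#'   (default) self-calibrates from the mask.
#' @param fraction area fraction below which components are removed
#'   (0 < fraction < 1).
#' @return logical mask with small components removed; attributes
#'   \code{"nRemoved"} (count removed) and \code{"meanConeAreaPx"} (area
#'   used).
#' @examples
#' m <- matrix(FALSE, 20, 20); m[2:11, 2:11] <- TRUE; m[15, 15] <- TRUE
#' sum(filterSmall(m))  # the 1-px speck is dropped
#' @export
filterSmall <- function(mask, meanConeAreaPx = NULL, fraction = 0.02) {
  if (fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie strictly between 0 and 1")
  mask <- asMatrix(mask) > 0
  lab <- asMatrix(EBImage::bwlabel(mask))
  nComp <- max(lab)
  if (nComp == 0L) {
    out <- mask
    attr(out, "nRemoved") <- 0L
    attr(out, "meanConeAreaPx") <- meanConeAreaPx
    return(out)
  }
  areas <- tabulate(lab[lab > 0], nbins = nComp)
  if (is.null(meanConeAreaPx)) meanConeAreaPx <- mean(areas)
  if (meanConeAreaPx <= 0) stop("'meanConeAreaPx' must be positive")
  drop <- which(areas < fraction * meanConeAreaPx)
  out <- mask & !(lab %in% drop)
  dim(out) <- dim(mask)
  attr(out, "nRemoved") <- length(drop)
  attr(out, "meanConeAreaPx") <- meanConeAreaPx
  out
}

#' Downsample a binary mask
#'
#' Nearest-neighbour downsampling to \code{round(factor * dim)}; sampling
#' indices span the full extent so the first and last rows/columns of the
#' input are represented, preserving border contacts.  Nearest-neighbour
#' sampling preserves binarity.
#'
#' @param mask logical matrix.
#' @param factor scale factor in (0, 1]; the counting chain default is 0.3.
#' @return logical matrix of dimensions \code{round(factor * dim(mask))}.
#' @examples
#' dim(downsampleMask(matrix(FALSE, 700, 524), 0.3))  # 210 x 157
#' @export
downsampleMask <- function(mask, factor = 0.3) {
  if (factor <= 0 || factor > 1)
    stop("'factor' must lie in (0, 1]")
  mask <- asMatrix(mask) > 0
  if (factor == 1) return(mask)
  idx <- dsIndices(dim(mask), factor)
  mask[idx$rows, idx$cols, drop = FALSE]
}

# Nearest-neighbour sampling indices for downsampling to round(factor * d),
# spanning the full extent so border rows/columns stay represented.
dsIndices <- function(d, factor) {
  m <- pmax(round(factor * d), 1L)
  list(rows = round(seq(1, d[1], length.out = m[1])),
       cols = round(seq(1, d[2], length.out = m[2])))
}

#' Split touching components by watershed on the distance transform
#'
#' Applies marker-controlled watershed segmentation to the Euclidean
#' distance transform of the mask so that touching cells merged into one
#' connected component receive distinct labels.  Markers are regional
#' maxima of the distance map detected within a neighbourhood radius
#' \code{minSepPx} and merged when their catchment basins differ by less
#' than \code{tolerance} in distance-map height.
#'
#' When the mask is a downsampled version of a higher-resolution mask, the
#' distance transform of the original mask (sampled at the same positions)
#' can be supplied as \code{heightMap}: it carries sub-pixel geometry that
#' the quantized distance map of the coarse mask loses, so touching pairs
#' remain separable after downsampling.
#'
#' @param mask logical matrix.
#' @param minSepPx minimum marker separation in pixels (default 1; the full
#'   counting chain uses 0.6 x the nominal cone radius in downsampled
#'   pixels).
#' @param tolerance minimum height difference between a maximum and its
#'   merge point for a split (height-map units, default 0.5: half a pixel
#'   of distance, below which maxima are indistinguishable from boundary
#'   discretization ripple).
#' @param heightMap optional numeric matrix, same shape as \code{mask},
#'   used as the watershed height; defaults to the Euclidean distance
#'   transform of \code{mask}.
#' @return integer label matrix; 0 is background.
#' @examples
#' m <- matrix(FALSE, 20, 30); m[5:15, 5:15] <- TRUE
#' max(splitTouching(m))  # one isolated blob keeps one label
#' @export
splitTouching <- function(mask, minSepPx = 1, tolerance = 0.5,
                          heightMap = NULL) {
  mask <- asMatrix(mask) > 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- if (is.null(heightMap)) EBImage::distmap(mask)
        else asMatrix(heightMap) * mask
  w <- EBImage::watershed(dm, tolerance = tolerance,
                          ext = max(1L, round(minSepPx)))
  out <- asMatrix(w)
  storage.mode(out) <- "integer"
  out
}

#' Exclude components intersecting the right or bottom border
#'
#' Counting convention for tiled fields: components touching the last
#' column (right border) or last row (bottom border) are dropped so that
#' cells straddling field boundaries are counted exactly once across
#' adjacent fields; components touching only the top or left borders are
#' retained.
#'
#' @param labels integer label matrix.
#' @return label matrix with border-touching labels zeroed; attribute
#'   \code{"nRemoved"} records how many labels were dropped.
#' @examples
#' lab <- matrix(0L, 5, 5); lab[3, 4:5] <- 1L
#' max(excludeBorder(lab))  # touches the right border: removed
#' @export
excludeBorder <- function(labels) {
  labels <- asMatrix(labels)
  d <- dim(labels)
  borderLabels <- unique(c(labels[d[1], ], labels[, d[2]]))
  borderLabels <- borderLabels[borderLabels > 0]
  out <- labels
  out[out %in% borderLabels] <- 0L
  storage.mode(out) <- "integer"
  attr(out, "nRemoved") <- length(borderLabels)
  out
}

#' Automated cone counting on one field
#'
#' Runs the full automated counting chain on a field image: binarization,
#' removal of connected components smaller than \code{areaFraction} of the
#' average cone area, downsampling by \code{downsampleFactor},
#' watershed splitting of touching components on the distance transform,
#' and exclusion of components intersecting the right or bottom border.
#' Defaults follow the validated configuration (Otsu binarization, area
#' fraction 0.02, downsampling factor 0.3).
#'
#' If Otsu binarization is degenerate (blank field), the chain falls back
#' to the fixed threshold \code{fixedThreshold}.
#'
#' @param image a \linkS4class{FieldImage}.
#' @param binarizeMethod \code{"otsu"} (default) or \code{"fixed"}.
#' @param fixedThreshold threshold for the fixed method and the blank-field
#'   fallback (a.u., default 20).
#' @param areaFraction small-component threshold as a fraction of the mean
#'   cone area (default 0.02).
#' @param downsampleFactor mask downsampling factor (default 0.3).
#' @param meanConeAreaPx optional calibrated mean cone area (full-resolution
#'   pixels); by default self-calibrated per image.
#' @param nominalRadiusUm nominal cone inner-segment radius (um) used to set
#'   the watershed marker separation (default 2.5).
#' @param watershedTolerance distance-map height tolerance for splitting
#'   (default 0.5).
#' @return A \linkS4class{CountResult}.
#' @examples
#' f <- generateConeMosaic(6000, 80, 80, seed = 3, noiseSd = 0,
#'                         touchingFraction = 0)
#' nCones(countField(f$image)) == f$truth@nTotal
#' @export
countField <- function(image, binarizeMethod = c("otsu", "fixed"),
                       fixedThreshold = 20, areaFraction = 0.02,
                       downsampleFactor = 0.3, meanConeAreaPx = NULL,
                       nominalRadiusUm = 2.5, watershedTolerance = 0.5) {
  binarizeMethod <- match.arg(binarizeMethod)
  stageTry <- function(stage, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
  usedMethod <- binarizeMethod
  mask <- if (binarizeMethod == "otsu") {
    tryCatch(binarizeField(image, "otsu"), error = function(e) {
      usedMethod <<- "fixed (fallback)"
      binarizeField(image, "fixed", fixedThreshold)
    })
  } else {
    stageTry("binarize", binarizeField(image, "fixed", fixedThreshold))
  }
  filtered <- stageTry("filter_small",
                       filterSmall(mask, meanConeAreaPx, areaFraction))
  nSmall <- attr(filtered, "nRemoved")
  ds <- stageTry("downsample", downsampleMask(filtered, downsampleFactor))
  # the watershed height is the full-resolution distance transform sampled
  # at the downsampled grid: sub-pixel blob geometry survives downsampling
  height <- dsBorderMask <- NULL
  if (downsampleFactor < 1) {
    dmFull <- EBImage::distmap(filtered)
    idx <- dsIndices(dim(filtered), downsampleFactor)
    height <- asMatrix(dmFull)[idx$rows, idx$cols, drop = FALSE]
    # full-resolution border contact, projected to the downsampled grid:
    # a component grazing the last row/column only between sampled
    # positions must still count as border-intersecting
    labFull <- asMatrix(EBImage::bwlabel(filtered))
    d <- dim(labFull)
    bl <- unique(c(labFull[d[1], ], labFull[, d[2]]))
    bl <- bl[bl > 0]
    dsBorderMask <- matrix(labFull %in% bl, d[1], d[2])[idx$rows, idx$cols,
                                                        drop = FALSE]
  }
  radiusDsPx <- nominalRadiusUm / pxUm(image) * downsampleFactor
  labels <- stageTry("split_touching",
                     splitTouching(ds, minSepPx = 0.6 * radiusDsPx,
                                   tolerance = watershedTolerance,
                                   heightMap = height))
  nComp <- max(labels)
  areas <- if (nComp > 0) tabulate(labels[labels > 0], nbins = nComp)
           else integer(0)
  kept <- stageTry("exclude_border", excludeBorder(labels))
  nBorder <- attr(kept, "nRemoved")
  if (!is.null(dsBorderMask)) {
    extra <- setdiff(unique(kept[dsBorderMask]), 0L)
    if (length(extra)) {
      kept[kept %in% extra] <- 0L
      nBorder <- nBorder + length(extra)
    }
  }
  new("CountResult",
      nCones = as.integer(nComp - nBorder),
      nRemovedSmall = as.integer(nSmall),
      nRemovedBorder = as.integer(nBorder),
      componentAreasPx = as.integer(areas),
      params = list(binarizeMethod = usedMethod,
                    areaFraction = areaFraction,
                    downsampleFactor = downsampleFactor,
                    watershedTolerance = watershedTolerance,
                    nominalRadiusUm = nominalRadiusUm))
}

#' Validate automated counts against manual counts
#'
#' Computes the Pearson correlation between per-image manual and automated
#' counts, the per-image relative error (manual - automated) / manual, and
#' the overall accuracy 1 - mean(|error|).
#'
#' @param manual,automated integer vectors of equal length; all manual
#'   counts must be positive (the relative error is undefined at 0).
#' @return A \linkS4class{ComparisonStats}.
#' @examples
#' compareCounts(c(100, 200), c(95, 210))  # accuracy 0.95
#' @export
compareCounts <- function(manual, automated) {
  if (length(manual) != length(automated))
    stop("'manual' and 'automated' must have equal length")
  if (length(manual) == 0L) stop("empty count vectors")
  if (any(manual == 0))
    stop("manual count of 0: relative error undefined")
  errors <- (manual - automated) / manual
  r <- if (length(manual) < 2L || stats::var(manual) == 0 ||
           stats::var(automated) == 0) {
    warning("constant count vector: Pearson correlation undefined")
    NA_real_
  } else {
    stats::cor(manual, automated)
  }
  new("ComparisonStats", pearsonR = r, errors = errors,
      accuracy = 1 - mean(abs(errors)))
}
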