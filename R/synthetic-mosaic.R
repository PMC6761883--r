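#' @include AllClasses.R
NULL

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators never perturb the session stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Place cone centres (um) in a field with rejection sampling.  Non-touching
# centres keep >= sepFactor * radius separation; a designated fraction of
# cones is placed in touching pairs at 1.1--1.5 radii from their partner.
placeCones <- function(n, fieldWum, fieldHum, radiusUm, touchingFraction,
                       sepFactor = 2.2, maxAttempts = NULL) {
  if (n == 0L)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row_um", "col_um"))))
  if (is.null(maxAttempts)) maxAttempts <- 100L * n + 2000L
  # fast infeasibility check: disks of diameter minSep cannot pack beyond
  # ~90% of the field area even hexagonally
  packArea <- n * pi * (sepFactor * radiusUm / 2)^2
  if (packArea > 0.85 * fieldWum * fieldHum)
    stop("infeasible density: requested cones cannot be packed at the minimum separation")
  nPairs <- round(touchingFraction * n / 2)
  nSingles <- n - 2L * nPairs
  pos <- matrix(NA_real_, n, 2)
  partner <- integer(n)          # 0 = none
  minSep <- sepFactor * radiusUm
  rowRange <- c(radiusUm, fieldHum)
  colRange <- c(radiusUm, fieldWum)
  attempts <- 0L
  k <- 0L
  farEnough <- function(p, exclude = 0L) {
    if (k == 0L) return(TRUE)
    idx <- seq_len(k)
    if (exclude > 0L) idx <- idx[idx != exclude]
    if (length(idx) == 0L) return(TRUE)
    d2 <- (pos[idx, 1] - p[1])^2 + (pos[idx, 2] - p[2])^2
    all(d2 >= minSep^2)
  }
  drawPoint <- function() c(stats::runif(1, rowRange[1], rowRange[2]),
                            stats::runif(1, colRange[1], colRange[2]))
  # touching pairs first (hardest to place), then singles
  for (i in seq_len(nPairs)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop("infeasible density: cone placement failed after bounded retries")
      p1 <- drawPoint()
      if (!farEnough(p1)) next
      ang <- stats::runif(1, 0, 2 * pi)
      d <- stats::runif(1, 1.1, 1.5) * radiusUm
      p2 <- p1 + d * c(sin(ang), cos(ang))
      if (p2[1] < rowRange[1] || p2[1] > rowRange[2] ||
          p2[2] < colRange[1] || p2[2] > colRange[2]) next
      if (!farEnough(p2)) next
      pos[k + 1L, ] <- p1
      pos[k + 2L, ] <- p2
      partner[k + 1L] <- k + 2L
      partner[k + 2L] <- k + 1L
      k <- k + 2L
      break
    }
  }
  for (i in seq_len(nSingles)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop("infeasible density: cone placement failed after bounded retries")
      p <- drawPoint()
      if (farEnough(p)) {
        k <- k + 1L
        pos[k, ] <- p
        break
      }
    }
  }
  colnames(pos) <- c("row_um", "col_um")
  pos
}

# Render Gaussian-profile disks (peak `peak`, hard support of one radius)
# onto a zero background.  Also records, per blob, whether its rendered
# footprint reaches the last row (bottom border) or last column (right
# border) of the image.
renderBlobs <- function(nr, nc, posPx, radiusPx, peak = 200) {
  img <- matrix(0, nr, nc)
  touches <- logical(nrow(posPx))
  if (nrow(posPx) == 0L) return(list(img = img, touchesBorder = touches))
  sigma <- radiusPx / 1.5
  for (b in seq_len(nrow(posPx))) {
    r0 <- posPx[b, 1]; c0 <- posPx[b, 2]
    ri <- max(1L, floor(r0 - radiusPx)):min(nr, ceiling(r0 + radiusPx))
    ci <- max(1L, floor(c0 - radiusPx)):min(nc, ceiling(c0 + radiusPx))
    if (length(ri) == 0L || length(ci) == 0L) next
    d2 <- outer((ri - r0)^2, (ci - c0)^2, "+")
    inside <- d2 <= radiusPx^2
    blob <- peak * exp(-d2 / (2 * sigma^2))
    blob[!inside] <- 0
    img[ri, ci] <- img[ri, ci] + blob
    touches[b] <- (nr %in% ri && any(inside[ri == nr, ])) ||
                  (nc %in% ci && any(inside[, ci == nc]))
  }
  list(img = img, touchesBorder = touches)
}

#' Generate a ground-truthed synthetic cone-mosaic field
#'
#' Emulates a cone-arrestin-stained whole-mount counting field: bright
#' quasi-circular inner-segment profiles (2D Gaussian-profile disks of the
#' given radius, peak intensity 200/255) on a dark background, with a
#' configurable fraction of cones placed within 1.1--1.5 radii of a
#' neighbour so that their profiles merge into one connected component, plus
#' additive Gaussian noise clipped to [0, 255].  The truth records exact
#' placement and which blobs intersect the right or bottom field border
#' (excluded from counts by the counting convention).
#'
#' @param densityPerMm2 target cone density (cones/mm^2); the number placed
#'   is \code{round(density * field area)}.
#' @param fieldWum,fieldHum field width and height in micrometres
#'   (defaults: the 223.8 x 167.6 um counting field).
#' @param pxUm pixel size (um/px, default 0.32).
#' @param touchingFraction fraction of cones belonging to touching pairs
#'   (0--0.5).
#' @param noiseSd additive Gaussian noise SD (a.u.).
#' @param radiusUm nominal inner-segment radius (um, default 2.5).
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return list with elements \code{image} (a \linkS4class{FieldImage}) and
#'   \code{truth} (a \linkS4class{MosaicTruth}).
#' @examples
#' f <- generateConeMosaic(12000, seed = 1, noiseSd = 0, touchingFraction = 0)
#' f$truth
#' @export
generateConeMosaic <- function(densityPerMm2, fieldWum = 223.8,
                               fieldHum = 167.6, pxUm = 0.32,
                               touchingFraction = 0.1, noiseSd = 5,
                               radiusUm = 2.5, seed = 1) {
  if (densityPerMm2 <= 0) stop("'densityPerMm2' must be positive")
  if (pxUm <= 0) stop("'pxUm' must be positive")
  if (touchingFraction < 0 || touchingFraction > 0.5)
    stop("'touchingFraction' must lie in [0, 0.5]")
  if (fieldWum < 10 * pxUm || fieldHum < 10 * pxUm)
    stop("field dimensions must be at least 10 pixels")
  areaMm2 <- fieldWum * fieldHum * 1e-6
  n <- round(densityPerMm2 * areaMm2)
  nr <- round(fieldHum / pxUm)
  nc <- round(fieldWum / pxUm)
  withSeed(seed, {
    pos <- placeCones(n, fieldWum, fieldHum, radiusUm, touchingFraction)
    posPx <- cbind(pos[, 1] / pxUm + 0.5, pos[, 2] / pxUm + 0.5)
    rend <- renderBlobs(nr, nc, posPx, radiusUm / pxUm)
    img <- rend$img
    if (noiseSd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, noiseSd), nr, nc)
    img <- pmin(pmax(img, 0), 255)
    # border rule: a blob intersects the right/bottom border when its
    # rendered footprint reaches the last column/row of pixels
    border <- rend$touchesBorder
    truth <- new("MosaicTruth", positionsUm = pos, radiusUm = radiusUm,
                 borderFlag = border, nTotal = as.integer(sum(!border)),
                 nExcludable = as.integer(sum(border)))
    list(image = FieldImage(img, pxUm = pxUm), truth = truth)
  })
}

#' Generate a synthetic whole-retina cone distribution
#'
#' Places exactly \code{totalCones} cone centres on a disk of the given
#' area, either uniformly or with a linear centre-to-periphery density
#' decline, as the ground-truth oracle for the 16-field meridian sampling
#' estimator.
#'
#' @param totalCones exact number of cones to place (> 0).
#' @param retinaAreaMm2 retinal area (mm^2, default 15).
#' @param gradient linear density decline: the density at radial position r
#'   is proportional to \code{1 - gradient * r / R} (clamped at 0); 0 gives
#'   a uniform distribution.
#' @param seed integer seed.
#' @return A \linkS4class{WholeRetinaTruth}.
#' @examples
#' wr <- generateWholeRetina(1000, retinaAreaMm2 = 1, seed = 1)
#' nrow(wr@positionsMm)
#' @export
generateWholeRetina <- function(totalCones, retinaAreaMm2 = 15, gradient = 0,
                                seed = 1) {
  if (totalCones <= 0) stop("'totalCones' must be positive")
  if (retinaAreaMm2 <= 0) stop("'retinaAreaMm2' must be positive")
  if (gradient < 0) stop("'gradient' must be >= 0")
  R <- sqrt(retinaAreaMm2 / pi)
  withSeed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < totalCones) {
      m <- max(2L * (totalCones - length(xs)), 1000L)
      r <- R * sqrt(stats::runif(m))
      th <- stats::runif(m, 0, 2 * pi)
      keep <- if (gradient > 0)
        stats::runif(m) <= pmax(1 - gradient * r / R, 0)
      else rep(TRUE, m)
      xs <- c(xs, (r * cos(th))[keep])
      ys <- c(ys, (r * sin(th))[keep])
    }
    pos <- cbind(x_mm = xs[seq_len(totalCones)], y_mm = ys[seq_len(totalCones)])
    new("WholeRetinaTruth", positionsMm = pos, areaMm2 = retinaAreaMm2,
        gradient = gradient)
  })
}
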