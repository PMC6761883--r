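#' @include AllClasses.R synthetic-mosaic.R
NULL

#' Generate a ground-truthed two-channel RPE tile
#'
#' The green channel carries a polygonal tight-junction mesh: seed points
#' are scattered over the tile and the mesh is the boundary set of their
#' nearest-seed tessellation (pixels whose two nearest seeds are nearly
#' equidistant), about 2 px wide, at \code{junctionIntensity}.  Round
#' autofluorescent puncta (radius 2 px) are written into both channels at
#' the same coordinates (\code{punctaGreen} in green, \code{punctaRed} in
#' red); the red channel is otherwise zero.  Gaussian noise (clipped to
#' [0, 255]) is added to both channels.
#'
#' @param junctionIntensity mean green intensity on junction pixels
#'   (a.u., 0--255).
#' @param cellDensity polygonal cells per 100 x 100 px block (default 4).
#' @param punctaCount number of autofluorescent puncta.
#' @param punctaGreen,punctaRed puncta intensity in each channel (0--255).
#' @param noiseSd additive Gaussian noise SD.
#' @param width,height tile dimensions in pixels.
#' @param seed integer seed.
#' @return list with elements \code{tile} (a \linkS4class{TwoChannelTile})
#'   and \code{truth} (an \linkS4class{RPETileTruth}).
#' @examples
#' tl <- generateRPETile(17.14, punctaCount = 20, seed = 1, noiseSd = 0)
#' tl$truth@cellCount
#' @export
generateRPETile <- function(junctionIntensity, cellDensity = 4,
                            punctaCount = 30, punctaGreen = 200,
                            punctaRed = 50, noiseSd = 2,
                            width = 256, height = 256, seed = 1) {
  for (v in c(junctionIntensity, punctaGreen, punctaRed))
    if (v < 0 || v > 255) stop("intensities must lie in [0, 255]")
  if (punctaCount < 0) stop("'punctaCount' must be >= 0")
  nCells <- max(3L, round(cellDensity * width * height / 1e4))
  withSeed(seed, {
    sr <- stats::runif(nCells, 1, height)
    sc <- stats::runif(nCells, 1, width)
    px <- expand.grid(r = seq_len(height), c = seq_len(width))
    # distance from every pixel to every seed; mesh = near-ties between the
    # two closest seeds
    d2 <- outer(px$r, sr, "-")^2 + outer(px$c, sc, "-")^2
    twoSmallest <- apply(d2, 1L, function(z) sort.int(z, partial = 2)[1:2])
    isJunction <- (sqrt(twoSmallest[2, ]) - sqrt(twoSmallest[1, ])) <= 1
    junctionIdx <- sort((px$c[isJunction] - 1L) * height + px$r[isJunction])
    green <- matrix(0, height, width)
    green[junctionIdx] <- junctionIntensity
    red <- matrix(0, height, width)
    punctaIdx <- integer(0)
    if (punctaCount > 0) {
      pr <- stats::runif(punctaCount, 3, height - 2)
      pc <- stats::runif(punctaCount, 3, width - 2)
      for (i in seq_len(punctaCount)) {
        ri <- max(1L, floor(pr[i] - 2)):min(height, ceiling(pr[i] + 2))
        ci <- max(1L, floor(pc[i] - 2)):min(width, ceiling(pc[i] + 2))
        d2p <- outer((ri - pr[i])^2, (ci - pc[i])^2, "+")
        hit <- which(d2p <= 4, arr.ind = TRUE)
        idx <- (ci[hit[, 2]] - 1L) * height + ri[hit[, 1]]
        punctaIdx <- c(punctaIdx, idx)
      }
      punctaIdx <- sort(unique(punctaIdx))
      green[punctaIdx] <- punctaGreen
      red[punctaIdx] <- punctaRed
    }
    if (noiseSd > 0) {
      green <- green + matrix(stats::rnorm(length(green), 0, noiseSd),
                              height, width)
      red <- red + matrix(stats::rnorm(length(red), 0, noiseSd),
                          height, width)
    }
    green <- pmin(pmax(green, 0), 255)
    red <- pmin(pmax(red, 0), 255)
    truth <- new("RPETileTruth", junctionIntensity = junctionIntensity,
                 junctionIdx = as.integer(junctionIdx),
                 punctaIdx = as.integer(punctaIdx),
                 cellCount = as.integer(nCells))
    list(tile = TwoChannelTile(green, red), truth = truth)
  })
}
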