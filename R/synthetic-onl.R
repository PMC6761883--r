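#' @include AllClasses.R synthetic-mosaic.R
NULL

#' Generate a synthetic ONL row-count table
#'
#' Draws per-mouse, per-field outer-nuclear-layer row counts so that each
#' group's mean and coefficient of variation converge to the specified
#' values as the sample grows.  Counts are drawn from a normal distribution
#' with mean \code{meanRows} and SD \code{cvPercent/100 * meanRows},
#' resampled to stay positive.  Fields cycle through the four standard
#' eccentricities (peripheral/central x ventral/dorsal) across sections.
#'
#' @param groupSpecs a data.frame (or list of lists) with columns/elements
#'   \code{name}, \code{meanRows}, \code{cvPercent}, \code{nMice},
#'   \code{nFields} (fields per mouse; 12 = 4 eccentricities x 3 sections).
#' @param seed integer seed.
#' @return data.frame with columns group, mouse, section, eccentricity,
#'   rows.
#' @examples
#' spec <- data.frame(name = "WT", meanRows = 11.2, cvPercent = 8.5,
#'                    nMice = 4, nFields = 12)
#' head(generateONLTable(spec, seed = 1))
#' @export
generateONLTable <- function(groupSpecs, seed = 1) {
  if (!is.data.frame(groupSpecs))
    groupSpecs <- do.call(rbind, lapply(groupSpecs, as.data.frame))
  stopifnot(all(c("name", "meanRows", "cvPercent", "nMice", "nFields") %in%
                  names(groupSpecs)))
  if (any(groupSpecs$meanRows <= 0)) stop("'meanRows' must be positive")
  if (any(groupSpecs$cvPercent < 0)) stop("'cvPercent' must be >= 0")
  if (any(groupSpecs$nMice < 1) || any(groupSpecs$nFields < 1))
    stop("'nMice' and 'nFields' must be >= 1")
  eccLevels <- c("peripheral ventral", "central ventral",
                 "peripheral dorsal", "central dorsal")
  withSeed(seed, {
    out <- lapply(seq_len(nrow(groupSpecs)), function(g) {
      sp <- groupSpecs[g, ]
      sd <- sp$cvPercent / 100 * sp$meanRows
      n <- sp$nMice * sp$nFields
      vals <- stats::rnorm(n, sp$meanRows, sd)
      while (any(vals <= 0))
        vals[vals <= 0] <- stats::rnorm(sum(vals <= 0), sp$meanRows, sd)
      data.frame(
        group = sp$name,
        mouse = paste0(sp$name, "_m", rep(seq_len(sp$nMice), each = sp$nFields)),
        section = rep(rep(seq_len(ceiling(sp$nFields / 4)),
                          each = 4)[seq_len(sp$nFields)], sp$nMice),
        eccentricity = rep(rep_len(eccLevels, sp$nFields), sp$nMice),
        rows = vals
      )
    })
    do.call(rbind, out)
  })
}
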