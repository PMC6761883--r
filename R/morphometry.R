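#' @include AllClasses.R
NULL

#' Cone density of one counting field
#'
#' @param count cones counted in the field.
#' @param fieldAreaMm2 field area in mm^2 (the standard 223.8 x 167.6 um
#'   field is 0.0375 mm^2).
#' @return density in cones/mm^2.
#' @examples
#' fieldDensity(450, 223.8e-3 * 167.6e-3)  # ~12,000/mm2
#' @export
fieldDensity <- function(count, fieldAreaMm2) {
  if (fieldAreaMm2 <= 0) stop("'fieldAreaMm2' must be positive")
  count / fieldAreaMm2
}

#' Whole-retina cone total from meridian field sampling
#'
#' Estimates the total cone number of a retina as the mean of the per-field
#' densities multiplied by the measured retinal area, following the
#' 16-field two-meridian sampling scheme.
#'
#' @param sample a \linkS4class{RetinaSample}.
#' @return estimated total cones in the retina.
#' @examples
#' flds <- data.frame(meridian = "dorso-ventral", eccentricityIndex = 1:2,
#'                    count = c(225, 225), fieldAreaMm2 = 0.0375)
#' retinaTotal(RetinaSample("r1", flds, 15))  # 6000/mm2 * 15 mm2
#' @export
retinaTotal <- function(sample) {
  stopifnot(methods::is(sample, "RetinaSample"))
  dens <- sample@fields$count / sample@fields$fieldAreaMm2
  mean(dens) * sample@retinaAreaMm2
}

#' Coefficient of variation (percent)
#'
#' 100 x sample standard deviation (n - 1 denominator) divided by the mean;
#' the index used for intraretinal variation of degeneration.
#'
#' @param values numeric vector (>= 2 values, non-zero mean).
#' @return CV in percent.
#' @examples
#' coefficientOfVariation(c(8, 10, 12))  # 20
#' @export
coefficientOfVariation <- function(values) {
  if (length(values) < 2L) stop("at least 2 values required")
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Summarize per-retina values for one experimental group
#'
#' @param perRetinaValues numeric vector, one value per retina/mouse
#'   (>= 2).
#' @param groupName group label.
#' @return A \linkS4class{GroupSummary} with mean, SEM (sd/sqrt(n)) and CV
#'   (percent).
#' @examples
#' groupSummary(c(11.0, 11.5, 10.9, 11.4), "WT12")
#' @export
groupSummary <- function(perRetinaValues, groupName = "") {
  n <- length(perRetinaValues)
  if (n < 2L) stop("at least 2 retinas required per group")
  s <- stats::sd(perRetinaValues)
  m <- mean(perRetinaValues)
  new("GroupSummary", groupName = groupName, n = as.integer(n),
      mean = m, sem = s / sqrt(n),
      cvPercent = if (m != 0) 100 * s / m else NA_real_)
}

#' Per-group ONL row statistics with intraretinal variation
#'
#' For each retina (mouse), the coefficient of variation is computed across
#' its per-field row counts (all fields weighted equally) and the
#' per-retina mean row count across the same fields; per-group results are
#' the averages over retinas.  Retinas with fewer than 4 distinct
#' eccentricities trigger a warning and are computed on the available
#' fields.
#'
#' @param table data.frame with columns group, mouse, eccentricity, rows
#'   (as produced by \code{\link{generateONLTable}}).
#' @return list with elements \code{summaries} (list of
#'   \linkS4class{GroupSummary} of per-retina mean rows, by group),
#'   \code{cv} (named numeric, per-group mean CV percent) and
#'   \code{perRetina} (data.frame of per-retina means and CVs).
#' @examples
#' tab <- generateONLTable(data.frame(name = "WT", meanRows = 11.2,
#'   cvPercent = 8.5, nMice = 4, nFields = 12), seed = 1)
#' onlSummary(tab)$cv
#' @export
onlSummary <- function(table) {
  stopifnot(all(c("group", "mouse", "eccentricity", "rows") %in% names(table)))
  per <- do.call(rbind, lapply(split(table, table$mouse), function(d) {
    if (length(unique(d$eccentricity)) < 4L)
      warning(sprintf("retina '%s': missing eccentricities, computed on %d available fields",
                      d$mouse[1], nrow(d)))
    if (nrow(d) < 2L)
      stop(sprintf("retina '%s' needs >= 2 fields for a CV", d$mouse[1]))
    data.frame(group = d$group[1], mouse = d$mouse[1],
               meanRows = mean(d$rows),
               cvPercent = coefficientOfVariation(d$rows))
  }))
  rownames(per) <- NULL
  groups <- split(per, per$group)
  summaries <- lapply(groups, function(g) groupSummary(g$meanRows, g$group[1]))
  cv <- vapply(groups, function(g) mean(g$cvPercent), numeric(1))
  list(summaries = summaries, cv = cv, perRetina = per)
}

#' Sample 16 standard counting fields from a whole-retina truth
#'
#' Emulates the counting protocol: 8 fields along the dorso-ventral and 8
#' along the naso-temporal meridian at fractional eccentricities
#' +/- {0.2, 0.4, 0.6, 0.8} of the disk radius, each field a
#' \code{fieldWum} x \code{fieldHum} rectangle; cones of the synthetic
#' whole retina falling inside each rectangle are counted.
#'
#' @param truth a \linkS4class{WholeRetinaTruth}.
#' @param retinaId identifier for the resulting sample.
#' @param fieldWum,fieldHum field dimensions (um).
#' @return A \linkS4class{RetinaSample}.
#' @examples
#' wr <- generateWholeRetina(184922, seed = 1)
#' retinaTotal(sampleRetinaFields(wr))
#' @export
sampleRetinaFields <- function(truth, retinaId = "synthetic",
                               fieldWum = 223.8, fieldHum = 167.6) {
  stopifnot(methods::is(truth, "WholeRetinaTruth"))
  R <- sqrt(truth@areaMm2 / pi)
  ecc <- c(-0.8, -0.6, -0.4, -0.2, 0.2, 0.4, 0.6, 0.8)
  w <- fieldWum / 1000; h <- fieldHum / 1000
  x <- truth@positionsMm[, 1]; y <- truth@positionsMm[, 2]
  rows <- list()
  for (mer in c("dorso-ventral", "naso-temporal")) {
    for (i in seq_along(ecc)) {
      cx <- if (mer == "naso-temporal") ecc[i] * R else 0
      cy <- if (mer == "dorso-ventral") ecc[i] * R else 0
      inField <- x >= cx - w / 2 & x <= cx + w / 2 &
                 y >= cy - h / 2 & y <= cy + h / 2
      rows[[length(rows) + 1L]] <- data.frame(
        meridian = mer, eccentricityIndex = i, count = sum(inField),
        fieldAreaMm2 = w * h)
    }
  }
  RetinaSample(retinaId, do.call(rbind, rows), truth@areaMm2)
}
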