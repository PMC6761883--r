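#' @include AllClasses.R
NULL

#' Read and write field images as TIFF
#'
#' Single-channel 8-bit TIFF on the 0--255 intensity scale.  Pixel size and
#' metadata are not stored in the TIFF and must be supplied on reading.
#'
#' @param image a \linkS4class{FieldImage}.
#' @param path file path.
#' @param pxUm,fieldId,retinaId,eccentricityIndex,meridian metadata for the
#'   returned \linkS4class{FieldImage}.
#' @return \code{readFieldTIFF} returns a \linkS4class{FieldImage};
#'   \code{writeFieldTIFF} returns the path invisibly.
#' @rdname fieldTIFF
#' @export
writeFieldTIFF <- function(image, path) {
  stopifnot(methods::is(image, "FieldImage"))
  tiff::writeTIFF(pixels(image) / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname fieldTIFF
#' @export
readFieldTIFF <- function(path, pxUm = 0.32, fieldId = "", retinaId = "",
                          eccentricityIndex = NA_integer_, meridian = "") {
  px <- tiff::readTIFF(path) * 255
  if (length(dim(px)) == 3L) px <- px[, , 1]
  FieldImage(px, pxUm = pxUm, fieldId = fieldId, retinaId = retinaId,
             eccentricityIndex = eccentricityIndex, meridian = meridian)
}

#' Read and write two-channel RPE tiles as TIFF
#'
#' Channel order green, red; written as two pages of an 8-bit TIFF.
#'
#' @param tile a \linkS4class{TwoChannelTile}.
#' @param path file path.
#' @return \code{readTileTIFF} returns a \linkS4class{TwoChannelTile};
#'   \code{writeTileTIFF} returns the path invisibly.
#' @rdname tileTIFF
#' @export
writeTileTIFF <- function(tile, path) {
  stopifnot(methods::is(tile, "TwoChannelTile"))
  tiff::writeTIFF(list(greenChannel(tile) / 255, redChannel(tile) / 255),
                  path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname tileTIFF
#' @export
readTileTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) >= 2L)
  TwoChannelTile(pages[[1]] * 255, pages[[2]] * 255)
}

#' Read and write ERG traces as CSV
#'
#' Two columns (time_s, microvolts) preceded by a commented header line
#' carrying stimulus metadata:
#' \code{# onset_s=<x> flash_cd_s_m2=<x> condition=<x> background_cd_m2=<x>}.
#'
#' @param trace an \linkS4class{ERGTrace}.
#' @param path file path.
#' @return \code{readERGTraceCSV} returns an \linkS4class{ERGTrace};
#'   \code{writeERGTraceCSV} returns the path invisibly.
#' @rdname ergCSV
#' @export
writeERGTraceCSV <- function(trace, path) {
  stopifnot(methods::is(trace, "ERGTrace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# onset_s=%.9g flash_cd_s_m2=%.9g condition=%s background_cd_m2=%.9g",
                     trace@onset, trace@flash, trace@condition,
                     trace@background), con)
  utils::write.csv(data.frame(time_s = trace@t, microvolts = trace@v),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname ergCSV
#' @export
readERGTraceCSV <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#"))
    stop("missing metadata header line in trace CSV")
  kv <- strsplit(trimws(sub("^#\\s*", "", header)), "\\s+")[[1]]
  meta <- stats::setNames(
    lapply(strsplit(kv, "=", fixed = TRUE), `[`, 2),
    vapply(strsplit(kv, "=", fixed = TRUE), `[`, "", 1))
  d <- utils::read.csv(path, comment.char = "#")
  ERGTrace(t = d$time_s, v = d$microvolts,
           onset = as.numeric(meta$onset_s),
           flash = as.numeric(meta$flash_cd_s_m2),
           condition = meta$condition,
           background = as.numeric(meta$background_cd_m2))
}

#' Write generator truth as a JSON sidecar
#'
#' @param truth a \linkS4class{MosaicTruth}, \linkS4class{RPETileTruth},
#'   \linkS4class{ERGTruth} or \linkS4class{WholeRetinaTruth}.
#' @param path file path (.json).
#' @return the path, invisibly.
#' @export
writeTruthJSON <- function(truth, path) {
  slots <- methods::slotNames(class(truth))
  obj <- stats::setNames(lapply(slots, function(s) methods::slot(truth, s)),
                         slots)
  obj$class <- as.character(class(truth))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
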