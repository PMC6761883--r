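#' @include AllClasses.R
NULL

#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @export
setGeneric("pxUm", function(x) standardGeneric("pxUm"))

#' @export
setGeneric("nCones", function(x) standardGeneric("nCones"))

#' @export
setGeneric("nRemovedSmall", function(x) standardGeneric("nRemovedSmall"))

#' @export
setGeneric("nRemovedBorder", function(x) standardGeneric("nRemovedBorder"))

#' @export
setGeneric("componentAreasPx", function(x) standardGeneric("componentAreasPx"))

#' @export
setGeneric("countParams", function(x) standardGeneric("countParams"))

#' @export
setGeneric("greenChannel", function(x) standardGeneric("greenChannel"))

#' @export
setGeneric("redChannel", function(x) standardGeneric("redChannel"))

#' @export
setGeneric("voltages", function(x) standardGeneric("voltages"))

#' @export
setGeneric("times", function(x) standardGeneric("times"))

#' @export
setGeneric("stimulusOnset", function(x) standardGeneric("stimulusOnset"))

#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @export
setGeneric("groupMean", function(x) standardGeneric("groupMean"))

#' @export
setGeneric("groupSem", function(x) standardGeneric("groupSem"))

#' @export
setGeneric("cvPercent", function(x) standardGeneric("cvPercent"))
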