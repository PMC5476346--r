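#' @import methods
NULL

#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setGeneric("frameStart", function(x) standardGeneric("frameStart"))

#' @export
setGeneric("frameDuration", function(x) standardGeneric("frameDuration"))

#' @export
setGeneric("frameMid", function(x) standardGeneric("frameMid"))

#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))

#' @export
setGeneric("activity", function(x) standardGeneric("activity"))

#' @export
setGeneric("fitWeights", function(x) standardGeneric("fitWeights"))

#' @export
setGeneric("roiId", function(x) standardGeneric("roiId"))

#' @export
setGeneric("gmMap", function(x) standardGeneric("gmMap"))

#' @export
setGeneric("wmMap", function(x) standardGeneric("wmMap"))

#' @export
setGeneric("csfMap", function(x) standardGeneric("csfMap"))

#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @export
setGeneric("bpnd", function(object) standardGeneric("bpnd"))

#' @export
setGeneric("resultsTable", function(object, ...) standardGeneric("resultsTable"))

#' @export
setGeneric("modelName", function(object) standardGeneric("modelName"))
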