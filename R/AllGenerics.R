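#' Accessors for pullback and label objects
#'
#' @param x a \linkS4class{PullbackImage} or \linkS4class{LabelMap}.
#' @param i frame index (1-based).
#' @return \code{frames} and \code{labelArray} return the full 3-D array;
#'   \code{getFrame} and \code{getLabelFrame} return one frame as a matrix;
#'   \code{nFrames}, \code{nSamples}, \code{nALines} return counts;
#'   \code{radialRes} and \code{frameSpacing} return calibration in mm.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("nALines", function(x) standardGeneric("nALines"))
#' @rdname accessors
#' @export
setGeneric("radialRes", function(x) standardGeneric("radialRes"))
#' @rdname accessors
#' @export
setGeneric("frameSpacing", function(x) standardGeneric("frameSpacing"))
#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setGeneric("getLabelFrame", function(x, i) standardGeneric("getLabelFrame"))

#' @rdname accessors
#' @export
setMethod("frames", "PullbackImage", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("labelArray", "LabelMap", function(x) x@classes)
#' @rdname accessors
#' @export
setMethod("nFrames", "PullbackImage", function(x) dim(x@frames)[3])
#' @rdname accessors
#' @export
setMethod("nFrames", "LabelMap", function(x) dim(x@classes)[3])
#' @rdname accessors
#' @export
setMethod("nSamples", "PullbackImage", function(x) dim(x@frames)[1])
#' @rdname accessors
#' @export
setMethod("nSamples", "LabelMap", function(x) dim(x@classes)[1])
#' @rdname accessors
#' @export
setMethod("nALines", "PullbackImage", function(x) dim(x@frames)[2])
#' @rdname accessors
#' @export
setMethod("nALines", "LabelMap", function(x) dim(x@classes)[2])
#' @rdname accessors
#' @export
setMethod("radialRes", "PullbackImage", function(x) x@radialResMm)
#' @rdname accessors
#' @export
setMethod("frameSpacing", "PullbackImage", function(x) x@frameSpacingMm)
#' @rdname accessors
#' @export
setMethod("getFrame", "PullbackImage", function(x, i) x@frames[, , i])
#' @rdname accessors
#' @export
setMethod("getLabelFrame", "LabelMap", function(x, i) x@classes[, , i])
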