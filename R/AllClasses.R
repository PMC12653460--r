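#' @import methods
NULL

#' Pixel class vocabulary
#'
#' The ten pixel classes used throughout the package, in their fixed integer
#' coding (0-based, as stored in label arrays and emitted by the segmenter).
#' Classes 0--6 are the structural regions of any polar OCT frame; classes
#' 7--9 are the plaque morphologies (calcified, fibrous, lipidic).
#'
#' @return Character vector of length 10; element \code{i} names class code
#'   \code{i - 1}.
#' @examples
#' octClassNames()
#' @export
octClassNames <- function() {
  c("background", "lumen", "catheter", "lumen_boundary", "guidewire",
    "guidewire_shadow", "wall_tissue", "calcium", "fibrous", "lipid")
}

#' Plaque class codes
#'
#' Integer codes of the three plaque morphologies, in the order used by the
#' 3x3 plaque confusion matrix.
#'
#' @return Named integer vector (calcium, fibrous, lipid).
#' @export
octPlaqueClasses <- function() {
  c(calcium = 7L, fibrous = 8L, lipid = 9L)
}

.check_frames_array <- function(a, what = "frames") {
  if (!is.array(a) || length(dim(a)) != 3L)
    return(sprintf("%s must be a 3-D array (radial x angular x frame)", what))
  NULL
}

#' PullbackImage: a polar OCT pullback with physical calibration
#'
#' Stack of polar frames (rows = radial samples along each A-line, columns =
#' A-lines over 360 degrees, third dimension = frames along the pullback)
#' with intensities in [0, 255], plus the radial pixel size and the
#' longitudinal frame spacing in millimetres.
#'
#' @slot frames numeric array, \code{n_samples x n_alines x n_frames}, values
#'   in [0, 255].
#' @slot radialResMm radial sampling interval, mm per pixel.
#' @slot frameSpacingMm longitudinal distance between consecutive frames, mm.
#' @aliases PullbackImage-class
#' @exportClass PullbackImage
setClass("PullbackImage",
  representation(frames = "array", radialResMm = "numeric",
                 frameSpacingMm = "numeric"),
  validity = function(object) {
    msg <- .check_frames_array(object@frames)
    if (!is.null(msg)) return(msg)
    f <- object@frames
    if (!all(is.finite(f))) return("frame intensities must all be finite")
    if (min(f) < 0 || max(f) > 255)
      return("frame intensities must lie in [0, 255]")
    if (length(object@radialResMm) != 1L || !is.finite(object@radialResMm) ||
        object@radialResMm <= 0)
      return("radialResMm must be a single positive number")
    if (length(object@frameSpacingMm) != 1L ||
        !is.finite(object@frameSpacingMm) || object@frameSpacingMm <= 0)
      return("frameSpacingMm must be a single positive number")
    TRUE
  })

#' LabelMap: per-pixel class indices aligned to a PullbackImage
#'
#' @slot classes integer array with the same spatial shape as the paired
#'   \linkS4class{PullbackImage}; every pixel carries exactly one class code
#'   in 0..9.
#' @slot classNames the 10-entry class vocabulary (see
#'   \code{\link{octClassNames}}).
#' @aliases LabelMap-class
#' @exportClass LabelMap
setClass("LabelMap",
  representation(classes = "array", classNames = "character"),
  validity = function(object) {
    msg <- .check_frames_array(object@classes, "classes")
    if (!is.null(msg)) return(msg)
    cl <- object@classes
    if (anyNA(cl)) return("label classes must not contain NA")
    if (min(cl) < 0 || max(cl) > 9 || any(cl != round(cl)))
      return("label classes must be integers in 0..9")
    if (length(object@classNames) != 10L)
      return("classNames must have exactly 10 entries")
    TRUE
  })

#' PullbackImage constructor
#'
#' @param frames numeric array \code{n_samples x n_alines x n_frames} (a
#'   single matrix is promoted to a one-frame stack), intensities in [0, 255].
#' @param radialResMm radial mm per pixel.
#' @param frameSpacingMm frame spacing in mm.
#' @return A \linkS4class{PullbackImage}.
#' @export
PullbackImage <- function(frames, radialResMm, frameSpacingMm) {
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  new("PullbackImage", frames = frames, radialResMm = radialResMm,
      frameSpacingMm = frameSpacingMm)
}

#' LabelMap constructor
#'
#' @param classes integer array of class codes (a single matrix is promoted
#'   to a one-frame stack).
#' @param classNames class vocabulary; defaults to \code{octClassNames()}.
#' @return A \linkS4class{LabelMap}.
#' @export
LabelMap <- function(classes, classNames = octClassNames()) {
  if (is.matrix(classes)) dim(classes) <- c(dim(classes), 1L)
  storage.mode(classes) <- "integer"
  new("LabelMap", classes = classes, classNames = classNames)
}

#' EvalReport: validation statistics for a segmentation
#'
#' Bundles the per-class ROC/AUC analysis, Youden operating thresholds, the
#' 3x3 plaque confusion matrix with derived precision/recall/F1, the angular
#' (1-D) Dice overlap, and measurement-agreement statistics.
#'
#' @slot perClassAuc named numeric, AUC per evaluated pixel class.
#' @slot youdenThreshold named numeric, Youden-optimal probability threshold
#'   per evaluated class.
#' @slot confusion 3x3 integer matrix, rows = ground truth, columns =
#'   prediction, over (calcium, fibrous, lipid).
#' @slot perClassStats data.frame with precision, recall, F1 per plaque class.
#' @slot overallAccuracy trace of the confusion matrix over its total.
#' @slot dice1d numeric, angular Dice coefficient(s).
#' @slot agreement list with pearson_r, spearman_rho, icc and 95% CIs (empty
#'   when not computed).
#' @aliases EvalReport-class
#' @exportClass EvalReport
setClass("EvalReport",
  representation(perClassAuc = "numeric", youdenThreshold = "numeric",
                 confusion = "matrix", perClassStats = "data.frame",
                 overallAccuracy = "numeric", dice1d = "numeric",
                 agreement = "list"))

setMethod("show", "PullbackImage", function(object) {
  d <- dim(object@frames)
  cat(sprintf("PullbackImage: %d frame(s), %d radial samples x %d A-lines\n",
              d[3], d[1], d[2]))
  cat(sprintf("  radial resolution: %g mm/px, frame spacing: %g mm\n",
              object@radialResMm, object@frameSpacingMm))
  cat(sprintf("  pullback length: %g mm, imaging depth: %g mm\n",
              d[3] * object@frameSpacingMm, d[1] * object@radialResMm))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@classes)
  cat(sprintf("LabelMap: %d frame(s), %d x %d px, 10 classes\n",
              d[3], d[1], d[2]))
  tab <- table(factor(object@classes, levels = 0:9,
                      labels = object@classNames))
  present <- tab[tab > 0]
  cat("  pixels per class:\n")
  for (nm in names(present))
    cat(sprintf("    %-16s %d\n", nm, present[[nm]]))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  if (length(object@perClassAuc)) {
    cat("  per-class AUC:\n")
    for (nm in names(object@perClassAuc))
      cat(sprintf("    %-16s %.4f (Youden threshold %.4f)\n", nm,
                  object@perClassAuc[[nm]], object@youdenThreshold[[nm]]))
  }
  if (length(object@overallAccuracy))
    cat(sprintf("  plaque confusion overall accuracy: %.4f\n",
                object@overallAccuracy))
  if (length(object@dice1d))
    cat(sprintf("  angular Dice: %s\n",
                paste(sprintf("%.4f", object@dice1d), collapse = ", ")))
  if (length(object@agreement))
    cat(sprintf("  agreement: r = %.3f, rho = %.3f, ICC = %.3f\n",
                object@agreement$pearson_r, object@agreement$spearman_rho,
                object@agreement$icc))
})
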