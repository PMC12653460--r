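#' Read / write pullbacks as multi-frame TIFF with a JSON sidecar
#'
#' Image stacks are stored as multi-frame 8-bit grayscale TIFF on the 0--255
#' scale; calibration and the class vocabulary travel in a JSON metadata
#' sidecar (\code{radial_res_mm}, \code{frame_spacing_mm}, \code{n_frames},
#' \code{n_samples}, \code{n_alines}, \code{class_names}, plus provenance
#' fields \code{seed} and \code{config_hash} when supplied). Reading checks
#' that the sidecar dimensions agree with the TIFF and reports both shapes
#' when they do not. Write-then-read round-trips are bit-identical for 8-bit
#' content.
#'
#' @param pullback a \linkS4class{PullbackImage}.
#' @param tiff_path,meta_path file paths.
#' @param provenance optional named list merged into the sidecar (e.g. seed,
#'   config_hash).
#' @return \code{readPullback} returns a \linkS4class{PullbackImage};
#'   writers return their paths invisibly.
#' @export
writePullback <- function(pullback, tiff_path, meta_path,
                          provenance = list()) {
  a <- frames(pullback)
  imgs <- lapply(seq_len(dim(a)[3]), function(k) round(a[, , k]) / 255)
  tiff::writeTIFF(imgs, tiff_path, bits.per.sample = 8L)
  meta <- c(list(radial_res_mm = radialRes(pullback),
                 frame_spacing_mm = frameSpacing(pullback),
                 n_frames = dim(a)[3], n_samples = dim(a)[1],
                 n_alines = dim(a)[2], class_names = octClassNames()),
            provenance)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tiff_path, meta_path))
}

#' @rdname writePullback
#' @export
readPullback <- function(tiff_path, meta_path) {
  if (!file.exists(tiff_path)) stop("no such file: ", tiff_path)
  if (!file.exists(meta_path)) stop("no such file: ", meta_path)
  imgs <- tiff::readTIFF(tiff_path, all = TRUE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  a <- .stackFrames(imgs, meta, what = "pullback")
  PullbackImage(round(a * 255), meta$radial_res_mm, meta$frame_spacing_mm)
}

.stackFrames <- function(imgs, meta, what) {
  d <- dim(imgs[[1]])
  got <- c(d[1], d[2], length(imgs))
  want <- c(meta$n_samples, meta$n_alines, meta$n_frames)
  if (!identical(as.integer(got), as.integer(want)))
    stop(sprintf(
      "%s TIFF is %d x %d x %d but metadata declares %d x %d x %d",
      what, got[1], got[2], got[3], want[1], want[2], want[3]))
  a <- array(0, dim = got)
  for (k in seq_along(imgs)) a[, , k] <- imgs[[k]]
  a
}

#' Read / write label maps as multi-frame 8-bit TIFF
#'
#' Class codes 0..9 are stored directly in the 8-bit sample values.
#'
#' @param labelmap a \linkS4class{LabelMap}.
#' @param tiff_path,meta_path file paths (the sidecar may be shared with the
#'   paired pullback).
#' @param provenance optional named list merged into the sidecar.
#' @return \code{readLabelMap} returns a \linkS4class{LabelMap}.
#' @export
writeLabelMap <- function(labelmap, tiff_path, meta_path = NULL,
                          provenance = list()) {
  a <- labelArray(labelmap)
  imgs <- lapply(seq_len(dim(a)[3]), function(k) a[, , k] / 255)
  tiff::writeTIFF(imgs, tiff_path, bits.per.sample = 8L)
  if (!is.null(meta_path)) {
    meta <- c(list(n_frames = dim(a)[3], n_samples = dim(a)[1],
                   n_alines = dim(a)[2], class_names = labelmap@classNames),
              provenance)
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tiff_path)
}

#' @rdname writeLabelMap
#' @export
readLabelMap <- function(tiff_path, meta_path = NULL) {
  if (!file.exists(tiff_path)) stop("no such file: ", tiff_path)
  imgs <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.null(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    a <- .stackFrames(imgs, meta, what = "label")
  } else {
    a <- array(0, dim = c(dim(imgs[[1]]), length(imgs)))
    for (k in seq_along(imgs)) a[, , k] <- imgs[[k]]
  }
  LabelMap(array(as.integer(round(a * 255)), dim = dim(a)))
}

#' Stable hash of a configuration object
#'
#' MD5 of the canonical JSON serialization; embedded in output files for
#' provenance.
#'
#' @param x any jsonlite-serializable object.
#' @return Character MD5 hash.
#' @export
configHash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level blocks: \code{phantom}, \code{preprocess},
#' \code{augment}, \code{net}, \code{train}, \code{quantify}; each maps
#' field-for-field onto the corresponding config constructor arguments.
#'
#' @param path YAML file.
#' @return Named list of blocks.
#' @export
readPipelineConfig <- function(path) yaml::read_yaml(path)
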