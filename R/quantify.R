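#' ScoreRule: the OCT-calcium scoring thresholds
#'
#' A calcified lesion scores 1 point for maximum thickness strictly greater
#' than 0.5 mm, 2 points for maximum arc strictly greater than 180 degrees,
#' and 1 point for length strictly greater than 5 mm; the total lies in
#' 0..4. Scores of 3--4 indicate severe calcification with elevated risk of
#' stent under-expansion.
#'
#' @slot thicknessThresholdMm,thicknessPoints thickness criterion (> 0.5 mm,
#'   1 point).
#' @slot arcThresholdDeg,arcPoints arc criterion (> 180 deg, 2 points).
#' @slot lengthThresholdMm,lengthPoints length criterion (> 5 mm, 1 point).
#' @aliases ScoreRule-class
#' @exportClass ScoreRule
setClass("ScoreRule",
  representation(thicknessThresholdMm = "numeric", thicknessPoints = "numeric",
                 arcThresholdDeg = "numeric", arcPoints = "numeric",
                 lengthThresholdMm = "numeric", lengthPoints = "numeric"))

#' @rdname ScoreRule-class
#' @return \code{scoreRule()} returns the standard rule.
#' @export
scoreRule <- function() {
  new("ScoreRule", thicknessThresholdMm = 0.5, thicknessPoints = 1,
      arcThresholdDeg = 180, arcPoints = 2,
      lengthThresholdMm = 5, lengthPoints = 1)
}

#' LesionSummary: cross-frame calcium quantification
#'
#' @slot lengthMm longest contiguous calcified segment, mm.
#' @slot maxArcDeg largest single-frame arc, degrees.
#' @slot maxThicknessMm,minThicknessMm extreme single-plaque thicknesses, mm.
#' @slot score OCT-calcium score in 0..4.
#' @slot severity \code{"severe"} iff score >= 3, else \code{"non-severe"}.
#' @slot nPlaques number of per-frame plaque records contributing.
#' @aliases LesionSummary-class
#' @exportClass LesionSummary
setClass("LesionSummary",
  representation(lengthMm = "numeric", maxArcDeg = "numeric",
                 maxThicknessMm = "numeric", minThicknessMm = "numeric",
                 score = "integer", severity = "character",
                 nPlaques = "integer"),
  validity = function(object) {
    if (!object@score %in% 0:4) return("score must lie in 0..4")
    sev_expected <- if (object@score >= 3) "severe" else "non-severe"
    if (length(object@severity) && object@severity != sev_expected)
      return("severity must be severe iff score >= 3")
    TRUE
  })

setMethod("show", "LesionSummary", function(object) {
  cat(sprintf(
    "LesionSummary: length %.2f mm, max arc %.1f deg, thickness %.2f-%.2f mm\n",
    object@lengthMm, object@maxArcDeg, object@minThicknessMm,
    object@maxThicknessMm))
  cat(sprintf("  OCT-calcium score %d (%s), %d plaque record(s)\n",
              object@score, object@severity, object@nPlaques))
})

#' @rdname LesionSummary-class
#' @param x a LesionSummary.
#' @param ... unused.
#' @export
setMethod("as.list", "LesionSummary", function(x, ...) {
  list(length_mm = x@lengthMm, max_arc_deg = x@maxArcDeg,
       max_thickness_mm = x@maxThicknessMm,
       min_thickness_mm = x@minThicknessMm, score = x@score,
       severity = x@severity, n_plaques = x@nPlaques)
})

# ---- connected components on the polar grid -------------------------------

# Vertical runs of TRUE per column of a logical matrix; 8-connected
# union-find across adjacent columns with wrap across the angular seam.
# Returns an integer matrix of component ids (0 = background).
.polarComponents <- function(mask) {
  nr <- nrow(mask); na <- ncol(mask)
  runs <- vector("list", na)
  nrun <- 0L
  for (j in seq_len(na)) {
    col <- mask[, j]
    if (!any(col)) { runs[[j]] <- matrix(integer(), 0, 3); next }
    d <- diff(c(FALSE, col, FALSE))
    a <- which(d == 1L); b <- which(d == -1L) - 1L
    runs[[j]] <- cbind(a, b, nrun + seq_along(a))
    nrun <- nrun + length(a)
  }
  parent <- seq_len(nrun)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  link_cols <- function(j1, j2) {
    r1 <- runs[[j1]]; r2 <- runs[[j2]]
    if (!nrow(r1) || !nrow(r2)) return(invisible())
    for (i in seq_len(nrow(r1)))
      for (k in seq_len(nrow(r2)))
        if (r2[k, 1] <= r1[i, 2] + 1L && r2[k, 2] >= r1[i, 1] - 1L)
          union(r1[i, 3], r2[k, 3])
  }
  if (na > 1L) {
    for (j in seq_len(na - 1L)) link_cols(j, j + 1L)
    link_cols(na, 1L)   # angular wrap
  }
  out <- matrix(0L, nr, na)
  if (nrun == 0L) return(out)
  root <- vapply(seq_len(nrun), find, integer(1))
  ids <- match(root, sort(unique(root)))
  for (j in seq_len(na)) {
    r <- runs[[j]]
    if (nrow(r)) for (i in seq_len(nrow(r)))
      out[r[i, 1]:r[i, 2], j] <- ids[r[i, 3]]
  }
  out
}

# circular span of a set of occupied column indices (1-based):
# returns c(start_col, n_cols); the span is the smallest circular interval
# covering all occupied columns.
.circularSpan <- function(cols, na) {
  cols <- sort(unique(cols))
  n <- length(cols)
  if (n == na) return(c(1L, na))
  ext <- c(cols, cols[1] + na)
  gaps <- diff(ext)
  g <- which.max(gaps)          # largest circular gap; span starts after it
  start <- ext[g + 1]
  c(((start - 1L) %% na) + 1L, na - (max(gaps) - 1L))
}

#' Extract per-frame plaque measurements from a label frame
#'
#' Finds the angularly connected components (8-connectivity on the polar
#' grid, wrapping across theta = 0/360) of a target plaque class and
#' measures each: arc as the angular extent in degrees, thickness as the
#' per-A-line radial pixel extent times the radial resolution (min and max
#' over the component's A-lines). A component whose abluminal border abuts a
#' signal-void region (guidewire shadow or background) is flagged as
#' truncated, since near-infrared shadowing hides the true posterior border.
#'
#' @param labels integer label matrix (radial x angular) or a
#'   \linkS4class{LabelMap} with \code{frame}.
#' @param radial_res_mm radial pixel size, mm (required for a matrix input).
#' @param target_class integer class code (default calcium, 7).
#' @param frame frame index when \code{labels} is a \linkS4class{LabelMap}.
#' @return data.frame with one row per plaque: \code{frame_index},
#'   \code{arc_deg}, \code{theta_start_deg}, \code{theta_end_deg} (half-open
#'   span), \code{min_thickness_mm}, \code{max_thickness_mm},
#'   \code{n_pixels}, \code{truncated}.
#' @export
extractPlaques <- function(labels, radial_res_mm = NULL,
                           target_class = octPlaqueClasses()[["calcium"]],
                           frame = 1L) {
  if (is(labels, "LabelMap")) {
    lab <- getLabelFrame(labels, frame)
  } else lab <- labels
  if (is.null(radial_res_mm) || !is.finite(radial_res_mm) ||
      radial_res_mm <= 0)
    stop("extractPlaques requires a positive radial_res_mm calibration")
  nr <- nrow(lab); na <- ncol(lab)
  binw <- 360 / na
  comp <- .polarComponents(lab == target_class)
  k <- max(comp)
  void <- c(0L, 5L)   # background, guidewire_shadow
  out <- lapply(seq_len(k), function(id) {
    idx <- which(comp == id, arr.ind = TRUE)
    colsz <- table(idx[, 2])
    cols <- as.integer(names(colsz))
    span <- .circularSpan(cols, na)
    ext_px <- as.integer(colsz)
    # truncation: outermost pixel per column against a signal-void neighbour
    rmax <- vapply(cols, function(j) max(idx[idx[, 2] == j, 1]), integer(1))
    trunc <- any(rmax == nr) ||
      any(lab[cbind(pmin(rmax + 1L, nr), cols)] %in% void)
    data.frame(frame_index = frame, arc_deg = span[2] * binw,
               theta_start_deg = (span[1] - 1L) * binw,
               theta_end_deg = ((span[1] - 1L + span[2]) * binw) %% 360,
               min_thickness_mm = min(ext_px) * radial_res_mm,
               max_thickness_mm = max(ext_px) * radial_res_mm,
               n_pixels = nrow(idx), truncated = trunc)
  })
  if (!length(out))
    return(data.frame(frame_index = integer(), arc_deg = numeric(),
                      theta_start_deg = numeric(), theta_end_deg = numeric(),
                      min_thickness_mm = numeric(),
                      max_thickness_mm = numeric(), n_pixels = integer(),
                      truncated = logical()))
  do.call(rbind, out)
}

#' Extract plaques on every frame of a label map
#'
#' @param labelmap a \linkS4class{LabelMap}.
#' @param radial_res_mm radial pixel size, mm.
#' @param target_class integer class code.
#' @return data.frame of per-frame plaque records (see
#'   \code{\link{extractPlaques}}).
#' @export
extractPlaquesStack <- function(labelmap, radial_res_mm,
                                target_class = octPlaqueClasses()[["calcium"]]) {
  res <- lapply(seq_len(nFrames(labelmap)), function(k)
    extractPlaques(labelmap, radial_res_mm, target_class, frame = k))
  do.call(rbind, res)
}

# 1-degree angular bins (0..359) covered by the half-open spans in a
# per-frame plaque table
.arcBins <- function(plaques) {
  bins <- logical(360)
  for (i in seq_len(nrow(plaques))) {
    n <- max(1L, round(plaques$arc_deg[i]))
    b <- (floor(plaques$theta_start_deg[i]) + seq_len(n) - 1L) %% 360L
    bins[b + 1L] <- TRUE
  }
  bins
}

#' Frame indices annotated at fixed longitudinal intervals
#'
#' Returns the 1-based frame indices sampled every \code{interval_mm} of
#' pullback, i.e. indices 1, 1+k, 1+2k, ... with
#' \code{k = round(interval_mm / frame_spacing_mm)}.
#'
#' @param n_frames number of frames in the pullback.
#' @param frame_spacing_mm frame spacing, mm.
#' @param interval_mm sampling interval, mm; must be >= the frame spacing.
#' @return Integer vector of frame indices.
#' @examples
#' sampleFrames(50, 0.2, 1)   # every 5th frame
#' @export
sampleFrames <- function(n_frames, frame_spacing_mm, interval_mm) {
  if (frame_spacing_mm <= 0) stop("frame_spacing_mm must be > 0")
  if (interval_mm < frame_spacing_mm)
    stop("interval_mm must be >= frame_spacing_mm")
  k <- as.integer(max(1, round(interval_mm / frame_spacing_mm)))
  seq.int(1L, as.integer(n_frames), by = k)
}

.longestRun <- function(flags) {
  if (!any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

#' Length of the longest contiguous calcified segment
#'
#' Two conventions are supported. \code{every_frame} (the automated reading):
#' consecutive frames are contiguous when their calcium arcs share at least
#' one angular degree bin; the segment length is the run's frame count times
#' the frame spacing. \code{interval_quadrant} (the manual reading): frames
#' are sampled every \code{interval_mm}, contiguity requires calcium in the
#' same 90-degree quadrant on consecutive sampled frames, and the length is
#' the run count times the interval.
#'
#' @param per_frame_plaques data.frame of plaque records as returned by
#'   \code{\link{extractPlaquesStack}}.
#' @param n_frames total number of frames in the pullback.
#' @param mode \code{"every_frame"} or \code{"interval_quadrant"}.
#' @param frame_spacing_mm frame spacing, mm.
#' @param interval_mm sampling interval for \code{interval_quadrant}, mm.
#' @return Length in mm (0 when no frame carries the target class).
#' @export
lesionLength <- function(per_frame_plaques, n_frames,
                         mode = c("every_frame", "interval_quadrant"),
                         frame_spacing_mm, interval_mm = 1) {
  mode <- match.arg(mode)
  if (is.null(per_frame_plaques) || nrow(per_frame_plaques) == 0L) return(0)
  bins_by_frame <- lapply(seq_len(n_frames), function(k) {
    p <- per_frame_plaques[per_frame_plaques$frame_index == k, , drop = FALSE]
    if (nrow(p)) .arcBins(p) else logical(360)
  })
  has <- vapply(bins_by_frame, any, logical(1))
  if (mode == "every_frame") {
    if (!any(has)) return(0)
    # contiguity: angular overlap >= 1 degree bin between consecutive frames
    run <- 0L; best <- 0L
    for (k in seq_len(n_frames)) {
      if (!has[k]) { run <- 0L; next }
      if (run == 0L) run <- 1L
      else if (any(bins_by_frame[[k]] & bins_by_frame[[k - 1L]]))
        run <- run + 1L
      else run <- 1L
      best <- max(best, run)
    }
    return(best * frame_spacing_mm)
  }
  idx <- sampleFrames(n_frames, frame_spacing_mm, interval_mm)
  quad <- function(bins) vapply(0:3, function(q)
    any(bins[(90 * q + 1):(90 * (q + 1))]), logical(1))
  qmat <- t(vapply(bins_by_frame[idx], quad, logical(4)))
  best <- max(vapply(1:4, function(q) .longestRun(qmat[, q]), integer(1)))
  best * interval_mm
}

#' OCT-calcium score
#'
#' Sum of points for strictly exceeding each threshold of the scoring rule:
#' maximum thickness > 0.5 mm earns 1 point, maximum arc > 180 degrees earns
#' 2 points, length > 5 mm earns 1 point. Values exactly at a threshold earn
#' no point.
#'
#' @param max_thickness_mm,max_arc_deg,length_mm lesion measures; all
#'   nonnegative.
#' @param rule a \linkS4class{ScoreRule}.
#' @return Integer score in 0..4.
#' @examples
#' octCalciumScore(0.6, 200, 6)    # 4
#' octCalciumScore(0.5, 180, 5)    # 0: equality earns no point
#' @export
octCalciumScore <- function(max_thickness_mm, max_arc_deg, length_mm,
                            rule = scoreRule()) {
  if (any(c(max_thickness_mm, max_arc_deg, length_mm) < 0))
    stop("lesion measures must be nonnegative")
  s <- rule@thicknessPoints * (max_thickness_mm > rule@thicknessThresholdMm) +
    rule@arcPoints * (max_arc_deg > rule@arcThresholdDeg) +
    rule@lengthPoints * (length_mm > rule@lengthThresholdMm)
  as.integer(s)
}

#' Dichotomize an OCT-calcium score into severity
#'
#' @param score integer score in 0..4.
#' @return \code{"severe"} for scores 3--4, \code{"non-severe"} for 0--2.
#' @export
dichotomize <- function(score) {
  if (any(!score %in% 0:4)) stop("score must lie in 0..4")
  ifelse(score >= 3, "severe", "non-severe")
}

#' Quantify calcium over a whole pullback
#'
#' Extracts per-frame calcified plaques, summarizes the lesion (cross-frame
#' length, per-frame arc and thickness extremes), scores it, and
#' dichotomizes the score.
#'
#' @param labelmap a \linkS4class{LabelMap}.
#' @param radial_res_mm,frame_spacing_mm calibration, mm.
#' @param mode lesion-length convention (see \code{\link{lesionLength}}).
#' @param interval_mm sampling interval for \code{interval_quadrant}.
#' @param target_class plaque class code (default calcium).
#' @param rule a \linkS4class{ScoreRule}.
#' @return A \linkS4class{LesionSummary}.
#' @export
quantifyCalcium <- function(labelmap, radial_res_mm, frame_spacing_mm,
                            mode = "every_frame", interval_mm = 1,
                            target_class = octPlaqueClasses()[["calcium"]],
                            rule = scoreRule()) {
  pl <- extractPlaquesStack(labelmap, radial_res_mm, target_class)
  len <- lesionLength(pl, nFrames(labelmap), mode, frame_spacing_mm,
                      interval_mm)
  if (!nrow(pl)) {
    return(new("LesionSummary", lengthMm = 0, maxArcDeg = 0,
               maxThicknessMm = 0, minThicknessMm = 0, score = 0L,
               severity = "non-severe", nPlaques = 0L))
  }
  sc <- octCalciumScore(max(pl$max_thickness_mm), max(pl$arc_deg), len, rule)
  new("LesionSummary", lengthMm = len, maxArcDeg = max(pl$arc_deg),
      maxThicknessMm = max(pl$max_thickness_mm),
      minThicknessMm = min(pl$min_thickness_mm), score = sc,
      severity = dichotomize(sc), nPlaques = nrow(pl))
}
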