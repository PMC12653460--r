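#' AugmentConfig: intravascular artifact simulation settings
#'
#' Parameters for the three training-time artifact models: non-uniform
#' rotational distortion (NURD, a smooth periodic angular warp), radial
#' motion shift, and multiple reflection (a ghost copy of each A-line's
#' proximal segment at double depth).
#'
#' @slot nurdAmplitudeDeg maximum angular displacement of the NURD warp, deg.
#' @slot nurdFrequency warp cycles per revolution.
#' @slot motionShiftPx maximum absolute radial shift, pixels.
#' @slot reflectionGain ghost-echo gain in [0, 1].
#' @slot probNurd,probMotion,probReflection per-artifact application
#'   probabilities in [0, 1].
#' @slot seed integer seed for the augmentation stream.
#' @aliases AugmentConfig-class
#' @exportClass AugmentConfig
setClass("AugmentConfig",
  representation(nurdAmplitudeDeg = "numeric", nurdFrequency = "numeric",
                 motionShiftPx = "integer", reflectionGain = "numeric",
                 probNurd = "numeric", probMotion = "numeric",
                 probReflection = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@nurdAmplitudeDeg < 0 || object@nurdFrequency < 0)
      return("NURD amplitude and frequency must be nonnegative")
    if (object@motionShiftPx < 0)
      return("motionShiftPx must be nonnegative")
    if (object@reflectionGain < 0 || object@reflectionGain > 1)
      return("reflectionGain must lie in [0, 1]")
    p <- c(object@probNurd, object@probMotion, object@probReflection)
    if (any(p < 0 | p > 1)) return("probabilities must lie in [0, 1]")
    TRUE
  })

#' Build an AugmentConfig
#'
#' The default NURD warp (amplitude 1.5 degrees, one cycle per revolution)
#' is a mild distortion: a feature boundary moves by at most the amplitude,
#' so the pixel count of an arc of width \code{w} degrees changes by at most
#' roughly \code{2 * amplitude / w} — under 5\% for the plaque arcs the
#' phantoms produce — keeping augmented labels statistically faithful.
#'
#' @param nurd_amplitude_deg,nurd_frequency NURD warp amplitude (deg) and
#'   frequency (cycles/revolution).
#' @param motion_shift_px maximum radial shift in pixels.
#' @param reflection_gain ghost gain in [0, 1].
#' @param prob_nurd,prob_motion,prob_reflection application probabilities.
#' @param seed integer seed.
#' @return An \linkS4class{AugmentConfig}.
#' @export
augmentConfig <- function(nurd_amplitude_deg = 1.5, nurd_frequency = 1,
                          motion_shift_px = 4L, reflection_gain = 0.25,
                          prob_nurd = 0.5, prob_motion = 0.5,
                          prob_reflection = 0.3, seed = 1L) {
  new("AugmentConfig", nurdAmplitudeDeg = nurd_amplitude_deg,
      nurdFrequency = nurd_frequency,
      motionShiftPx = as.integer(motion_shift_px),
      reflectionGain = reflection_gain, probNurd = prob_nurd,
      probMotion = prob_motion, probReflection = prob_reflection,
      seed = as.integer(seed))
}

# displacement (degrees) at angles theta_deg
.nurdDisplacement <- function(theta_deg, amplitude, frequency, phase) {
  amplitude * sin(2 * pi * frequency * theta_deg / 360 + phase)
}

#' Non-uniform rotational distortion warp
#'
#' Applies the smooth periodic angular displacement field
#' \code{theta' = theta + A sin(2 pi f theta / 360 + phase)} to a frame
#' and (identically) to its label map, wrapping across 0/360. The image is
#' resampled with linear interpolation along theta, labels with
#' nearest-neighbour, so a pixel's class travels with its intensity.
#' The warp must remain monotone in theta: \code{A f (2 pi / 360) < 1};
#' configurations violating this are rejected.
#'
#' @param image numeric matrix (radial x angular).
#' @param labels integer matrix, same shape (optional, NULL to skip).
#' @param amplitude_deg,frequency,phase warp parameters.
#' @return List \code{(image, labels)} after the warp.
#' @export
nurdWarp <- function(image, labels = NULL, amplitude_deg, frequency,
                     phase = 0) {
  if (amplitude_deg * frequency * 2 * pi / 360 >= 1)
    stop("NURD warp is non-monotone in theta: reduce amplitude or frequency")
  na <- ncol(image)
  if (amplitude_deg == 0)
    return(list(image = image, labels = labels))
  theta <- (seq_len(na) - 1) * 360 / na
  src <- theta + .nurdDisplacement(theta, amplitude_deg, frequency, phase)
  src_idx <- (src / (360 / na)) %% na          # 0-based fractional column
  j0 <- floor(src_idx)
  w <- src_idx - j0
  jlo <- (as.integer(j0) %% na) + 1L
  jhi <- (as.integer(j0 + 1) %% na) + 1L
  wim <- sweep(image[, jlo, drop = FALSE], 2, 1 - w, "*") +
         sweep(image[, jhi, drop = FALSE], 2, w, "*")
  wlab <- NULL
  if (!is.null(labels)) {
    jnn <- (as.integer(round(src_idx)) %% na) + 1L
    wlab <- labels[, jnn, drop = FALSE]
  }
  list(image = wim, labels = wlab)
}

#' Radial motion shift
#'
#' Shifts all A-lines of a frame jointly by \code{shift_px} radial pixels:
#' the content of pixel (r, theta) moves to (r + shift, theta). Vacated
#' pixels are zero-filled in the image and labelled background in the label
#' map. Negative shifts move content toward the catheter, vacating the far
#' edge.
#'
#' @param image numeric matrix (radial x angular).
#' @param labels integer matrix, same shape (optional).
#' @param shift_px signed integer radial shift; |shift| must be smaller than
#'   the number of radial samples.
#' @param background_class label assigned to shifted-in pixels (default 0).
#' @return List \code{(image, labels)}.
#' @export
motionShift <- function(image, labels = NULL, shift_px,
                        background_class = 0L) {
  nr <- nrow(image)
  s <- as.integer(shift_px)
  if (abs(s) >= nr) stop("|shift_px| must be < number of radial samples")
  if (s == 0) return(list(image = image, labels = labels))
  out <- matrix(0, nr, ncol(image))
  lout <- if (is.null(labels)) NULL else
    matrix(as.integer(background_class), nr, ncol(image))
  if (s > 0) {
    out[(s + 1L):nr, ] <- image[1:(nr - s), ]
    if (!is.null(labels)) lout[(s + 1L):nr, ] <- labels[1:(nr - s), ]
  } else {
    out[1:(nr + s), ] <- image[(1L - s):nr, ]
    if (!is.null(labels)) lout[1:(nr + s), ] <- labels[(1L - s):nr, ]
  }
  list(image = out, labels = lout)
}

#' Multiple-reflection ghost
#'
#' Adds to each A-line a ghost copy of its proximal half at double depth:
#' \code{out[2r] = in[2r] + gain * in[r]}, clipped to [0, 255]. Labels are
#' unchanged (the ghost is an optical artifact, not tissue).
#'
#' @param image numeric matrix (radial x angular), values in [0, 255].
#' @param gain ghost gain in [0, 1]; 0 is the identity.
#' @return The augmented image matrix.
#' @export
multipleReflection <- function(image, gain) {
  if (gain < 0 || gain > 1) stop("reflection gain must lie in [0, 1]")
  if (gain == 0) return(image)
  nr <- nrow(image)
  half <- seq_len(nr %/% 2)
  out <- image
  out[2L * half, ] <- out[2L * half, ] + gain * image[half, ]
  pmin(pmax(out, 0), 255)
}

#' Apply the seeded augmentation stream to one frame
#'
#' Draws artifact parameters from the configured ranges and applies, in fixed
#' order, NURD warp, motion shift and multiple reflection, each with its
#' configured probability. Image and labels are transported by identical
#' spatial maps. The stream is reproducible: the same \code{(cfg, draw)} pair
#' always produces the same augmentation.
#'
#' @param image numeric matrix (radial x angular) in [0, 255].
#' @param labels integer matrix, same shape.
#' @param cfg an \linkS4class{AugmentConfig}.
#' @param draw integer; different draws give independent augmentations under
#'   one seed.
#' @return List \code{(image, labels)}.
#' @export
augmentFrame <- function(image, labels, cfg, draw = 1L) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg@seed + 7919L * as.integer(draw))
  u <- stats::runif(3)
  if (u[1] < cfg@probNurd && cfg@nurdAmplitudeDeg > 0) {
    amp <- stats::runif(1, 0, cfg@nurdAmplitudeDeg)
    ph <- stats::runif(1, 0, 2 * pi)
    w <- nurdWarp(image, labels, amp, cfg@nurdFrequency, ph)
    image <- w$image; labels <- w$labels
  }
  if (u[2] < cfg@probMotion && cfg@motionShiftPx > 0) {
    s <- sample(seq(-cfg@motionShiftPx, cfg@motionShiftPx), 1)
    m <- motionShift(image, labels, s)
    image <- m$image; labels <- m$labels
  }
  if (u[3] < cfg@probReflection && cfg@reflectionGain > 0) {
    g <- stats::runif(1, 0, cfg@reflectionGain)
    image <- multipleReflection(image, g)
  }
  list(image = image, labels = labels)
}
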