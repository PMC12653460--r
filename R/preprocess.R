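#' PreprocessConfig: polar frame to network-tensor settings
#'
#' @slot logCompress apply log compression to the intensity channel.
#' @slot gamma gamma exponent applied to the scaled attenuation channel
#'   (values in [0,1] raised to \code{gamma} before rescaling to 0--255);
#'   gamma < 1 brightens low attenuation estimates.
#' @slot normCenter,normScale the fixed affine normalization constants
#'   (127.5 each): channels are mapped to [-1, 1] as (x - 127.5) / 127.5.
#' @slot attenuationWindow number of distal radial samples masked to zero in
#'   the attenuation channel, where the estimator's truncated tail sum is
#'   unreliable.
#' @slot muMax attenuation value (mm^-1) mapped to full scale when the
#'   estimate is squeezed into [0, 1]; estimates above it are clipped.
#' @aliases PreprocessConfig-class
#' @exportClass PreprocessConfig
setClass("PreprocessConfig",
  representation(logCompress = "logical", gamma = "numeric",
                 normCenter = "numeric", normScale = "numeric",
                 attenuationWindow = "integer", muMax = "numeric"),
  validity = function(object) {
    if (object@gamma <= 0) return("gamma must be > 0")
    if (object@normCenter != 127.5 || object@normScale != 127.5)
      return("normalization constants are fixed at 127.5")
    if (object@muMax <= 0) return("muMax must be > 0")
    if (object@attenuationWindow < 0) return("attenuationWindow must be >= 0")
    TRUE
  })

#' @rdname preprocessConfig
#' @export
setMethod("show", "PreprocessConfig", function(object) {
  cat(sprintf(
    "PreprocessConfig: log=%s, gamma=%g, window=%d px, muMax=%g mm^-1\n",
    object@logCompress, object@gamma, object@attenuationWindow, object@muMax))
})

#' Build a PreprocessConfig
#'
#' @param log_compress logical, log-compress the intensity channel.
#' @param gamma attenuation-channel gamma (default 0.5).
#' @param attenuation_window distal samples masked in the attenuation channel.
#' @param mu_max full-scale attenuation, mm^-1.
#' @return A \linkS4class{PreprocessConfig}.
#' @export
preprocessConfig <- function(log_compress = TRUE, gamma = 0.5,
                             attenuation_window = 32L, mu_max = 10) {
  new("PreprocessConfig", logCompress = log_compress, gamma = gamma,
      normCenter = 127.5, normScale = 127.5,
      attenuationWindow = as.integer(attenuation_window), muMax = mu_max)
}

#' Log-compress a polar frame
#'
#' Maps nonnegative intensities through \code{log(1 + I)} and affinely
#' rescales the result to [0, 255]. The map is monotone, so pixel ordering is
#' preserved; a constant frame maps to a constant frame (returned unchanged
#' on the 0--255 scale since the affine rescale is then degenerate).
#'
#' @param frame numeric matrix of nonnegative intensities.
#' @return Matrix of the same shape with values in [0, 255].
#' @export
logPolar <- function(frame) {
  if (any(frame < 0)) stop("logPolar requires nonnegative intensities")
  x <- log1p(frame)
  lo <- min(x); hi <- max(x)
  if (hi - lo < .Machine$double.eps) return(frame * 0 + 255 * (min(frame) > 0))
  (x - lo) / (hi - lo) * 255
}

#' Depth-resolved attenuation channel
#'
#' Estimates a per-pixel attenuation coefficient along each A-line with the
#' depth-resolved tail-sum estimator
#' \deqn{\hat\mu[i] = I[i] / (2 \Delta r \sum_{j > i} I[j]),}
#' which is exact for noiseless single-exponential decay up to discretization
#' and tail truncation. The estimate is clipped to [0, muMax], scaled to
#' [0, 1], gamma-adjusted (\code{x^gamma}) and rescaled to [0, 255]. The final
#' \code{attenuationWindow} samples of each A-line, where the truncated tail
#' makes the estimator blow up, are set to zero, as are pixels whose tail sum
#' is zero (e.g. an all-zero A-line).
#'
#' @param frame numeric matrix (radial samples x A-lines), linear (un-log-
#'   compressed) intensities.
#' @param radial_res_mm radial pixel size, mm.
#' @param cfg a \linkS4class{PreprocessConfig}.
#' @return Matrix of the same shape with values in [0, 255].
#' @export
attenuationChannel <- function(frame, radial_res_mm,
                               cfg = preprocessConfig()) {
  nr <- nrow(frame)
  # tail[i] = sum_{j > i} I[j], per column
  csum <- apply(frame, 2, cumsum)
  tail_sum <- sweep(-csum, 2, csum[nr, ], "+")
  mu <- matrix(0, nr, ncol(frame))
  ok <- tail_sum > 0
  mu[ok] <- frame[ok] / (2 * radial_res_mm * tail_sum[ok])
  mu <- pmin(pmax(mu, 0), cfg@muMax)
  if (cfg@attenuationWindow > 0L) {
    w <- min(cfg@attenuationWindow, nr)
    mu[(nr - w + 1L):nr, ] <- 0
  }
  (mu / cfg@muMax)^cfg@gamma * 255
}

#' Raw attenuation estimate (mm^-1)
#'
#' The tail-sum estimator of \code{\link{attenuationChannel}} without
#' clipping, gamma adjustment or rescaling; used for physical checks.
#'
#' @inheritParams attenuationChannel
#' @return Matrix of attenuation estimates in mm^-1 (0 where the tail sum
#'   vanishes).
#' @export
attenuationEstimate <- function(frame, radial_res_mm) {
  nr <- nrow(frame)
  csum <- apply(as.matrix(frame), 2, cumsum)
  tail_sum <- sweep(-csum, 2, csum[nr, ], "+")
  mu <- matrix(0, nr, ncol(as.matrix(frame)))
  ok <- tail_sum > 0
  mu[ok] <- as.matrix(frame)[ok] / (2 * radial_res_mm * tail_sum[ok])
  mu
}

#' Normalize channels to [-1, 1]
#'
#' The exact affine map (x - 127.5) / 127.5 applied to values on the 0--255
#' scale; its inverse is \code{denormalizeChannels}.
#'
#' @param x numeric array/matrix with values in [0, 255].
#' @return Same shape, values in [-1, 1].
#' @export
normalizeChannels <- function(x) {
  if (min(x) < 0 || max(x) > 255)
    stop("normalizeChannels expects values in [0, 255]")
  (x - 127.5) / 127.5
}

#' @rdname normalizeChannels
#' @export
denormalizeChannels <- function(x) {
  if (min(x) < -1 || max(x) > 1)
    stop("denormalizeChannels expects values in [-1, 1]")
  x * 127.5 + 127.5
}

#' Preprocess one polar frame into the two-channel network tensor
#'
#' Channel 1 is the (optionally log-compressed) intensity; channel 2 is the
#' gamma-adjusted attenuation channel, estimated on the linear intensities.
#' Both are normalized to [-1, 1].
#'
#' @param frame numeric matrix (radial x angular), intensities in [0, 255].
#' @param radial_res_mm radial pixel size, mm.
#' @param cfg a \linkS4class{PreprocessConfig}.
#' @return Numeric array (radial x angular x 2) in [-1, 1].
#' @export
preprocessFrame <- function(frame, radial_res_mm, cfg = preprocessConfig()) {
  att <- attenuationChannel(frame, radial_res_mm, cfg)
  ch1 <- if (cfg@logCompress) logPolar(frame) else frame
  out <- array(0, dim = c(dim(frame), 2L))
  out[, , 1] <- normalizeChannels(ch1)
  out[, , 2] <- normalizeChannels(att)
  out
}

#' Preprocess every frame of a pullback
#'
#' @param pullback a \linkS4class{PullbackImage}.
#' @param cfg a \linkS4class{PreprocessConfig}.
#' @return List of (radial x angular x 2) arrays, one per frame.
#' @export
preprocessPullback <- function(pullback, cfg = preprocessConfig()) {
  lapply(seq_len(nFrames(pullback)), function(k)
    preprocessFrame(getFrame(pullback, k), radialRes(pullback), cfg))
}
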