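#' PhantomConfig: parameters of the synthetic polar OCT phantom
#'
#' Describes the geometry, optics and noise of a synthetic pullback: frame
#' grid, calibration, lumen shape, plaque inclusions, per-tissue attenuation
#' coefficients and interface reflectivities, speckle statistics, guidewire
#' placement, and the seed that makes generation fully reproducible.
#'
#' @slot nFrames,nALines,nSamples frame count, angular samples per frame and
#'   radial samples per A-line. \code{nALines} and \code{nSamples} must be
#'   divisible by 16 (the segmenter downsamples four times by a factor 2).
#' @slot radialResMm,frameSpacingMm calibration, mm per radial pixel and mm
#'   between frames.
#' @slot lumenRadiusMm,lumenVariationMm mean lumen radius and amplitude of
#'   its smooth angular variation, mm.
#' @slot plaqueSpecs data.frame with one plaque per row: \code{class}
#'   (\code{"calcium"}, \code{"fibrous"} or \code{"lipid"}), \code{arc_deg}
#'   in (0, 360], \code{thickness_mm}, \code{start_frame} (1-based),
#'   \code{n_frames}, and optionally \code{theta_start_deg} (NA draws it at
#'   random) and \code{depth_offset_mm} (radial gap between the lumen
#'   boundary band and the plaque, default 0).
#' @slot speckleShape shape of the multiplicative gamma speckle (mean 1);
#'   larger is smoother.
#' @slot tissueMu named attenuation coefficients, mm^-1, for
#'   \code{wall_tissue}, \code{calcium}, \code{fibrous}, \code{lipid}.
#'   Lipid attenuates strongly, calcium weakly.
#' @slot tissueReflectivity named entrance reflectivities in (0, 1] on the
#'   255 intensity scale: fibrous is signal-rich, calcium signal-poor.
#' @slot guidewire logical, render a guidewire with its radial shadow.
#' @slot guidewireThetaDeg guidewire azimuth; NA draws it at random.
#' @slot guidewireWidthDeg angular width of the guidewire arc.
#' @slot catheterRadiusMm outer radius of the imaging catheter.
#' @slot boundaryMm thickness of the bright lumen-boundary band.
#' @slot penetrationMm labelled tissue depth beyond the lumen boundary;
#'   deeper pixels are labelled background.
#' @slot lipidDiffusePx radial box-smoothing width (pixels) applied to lipid
#'   reflectivity profiles to give lipid its diffuse border.
#' @slot seed integer seed fixing all randomness.
#' @aliases PhantomConfig-class
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(nFrames = "integer", nALines = "integer",
                 nSamples = "integer", radialResMm = "numeric",
                 frameSpacingMm = "numeric", lumenRadiusMm = "numeric",
                 lumenVariationMm = "numeric", plaqueSpecs = "data.frame",
                 speckleShape = "numeric", tissueMu = "numeric",
                 tissueReflectivity = "numeric", guidewire = "logical",
                 guidewireThetaDeg = "numeric", guidewireWidthDeg = "numeric",
                 catheterRadiusMm = "numeric", boundaryMm = "numeric",
                 penetrationMm = "numeric", lipidDiffusePx = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (object@nALines %% 16L != 0L || object@nSamples %% 16L != 0L)
      return("nALines and nSamples must be divisible by 16")
    if (object@nFrames < 1L) return("nFrames must be >= 1")
    if (object@radialResMm <= 0 || object@frameSpacingMm <= 0)
      return("calibration must be strictly positive")
    if (any(object@tissueMu <= 0))
      return("all attenuation coefficients must be > 0")
    ps <- object@plaqueSpecs
    if (nrow(ps)) {
      if (!all(ps$class %in% c("calcium", "fibrous", "lipid")))
        return("plaque class must be calcium, fibrous or lipid")
      if (any(ps$arc_deg <= 0 | ps$arc_deg > 360))
        return("plaque arcs must lie in (0, 360]")
      if (any(ps$thickness_mm <= 0))
        return("plaque thickness must be > 0")
      depth_mm <- object@nSamples * object@radialResMm
      if (any(ps$thickness_mm >= depth_mm))
        return("plaque thickness must be smaller than the imaging depth")
    }
    if (object@speckleShape <= 0) return("speckleShape must be > 0")
    TRUE
  })

#' Build a PhantomConfig
#'
#' Defaults render a 512 x 480-pixel polar frame (0.01 mm radial pixels,
#' 5.12 mm imaging depth) at 0.2 mm frame spacing, i.e. five frames per mm
#' of pullback.
#'
#' @param n_frames,n_alines,n_samples grid dimensions (angular and radial
#'   sizes must be divisible by 16).
#' @param radial_res_mm,frame_spacing_mm calibration in mm.
#' @param lumen_radius_mm,lumen_variation_mm lumen geometry in mm.
#' @param plaque_specs data.frame of plaque inclusions (see
#'   \linkS4class{PhantomConfig}); \code{plaqueSpec()} builds rows.
#' @param speckle_shape gamma shape of the multiplicative speckle.
#' @param tissue_mu named attenuation coefficients (mm^-1).
#' @param tissue_reflectivity named entrance reflectivities.
#' @param guidewire,guidewire_theta_deg,guidewire_width_deg guidewire
#'   rendering controls.
#' @param catheter_radius_mm,boundary_mm,penetration_mm,lipid_diffuse_px
#'   structural parameters (see class documentation).
#' @param seed integer seed.
#' @return A \linkS4class{PhantomConfig}.
#' @examples
#' cfg <- phantomConfig(n_frames = 2, n_samples = 128, n_alines = 128,
#'                      radial_res_mm = 0.04, seed = 1)
#' @export
phantomConfig <- function(n_frames = 20L, n_alines = 480L, n_samples = 512L,
                          radial_res_mm = 0.01, frame_spacing_mm = 0.2,
                          lumen_radius_mm = 1.4, lumen_variation_mm = 0.15,
                          plaque_specs = emptyPlaqueSpecs(),
                          speckle_shape = 4,
                          tissue_mu = c(wall_tissue = 2.2, calcium = 1.0,
                                        fibrous = 1.8, lipid = 6.0),
                          tissue_reflectivity = c(wall_tissue = 0.75,
                                                  calcium = 0.35,
                                                  fibrous = 1.0,
                                                  lipid = 0.55),
                          guidewire = TRUE, guidewire_theta_deg = NA_real_,
                          guidewire_width_deg = 12,
                          catheter_radius_mm = 0.45, boundary_mm = 0.03,
                          penetration_mm = 2.0, lipid_diffuse_px = 7L,
                          seed = 1L) {
  new("PhantomConfig", nFrames = as.integer(n_frames),
      nALines = as.integer(n_alines), nSamples = as.integer(n_samples),
      radialResMm = radial_res_mm, frameSpacingMm = frame_spacing_mm,
      lumenRadiusMm = lumen_radius_mm, lumenVariationMm = lumen_variation_mm,
      plaqueSpecs = .normalizePlaqueSpecs(plaque_specs),
      speckleShape = speckle_shape, tissueMu = tissue_mu,
      tissueReflectivity = tissue_reflectivity, guidewire = guidewire,
      guidewireThetaDeg = guidewire_theta_deg,
      guidewireWidthDeg = guidewire_width_deg,
      catheterRadiusMm = catheter_radius_mm, boundaryMm = boundary_mm,
      penetrationMm = penetration_mm,
      lipidDiffusePx = as.integer(lipid_diffuse_px), seed = as.integer(seed))
}

#' @rdname phantomConfig
#' @export
emptyPlaqueSpecs <- function() {
  data.frame(class = character(), arc_deg = numeric(),
             thickness_mm = numeric(), start_frame = integer(),
             n_frames = integer(), theta_start_deg = numeric(),
             depth_offset_mm = numeric(), stringsAsFactors = FALSE)
}

#' @rdname phantomConfig
#' @param class,arc_deg,thickness_mm,start_frame,n_frames_plaque,
#'   theta_start_deg,depth_offset_mm one plaque inclusion.
#' @export
plaqueSpec <- function(class, arc_deg, thickness_mm, start_frame = 1L,
                       n_frames_plaque = 1L, theta_start_deg = NA_real_,
                       depth_offset_mm = 0) {
  data.frame(class = class, arc_deg = arc_deg, thickness_mm = thickness_mm,
             start_frame = as.integer(start_frame),
             n_frames = as.integer(n_frames_plaque),
             theta_start_deg = theta_start_deg,
             depth_offset_mm = depth_offset_mm, stringsAsFactors = FALSE)
}

.normalizePlaqueSpecs <- function(ps) {
  if (is.null(ps) || nrow(ps) == 0L) return(emptyPlaqueSpecs())
  if (is.null(ps$theta_start_deg)) ps$theta_start_deg <- NA_real_
  if (is.null(ps$depth_offset_mm)) ps$depth_offset_mm <- 0
  ps
}

#' Mean reflected intensity at depth for a tissue class
#'
#' Round-trip exponential decay model: the mean (speckle-free) intensity of a
#' tissue at optical depth \code{depth_mm} below its entrance interface is
#' \code{I0 * exp(-2 * mu * depth)}, with \code{I0 = 255 * reflectivity} and
#' \code{mu} the class attenuation coefficient. Strictly decreasing in depth.
#'
#' @param class one of \code{"wall_tissue"}, \code{"calcium"},
#'   \code{"fibrous"}, \code{"lipid"}.
#' @param depth_mm depth(s) below the tissue entrance, mm, >= 0.
#' @param config a \linkS4class{PhantomConfig} supplying \code{mu} and
#'   reflectivity.
#' @return Numeric intensity (0--255 scale), same length as \code{depth_mm}.
#' @examples
#' cfg <- phantomConfig()
#' attenuationProfile("calcium", c(0, 0.5, 1), cfg)
#' @export
attenuationProfile <- function(class, depth_mm, config) {
  if (!class %in% names(config@tissueMu))
    stop("unknown tissue class: ", class)
  if (any(depth_mm < 0)) stop("depth_mm must be >= 0")
  i0 <- 255 * config@tissueReflectivity[[class]]
  i0 * exp(-2 * config@tissueMu[[class]] * depth_mm)
}

# Columns (1-based) whose bin-centre angle falls in [theta0, theta0 + arc),
# wrapping across 0/360.
.arcColumns <- function(theta0, arc_deg, n_alines) {
  theta <- (seq_len(n_alines) - 1) * 360 / n_alines
  d <- (theta - theta0) %% 360
  which(d < arc_deg - 1e-9)
}

#' Generate a synthetic polar OCT pullback with ground-truth labels
#'
#' Builds each frame as a per-A-line mean intensity profile — near-zero lumen,
#' a bright lumen-boundary band, and beyond it tissue decaying as
#' \code{I0 * exp(-2 mu depth)} with class-specific \code{mu} and entrance
#' reflectivity — multiplied by seeded gamma speckle. Plaque inclusions,
#' the catheter ring, and a guidewire arc with a zeroed radial shadow are
#' rendered and recorded per pixel in the paired label map. Output is
#' bit-reproducible for a fixed seed.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return A list with elements \code{image} (\linkS4class{PullbackImage})
#'   and \code{labels} (\linkS4class{LabelMap}).
#' @examples
#' cfg <- phantomConfig(n_frames = 1, n_samples = 128, n_alines = 128,
#'                      radial_res_mm = 0.04, seed = 7)
#' pb <- generatePullback(cfg)
#' pb$image
#' @export
generatePullback <- function(config) {
  validObject(config)
  nr <- config@nSamples; na <- config@nALines; nf <- config@nFrames
  res <- config@radialResMm
  depth_mm <- nr * res
  r_mm <- (seq_len(nr) - 0.5) * res
  theta <- (seq_len(na) - 1) * 360 / na
  cls <- octClassNames()
  code <- stats::setNames(seq_along(cls) - 1L, cls)

  ps <- config@plaqueSpecs
  # reject inclusions that would leave the imaging window
  if (nrow(ps)) {
    reach <- config@lumenRadiusMm + config@lumenVariationMm +
      config@boundaryMm + ps$depth_offset_mm + ps$thickness_mm
    if (any(reach > depth_mm))
      stop("plaque radial extent exceeds the imaging depth (",
           signif(depth_mm, 4), " mm)")
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config@seed)

  # per-pullback lumen shape harmonics and guidewire azimuth
  ph <- stats::runif(2, 0, 2 * pi)
  amp <- stats::runif(2, 0.5, 1)
  gw_theta <- if (is.na(config@guidewireThetaDeg))
    stats::runif(1, 0, 360) else config@guidewireThetaDeg
  th_start <- ps$theta_start_deg
  if (nrow(ps))
    th_start[is.na(th_start)] <- stats::runif(sum(is.na(th_start)), 0, 360)

  img <- array(0, dim = c(nr, na, nf))
  lab <- array(code[["background"]], dim = c(nr, na, nf))
  trad <- theta * pi / 180
  mu <- config@tissueMu
  refl <- config@tissueReflectivity
  cat_px <- max(1L, round(config@catheterRadiusMm / res))
  bnd_px <- max(1L, round(config@boundaryMm / res))

  for (k in seq_len(nf)) {
    drift <- stats::rnorm(1, 0, 0.02)
    r_lum <- config@lumenRadiusMm + drift + config@lumenVariationMm *
      (amp[1] * sin(trad + ph[1]) + 0.5 * amp[2] * sin(2 * trad + ph[2]))
    r_lum <- pmax(r_lum, config@catheterRadiusMm + 0.2)
    lum_px <- pmin(pmax(round(r_lum / res), cat_px + 2L), nr - bnd_px - 1L)

    labf <- matrix(code[["background"]], nr, na)
    # per-column class bands, innermost first
    reflp <- matrix(0, nr, na)   # entrance reflectivity profile
    mup <- matrix(mu[["wall_tissue"]], nr, na)
    pen_px <- round(config@penetrationMm / res)
    for (j in seq_len(na)) {
      lp <- lum_px[j]
      labf[seq_len(cat_px), j] <- code[["catheter"]]
      labf[(cat_px + 1L):lp, j] <- code[["lumen"]]
      b0 <- lp + 1L; b1 <- min(lp + bnd_px, nr)
      labf[b0:b1, j] <- code[["lumen_boundary"]]
      w1 <- min(b1 + pen_px, nr)
      if (b1 < nr) labf[(b1 + 1L):w1, j] <- code[["wall_tissue"]]
      reflp[b0:nr, j] <- refl[["wall_tissue"]]
    }

    # plaque inclusions active on this frame
    if (nrow(ps)) for (p in seq_len(nrow(ps))) {
      if (k < ps$start_frame[p] || k >= ps$start_frame[p] + ps$n_frames[p])
        next
      cols <- .arcColumns(th_start[p], ps$arc_deg[p], na)
      off_px <- round(ps$depth_offset_mm[p] / res)
      thick_px <- max(1L, round(ps$thickness_mm[p] / res))
      pcls <- ps$class[p]
      for (j in cols) {
        r0 <- lum_px[j] + bnd_px + off_px + 1L
        r1 <- min(r0 + thick_px - 1L, nr)
        if (r0 > nr) next
        labf[r0:r1, j] <- code[[pcls]]
        reflp[r0:r1, j] <- refl[[pcls]]
        mup[r0:r1, j] <- mu[[pcls]]
      }
      if (pcls == "lipid" && config@lipidDiffusePx > 1L) {
        w <- config@lipidDiffusePx
        for (j in cols) {
          sm <- stats::filter(reflp[, j], rep(1 / w, w), sides = 2)
          keep <- is.na(sm)
          sm[keep] <- reflp[keep, j]
          reflp[, j] <- as.numeric(sm)
        }
      }
    }

    # mean intensity: entrance reflectivity attenuated by the cumulative
    # round-trip optical depth below the lumen boundary
    meanf <- matrix(0, nr, na)
    for (j in seq_len(na)) {
      lp <- lum_px[j]
      tau <- cumsum(mup[, j]) * res
      entry <- tau[min(lp + 1L, nr)]
      beyond <- (lp + 1L):nr
      meanf[beyond, j] <- 255 * reflp[beyond, j] *
        exp(-2 * (tau[beyond] - entry))
      meanf[(lp + 1L):min(lp + bnd_px, nr), j] <- 220   # bright interface
      meanf[(cat_px + 1L):lp, j] <- 2                    # cleared lumen
      meanf[seq_len(cat_px), j] <- 6
      if (cat_px >= 3L) meanf[(cat_px - 2L):cat_px, j] <- 180  # sheath ring
    }

    # guidewire arc and its radial shadow override everything distal
    if (config@guidewire) {
      gcols <- .arcColumns((gw_theta - config@guidewireWidthDeg / 2) %% 360,
                           config@guidewireWidthDeg, na)
      g0 <- cat_px + 3L
      g1 <- min(g0 + max(2L, round(0.3 / res)) - 1L, nr)
      for (j in gcols) {
        labf[g0:g1, j] <- code[["guidewire"]]
        meanf[g0:g1, j] <- 235
        if (g1 < nr) {
          labf[(g1 + 1L):nr, j] <- code[["guidewire_shadow"]]
          meanf[(g1 + 1L):nr, j] <- 0
        }
      }
    }

    speckle <- matrix(stats::rgamma(nr * na, shape = config@speckleShape,
                                    rate = config@speckleShape), nr, na)
    img[, , k] <- pmin(pmax(meanf * speckle, 0), 255)
    lab[, , k] <- labf
  }

  list(image = PullbackImage(img, res, config@frameSpacingMm),
       labels = LabelMap(lab))
}

#' Generate a reduced-scale phantom training corpus
#'
#' Builds a set of synthetic pullbacks with randomized lumen geometry and
#' plaque content (one to three inclusions per pullback, mixed calcium /
#' fibrous / lipid, arcs 40--220 degrees, thickness 0.3--1.0 mm, random
#' azimuth and frame span), preprocesses every frame into the two-channel
#' network tensor, and pairs it with its ground-truth labels. Each sample
#' carries its pullback identifier so training can enforce a leakage-free
#' pullback-level split. Defaults target a desk-scale benchmark: 64 x 128
#' pixel frames at 0.04 mm radial resolution (2.56 mm imaging depth).
#'
#' @param n_pullbacks number of synthetic pullbacks.
#' @param frames_per_pullback frames in each.
#' @param n_samples,n_alines,radial_res_mm frame grid and calibration.
#' @param pre a \linkS4class{PreprocessConfig}.
#' @param augment an optional \linkS4class{AugmentConfig} applied to every
#'   frame before preprocessing (NULL for none).
#' @param seed integer seed.
#' @return List: \code{samples} (each with \code{x}, \code{y},
#'   \code{pullback}), \code{pullback_ids}.
#' @export
phantomTrainingSet <- function(n_pullbacks = 10L, frames_per_pullback = 20L,
                               n_samples = 64L, n_alines = 128L,
                               radial_res_mm = 0.04,
                               pre = preprocessConfig(),
                               augment = NULL, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  classes <- c("calcium", "fibrous", "lipid")
  samples <- list()
  for (p in seq_len(n_pullbacks)) {
    npl <- sample(1:3, 1)
    specs <- do.call(rbind, lapply(seq_len(npl), function(i) {
      sf <- sample(seq_len(max(1L, frames_per_pullback - 4L)), 1)
      plaqueSpec(sample(classes, 1), stats::runif(1, 40, 220),
                 stats::runif(1, 0.3, 1.0), start_frame = sf,
                 n_frames_plaque = sample(3:min(12, frames_per_pullback - sf + 1L), 1),
                 theta_start_deg = stats::runif(1, 0, 360))
    }))
    cfg <- phantomConfig(
      n_frames = frames_per_pullback, n_alines = n_alines,
      n_samples = n_samples, radial_res_mm = radial_res_mm,
      lumen_radius_mm = stats::runif(1, 0.85, 1.1),
      lumen_variation_mm = 0.08, plaque_specs = specs,
      penetration_mm = 1.2, seed = seed + 1000L * p)
    pb <- generatePullback(cfg)
    for (k in seq_len(frames_per_pullback)) {
      fr <- getFrame(pb$image, k)
      lb <- getLabelFrame(pb$labels, k)
      if (!is.null(augment)) {
        a <- augmentFrame(fr, lb, augment, draw = p * 1000L + k)
        fr <- a$image; lb <- a$labels
      }
      samples[[length(samples) + 1L]] <- list(
        x = preprocessFrame(fr, radial_res_mm, pre), y = lb, pullback = p)
    }
  }
  list(samples = samples, pullback_ids = seq_len(n_pullbacks))
}
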