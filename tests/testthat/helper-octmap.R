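# shared fixtures: small, fast phantom configurations built in code

# 128 x 128 px frame at 0.04 mm/px (5.12 mm depth), fixed guidewire azimuth
# so that plaques placed in [90, 330) never touch it
tinyPhantom <- function(plaques = emptyPlaqueSpecs(), n_frames = 1L,
                        seed = 1L, lumen = 1.2, variation = 0, ...) {
  phantomConfig(n_frames = n_frames, n_samples = 128L, n_alines = 128L,
                radial_res_mm = 0.04, lumen_radius_mm = lumen,
                lumen_variation_mm = variation, plaque_specs = plaques,
                guidewire_theta_deg = 30, seed = seed, ...)
}

# a bare label frame (all wall tissue) to paint masks onto
blankLabels <- function(nr = 64L, na = 120L) {
  matrix(6L, nr, na)
}

# paint an annular sector of class `cls` onto a label frame; theta half-open
# in degrees, rows in [r0, r1]
paintSector <- function(lab, theta0, arc, r0, r1, cls = 7L) {
  na <- ncol(lab)
  theta <- (seq_len(na) - 1) * 360 / na
  cols <- which(((theta - theta0) %% 360) < arc - 1e-9)
  lab[r0:r1, cols] <- cls
  lab
}
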