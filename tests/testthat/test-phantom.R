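test_that("generation is bit-identical for a fixed seed", {
  cfg <- tinyPhantom(plaqueSpec("calcium", 90, 0.8, theta_start_deg = 120),
                     n_frames = 2L, seed = 42, variation = 0.1)
  a <- generatePullback(cfg)
  b <- generatePullback(cfg)
  expect_identical(frames(a$image), frames(b$image))
  expect_identical(labelArray(a$labels), labelArray(b$labels))
})

test_that("a plaque-free phantom contains only structural classes", {
  pb <- generatePullback(tinyPhantom(n_frames = 2L, variation = 0.1))
  present <- sort(unique(as.integer(labelArray(pb$labels))))
  structural <- c(0L, 1L, 2L, 3L, 4L, 5L, 6L)  # background .. wall
  expect_true(all(present %in% structural))
  expect_false(any(octPlaqueClasses() %in% present))
})

test_that("calcium pixel count matches the analytic sector area", {
  # constant lumen radius makes the annular sector exactly constructible:
  # oracle = (angular bins covered) x (radial pixels covered), summed
  # directly over an independently painted mask
  cfg <- tinyPhantom(plaqueSpec("calcium", 90, 1.0, theta_start_deg = 180))
  pb <- generatePullback(cfg)
  lab <- getLabelFrame(pb$labels, 1)
  n_cols <- round(90 / 360 * 128)
  n_rows <- round(1.0 / 0.04)
  oracle_mask <- paintSector(matrix(0L, 128, 128), 180, 90, 1, n_rows)
  expect_equal(sum(oracle_mask == 7L), n_cols * n_rows)
  got <- sum(lab == 7L)
  expect_lt(abs(got - n_cols * n_rows) / (n_cols * n_rows), 0.02)
})

test_that("per-class areas scale with the requested arc", {
  for (arc in c(45, 180, 360)) {
    cfg <- tinyPhantom(plaqueSpec("fibrous", arc, 0.6, theta_start_deg = 0),
                       guidewire = FALSE)
    lab <- getLabelFrame(generatePullback(cfg)$labels, 1)
    expected <- round(arc / 360 * 128) * round(0.6 / 0.04)
    expect_lt(abs(sum(lab == 8L) - expected) / expected, 0.02)
  }
})

test_that("attenuationProfile follows round-trip exponential decay", {
  cfg <- tinyPhantom()
  i0 <- attenuationProfile("calcium", 0, cfg)
  expect_equal(i0, 255 * cfg@tissueReflectivity[["calcium"]])
  # half-life identity: mu = 2 gives I0/2 at depth ln(2)/4
  cfg2 <- phantomConfig(tissue_mu = c(wall_tissue = 2, calcium = 2,
                                      fibrous = 2, lipid = 2))
  expect_equal(attenuationProfile("fibrous", log(2) / 4, cfg2),
               attenuationProfile("fibrous", 0, cfg2) / 2)
  # strictly decreasing in depth
  d <- seq(0, 2, by = 0.1)
  expect_true(all(diff(attenuationProfile("lipid", d, cfg)) < 0))
  # lipid attenuates faster than calcium (equal reflectivity config)
  cfgr <- phantomConfig(tissue_reflectivity = c(wall_tissue = 1, calcium = 1,
                                                fibrous = 1, lipid = 1))
  expect_lt(attenuationProfile("lipid", 0.5, cfgr),
            attenuationProfile("calcium", 0.5, cfgr))
  expect_error(attenuationProfile("steel", 1, cfg), "unknown")
  expect_error(attenuationProfile("lipid", -1, cfg), ">= 0")
})

test_that("plaques deeper than the imaging window are rejected", {
  cfg <- tinyPhantom(plaqueSpec("calcium", 90, 4.5, theta_start_deg = 100))
  expect_error(generatePullback(cfg), "imaging depth")
  expect_error(phantomConfig(n_samples = 128, n_alines = 128,
                             radial_res_mm = 0.01,
                             plaque_specs = plaqueSpec("calcium", 90, 2)),
               "imaging depth")
})

test_that("lumen is dark and the fibrous wall is signal-rich", {
  pb <- generatePullback(tinyPhantom(n_frames = 1L, variation = 0.1,
                                     seed = 3))
  img <- getFrame(pb$image, 1)
  lab <- getLabelFrame(pb$labels, 1)
  expect_lt(mean(img[lab == 1L]), mean(img[lab == 6L]))
  expect_lt(mean(img[lab == 1L]), 10)
})

test_that("the guidewire casts a zero-intensity radial shadow", {
  pb <- generatePullback(tinyPhantom(seed = 9))
  img <- getFrame(pb$image, 1)
  lab <- getLabelFrame(pb$labels, 1)
  expect_true(any(lab == 5L))
  expect_equal(max(img[lab == 5L]), 0)
  expect_gt(mean(img[lab == 4L]), 100)   # guidewire itself is bright
})

test_that("configs violating the grid or optics invariants are rejected", {
  expect_error(phantomConfig(n_alines = 100), "divisible by 16")
  expect_error(phantomConfig(tissue_mu = c(wall_tissue = -1, calcium = 1,
                                           fibrous = 1, lipid = 1)), "> 0")
  expect_error(phantomConfig(
    plaque_specs = plaqueSpec("calcium", 400, 0.5)), "\\(0, 360]")
})

test_that("images respect the intensity range and finiteness contracts", {
  pb <- generatePullback(tinyPhantom(
    plaqueSpec("lipid", 120, 0.8, theta_start_deg = 200), seed = 17,
    variation = 0.1))
  f <- frames(pb$image)
  expect_true(all(is.finite(f)))
  expect_gte(min(f), 0)
  expect_lte(max(f), 255)
})
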