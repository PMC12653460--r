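test_that("an annular sector is measured exactly", {
  # 60 degrees starting at 30, radial rows 11..35 at 0.04 mm -> 1.0 mm
  lab <- paintSector(blankLabels(64, 120), 30, 60, 11, 35)
  p <- extractPlaques(lab, 0.04)
  expect_equal(nrow(p), 1L)
  expect_equal(p$arc_deg, 60)
  expect_equal(p$theta_start_deg, 30)
  expect_equal(p$min_thickness_mm, 1.0)
  expect_equal(p$max_thickness_mm, 1.0)
  expect_false(p$truncated)
})

test_that("plaques crossing the 0/360 seam are one component", {
  lab <- paintSector(blankLabels(64, 360), 350, 20, 10, 20)
  p <- extractPlaques(lab, 0.04)
  expect_equal(nrow(p), 1L)
  expect_equal(p$arc_deg, 20)
  expect_equal(p$theta_start_deg, 350)
  # oracle: rotate the mask 180 degrees away from the seam and re-measure
  rot <- lab[, c(181:360, 1:180)]
  q <- extractPlaques(rot, 0.04)
  expect_equal(q$arc_deg, p$arc_deg)
  expect_equal(q$min_thickness_mm, p$min_thickness_mm)
  expect_equal(q$max_thickness_mm, p$max_thickness_mm)
})

test_that("disjoint sectors and full annuli are counted correctly", {
  lab <- paintSector(blankLabels(), 0, 40, 5, 10)
  lab <- paintSector(lab, 180, 40, 5, 10)
  expect_equal(nrow(extractPlaques(lab, 0.04)), 2L)
  full <- paintSector(blankLabels(), 0, 360, 5, 10)
  p <- extractPlaques(full, 0.04)
  expect_equal(nrow(p), 1L)
  expect_equal(p$arc_deg, 360)
})

test_that("extraction is rotation-equivariant", {
  set.seed(11)
  lab0 <- paintSector(blankLabels(64, 120), 75, 84, 12, 30)
  base <- extractPlaques(lab0, 0.04)
  for (shift_cols in sample(1:119, 6)) {
    rot <- lab0[, c((shift_cols + 1):120, 1:shift_cols)]
    p <- extractPlaques(rot, 0.04)
    expect_equal(p$arc_deg, base$arc_deg)
    expect_equal(p$min_thickness_mm, base$min_thickness_mm)
    expect_equal(p$max_thickness_mm, base$max_thickness_mm)
  }
})

test_that("thickness is the per-A-line radial extent", {
  lab <- blankLabels(64, 120)
  lab <- paintSector(lab, 90, 30, 11, 20)   # 10 px = 0.4 mm
  lab <- paintSector(lab, 90, 15, 21, 30)   # half the arc thicker: 0.8 mm
  p <- extractPlaques(lab, 0.04)
  expect_equal(nrow(p), 1L)
  expect_equal(p$min_thickness_mm, 0.4)
  expect_equal(p$max_thickness_mm, 0.8)
})

test_that("truncation against signal voids is flagged", {
  lab <- paintSector(blankLabels(64, 120), 100, 40, 50, 64)  # touches edge
  expect_true(extractPlaques(lab, 0.04)$truncated)
  lab2 <- paintSector(blankLabels(64, 120), 100, 40, 30, 40)
  lab2[41:64, ] <- 5L                                        # shadow beyond
  expect_true(extractPlaques(lab2, 0.04)$truncated)
  lab3 <- paintSector(blankLabels(64, 120), 100, 40, 30, 40) # wall beyond
  expect_false(extractPlaques(lab3, 0.04)$truncated)
})

test_that("lesion length counts contiguous overlapping frames", {
  # 10 consecutive frames of the same sector at 0.2 mm spacing -> 2.0 mm
  mk <- function(frames, theta0 = 50) do.call(rbind, lapply(frames, function(k)
    data.frame(frame_index = k, arc_deg = 60, theta_start_deg = theta0,
               theta_end_deg = (theta0 + 60) %% 360, min_thickness_mm = 0.4,
               max_thickness_mm = 0.4, n_pixels = 100, truncated = FALSE)))
  expect_equal(lesionLength(mk(1:10), 20, "every_frame", 0.2), 2.0)
  expect_equal(lesionLength(mk(4), 20, "every_frame", 0.2), 0.2)
  # a gap splits the run
  expect_equal(lesionLength(mk(c(1:4, 8:15)), 20, "every_frame", 0.2),
               8 * 0.2)
  # angular overlap is required: alternating opposite sectors never chain
  alt <- rbind(mk(seq(1, 9, 2), 0), mk(seq(2, 10, 2), 180))
  expect_equal(lesionLength(alt, 10, "every_frame", 0.2), 0.2)
  expect_equal(lesionLength(mk(integer(0)), 10, "every_frame", 0.2), 0)
})

test_that("both length modes return multiples of their sampling step", {
  set.seed(21)
  for (rep in 1:5) {
    frames <- sort(sample(1:40, sample(5:20, 1)))
    pl <- do.call(rbind, lapply(frames, function(k)
      data.frame(frame_index = k, arc_deg = runif(1, 20, 120),
                 theta_start_deg = runif(1, 0, 360), theta_end_deg = 0,
                 min_thickness_mm = 0.3, max_thickness_mm = 0.5,
                 n_pixels = 10, truncated = FALSE)))
    le <- lesionLength(pl, 40, "every_frame", 0.2)
    li <- lesionLength(pl, 40, "interval_quadrant", 0.2, interval_mm = 1)
    expect_equal(le %% 0.2, 0, tolerance = 1e-9)
    expect_equal(li %% 1, 0, tolerance = 1e-9)
  }
})

test_that("frame sampling matches the 1 mm annotation convention", {
  expect_identical(sampleFrames(50, 0.2, 1), seq(1L, 50L, by = 5L))
  expect_length(sampleFrames(50, 0.2, 1), 10L)
  expect_identical(sampleFrames(10, 0.5, 0.5), 1:10)
  expect_length(sampleFrames(11, 0.2, 1), 3L)
  expect_error(sampleFrames(10, 0.5, 0.2), ">=")
})

test_that("the OCT-calcium score applies strict thresholds", {
  expect_identical(octCalciumScore(0.6, 200, 6), 4L)
  expect_identical(octCalciumScore(0.5, 180, 5), 0L)   # equality: no points
  expect_identical(octCalciumScore(0.75, 60, 2), 1L)
  expect_identical(octCalciumScore(0.4, 200, 3), 2L)   # arc only
  expect_identical(octCalciumScore(0.4, 90, 6), 1L)    # length only
  expect_error(octCalciumScore(-1, 90, 1), "nonnegative")
})

test_that("the score is monotone nondecreasing in each input", {
  th <- c(0, 0.3, 0.5, 0.5001, 0.8, 2)
  arc <- c(0, 90, 180, 180.5, 270, 360)
  len <- c(0, 2, 5, 5.1, 8, 40)
  grid <- expand.grid(t = th, a = arc, l = len)
  s <- mapply(octCalciumScore, grid$t, grid$a, grid$l)
  dimg <- array(s, c(6, 6, 6))
  expect_true(all(apply(dimg, c(2, 3), diff) >= 0))
  expect_true(all(apply(dimg, c(1, 3), diff) >= 0))
  expect_true(all(apply(dimg, c(1, 2), diff) >= 0))
  expect_true(all(s %in% 0:4))
})

test_that("severity dichotomization splits at score 3", {
  expect_identical(dichotomize(0:4),
                   c("non-severe", "non-severe", "non-severe",
                     "severe", "severe"))
  expect_error(dichotomize(5), "0..4")
})

test_that("phantom quantification recovers the generating parameters", {
  # arc 120 at 128 A-lines = 42.66 bins -> generator rounds to whole bins;
  # recovery must land within one angular bin and one radial pixel
  binw <- 360 / 128
  cfg <- tinyPhantom(plaqueSpec("calcium", 120, 0.8, start_frame = 2,
                                n_frames_plaque = 5, theta_start_deg = 135),
                     n_frames = 10L, seed = 14)
  pb <- generatePullback(cfg)
  pl <- extractPlaquesStack(pb$labels, radialRes(pb$image))
  expect_equal(nrow(pl), 5L)
  expect_identical(unique(pl$frame_index), 2:6)
  expect_true(all(abs(pl$arc_deg - 120) <= binw))
  expect_true(all(abs(pl$max_thickness_mm - 0.8) <= 0.04))
  summ <- quantifyCalcium(pb$labels, radialRes(pb$image), 0.2)
  expect_equal(summ@lengthMm, 5 * 0.2)
  expect_identical(summ@score, 1L)       # 0.8 mm thick, arc < 180, 1 mm long
  expect_identical(summ@severity, "non-severe")
})

test_that("an empty pullback quantifies to a zero lesion", {
  pb <- generatePullback(tinyPhantom(n_frames = 2L))
  summ <- quantifyCalcium(pb$labels, 0.04, 0.2)
  expect_identical(summ@score, 0L)
  expect_identical(summ@nPlaques, 0L)
  expect_equal(summ@lengthMm, 0)
})

test_that("components agree with an independent labeller off the seam", {
  skip_if_not_installed("EBImage")
  # solid sectors away from theta = 0/360, where 4- and 8-connectivity and
  # seam handling cannot differ: both labellers must count identically
  lab <- blankLabels(48, 96)
  lab <- paintSector(lab, 40, 30, 5, 15)
  lab <- paintSector(lab, 120, 45, 20, 40)
  lab <- paintSector(lab, 240, 25, 10, 22)
  n_own <- nrow(extractPlaques(lab, 0.04))
  eb <- EBImage::bwlabel(lab == 7L)
  expect_identical(n_own, 3L)
  expect_equal(max(eb), 3)
})
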