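test_that("the network maps (H, W, 2) to per-pixel class probabilities", {
  net <- buildNetwork(netConfig(), seed = 2)
  x <- array(runif(64 * 96 * 2, -1, 1), c(64, 96, 2))
  p <- predictProbs(net, x)
  expect_identical(dim(p), c(64L, 96L, 10L))
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-5)
  expect_gte(min(p), 0)
  expect_error(predictProbs(net, array(0, c(60, 96, 2))), "divisible by 16")
  expect_error(predictProbs(net, array(0, c(64, 96, 3))), "channels")
})

test_that("encoder filters start at 16 and double per block", {
  cfg <- netConfig()
  layout <- octmap:::.convLayout(cfg)
  enc <- layout$cout[seq_len(2 * cfg@depth)]
  expect_identical(enc[c(1, 3, 5, 7)], c(16, 32, 64, 128))
  expect_identical(enc[c(2, 4, 6, 8)], c(16, 32, 64, 128))
})

test_that("parameter count equals the layer-enumeration oracle", {
  # independent enumeration from the architecture definition: encoder pairs
  # (2 -> f1, f1 -> f1, f1 -> f2, ...), bottleneck pair, decoder (up, merge)
  # pairs from the deepest level, 1x1 head; (k^2 cin + 1) cout each
  countOracle <- function(base, depth, in_ch = 2, n_cls = 10) {
    f <- base * 2^(0:(depth - 1))
    total <- 0; cin <- in_ch
    for (k in seq_len(depth)) {
      total <- total + (9 * cin + 1) * f[k] + (9 * f[k] + 1) * f[k]
      cin <- f[k]
    }
    fb <- base * 2^depth
    total <- total + (9 * cin + 1) * fb + (9 * fb + 1) * fb
    cin <- fb
    for (k in rev(seq_len(depth))) {
      total <- total + (9 * cin + 1) * f[k] + (9 * 2 * f[k] + 1) * f[k]
      cin <- f[k]
    }
    total + (cin + 1) * n_cls
  }
  for (cse in list(c(16, 4), c(8, 3), c(4, 2))) {
    net <- buildNetwork(netConfig(base_filters = cse[1], depth = cse[2]),
                        seed = 1)
    expect_identical(parameterCount(net), countOracle(cse[1], cse[2]))
  }
})

test_that("the loss matches a hand-rolled per-pixel oracle", {
  # brute-force R implementation, summed pixel by pixel
  lossOracle <- function(p, y, w, mix) {
    n <- length(y); C <- ncol(p); eps <- 1e-6
    ce <- 0
    for (i in seq_len(n)) ce <- ce - w[y[i] + 1] * log(p[i, y[i] + 1])
    ce <- ce / n
    dice <- 0
    for (c in seq_len(C)) {
      t <- as.numeric(y == c - 1)
      dice <- dice + w[c] * (2 * sum(p[, c] * t) + eps) /
        (sum(p[, c]) + sum(t) + eps)
    }
    mix * ce + (1 - mix) * (1 - dice / sum(w))
  }
  set.seed(53)
  for (rep in 1:5) {
    z <- matrix(rnorm(16 * 10), 16, 10)
    p <- exp(z) / rowSums(exp(z))
    y <- matrix(sample(0:9, 16, TRUE), 4, 4)
    w <- runif(10, 0.5, 2)
    mix <- runif(1)
    got <- segLoss(array(p, c(4, 4, 10)), y, w, mix)
    expect_equal(got$loss, lossOracle(p, as.integer(y), w, mix),
                 tolerance = 1e-6)
  }
})

test_that("the loss is zero iff the prediction is the one-hot target", {
  y <- matrix(sample(0:9, 64, TRUE), 8, 8)
  p <- array(0, c(8, 8, 10))
  for (cl in 0:9) p[, , cl + 1][y == cl] <- 1
  l <- segLoss(p, y)
  expect_lt(l$dice_term, 1e-6)
  expect_lt(l$loss, 1e-6)
  # uniform prediction: CE term is ln 10 per pixel
  pu <- array(0.1, c(8, 8, 10))
  expect_equal(segLoss(pu, y)$ce, log(10), tolerance = 1e-12)
  expect_gt(segLoss(pu, y)$loss, 0)
})

test_that("analytic gradients match central finite differences", {
  set.seed(59)
  cfg <- netConfig(in_channels = 2, n_classes = 4, base_filters = 3,
                   depth = 2, dropout_rate = 0)
  net <- buildNetwork(cfg, seed = 3)
  x <- array(runif(8 * 8 * 2, -1, 1), c(8, 8, 2))
  y <- matrix(sample(0:3, 64, TRUE), 8, 8)
  w <- c(1, 2, 0.5, 1)
  g <- octmap:::.cpp_unet_grad(x, y, net@weights, 2L, w, 0.6, 0, 1)
  lossAt <- function(wts)
    segLoss(octmap:::.cpp_unet_forward(x, wts, 2L), y, w, 0.6)$loss
  eps <- 1e-6
  for (li in seq_along(net@weights$W)) {
    i <- sample(length(net@weights$W[[li]]), 1)
    up <- net@weights; up$W[[li]][i] <- up$W[[li]][i] + eps
    dn <- net@weights; dn$W[[li]][i] <- dn$W[[li]][i] - eps
    num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
    expect_equal(g$dW[[li]][i], num, tolerance = 1e-4)
  }
})

test_that("a one-epoch run on four frames emits one history row", {
  ds <- phantomTrainingSet(n_pullbacks = 2, frames_per_pullback = 2,
                           n_samples = 32, n_alines = 64,
                           radial_res_mm = 0.08, seed = 3)
  fit <- trainSegNet(ds$samples, val_pullbacks = 2,
                     net_cfg = netConfig(base_filters = 4, depth = 2),
                     train_cfg = trainConfig(epochs = 1, batch_size = 2,
                                             seed = 5))
  expect_identical(nrow(fit$history), 1L)
  expect_true(all(c("epoch", "train_loss", "val_loss", "val_plaque_dice")
                  %in% names(fit$history)))
  expect_true(is(fit$net, "SegNet"))
})

test_that("pullback-level split leakage is an error, not a warning", {
  ds <- phantomTrainingSet(n_pullbacks = 2, frames_per_pullback = 1,
                           n_samples = 32, n_alines = 64,
                           radial_res_mm = 0.08, seed = 4)
  small <- netConfig(base_filters = 4, depth = 2)
  expect_error(trainSegNet(ds$samples, val_pullbacks = 2,
                           net_cfg = small, train_pullbacks = c(1, 2)),
               "both train and validation")
  expect_error(trainSegNet(ds$samples, val_pullbacks = c(1, 2),
                           net_cfg = small),
               "empty training split")
  expect_error(trainSegNet(ds$samples, val_pullbacks = integer(0),
                           net_cfg = small),
               "empty validation split")
})

test_that("training is deterministic and reduces the loss", {
  ds <- phantomTrainingSet(n_pullbacks = 3, frames_per_pullback = 4,
                           n_samples = 32, n_alines = 64,
                           radial_res_mm = 0.08, seed = 6)
  cfg <- netConfig(base_filters = 8, depth = 3)
  tc <- trainConfig(epochs = 8, batch_size = 4, seed = 11)
  f1 <- trainSegNet(ds$samples, val_pullbacks = 3, cfg, tc)
  f2 <- trainSegNet(ds$samples, val_pullbacks = 3, cfg, tc)
  expect_identical(f1$history$train_loss[1], f2$history$train_loss[1])
  expect_identical(f1$history, f2$history)
  expect_lt(f1$history$train_loss[8], f1$history$train_loss[1])
})

test_that("checkpoints round-trip through JSON exactly", {
  net <- buildNetwork(netConfig(base_filters = 4, depth = 2), seed = 13)
  path <- tempfile(fileext = ".json")
  saveCheckpoint(net, path)
  back <- loadCheckpoint(path)
  expect_identical(back@config@baseFilters, 4L)
  x <- array(runif(32 * 32 * 2, -1, 1), c(32, 32, 2))
  expect_equal(predictProbs(back, x), predictProbs(net, x),
               tolerance = 1e-15)
})
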