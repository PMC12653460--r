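#' NetConfig: UNet-like architecture settings
#'
#' The network consumes a two-channel polar tensor (log-compressed intensity
#' plus attenuation channel) and emits per-pixel probabilities over the ten
#' classes. The contracting path has \code{depth} convolutional blocks of two
#' 3x3 convolutions with ReLU, each followed by 2x2 max-pooling and dropout;
#' filters start at \code{baseFilters} and double per block (16, 32, 64, 128
#' at the defaults). The expanding path mirrors it with nearest-neighbour
#' upsampling followed by a 3x3 convolution and ReLU, a skip concatenation
#' (feature bridge) at each resolution, and a second 3x3 convolution; a 1x1
#' convolution and softmax produce the segmentation map.
#'
#' @slot inChannels input channels (2).
#' @slot nClasses output classes (10).
#' @slot baseFilters filters in the first block (16); block k uses
#'   \code{baseFilters * 2^k}.
#' @slot depth number of down/upsampling levels (4); input height and width
#'   must be divisible by \code{2^depth}.
#' @slot dropoutRate encoder dropout rate in [0, 1).
#' @slot upsampleMode \code{"nearest"} (nearest-neighbour + 3x3 convolution).
#' @aliases NetConfig-class
#' @exportClass NetConfig
setClass("NetConfig",
  representation(inChannels = "integer", nClasses = "integer",
                 baseFilters = "integer", depth = "integer",
                 dropoutRate = "numeric", upsampleMode = "character"),
  validity = function(object) {
    if (object@depth < 1L) return("depth must be >= 1")
    if (object@baseFilters < 1L) return("baseFilters must be >= 1")
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
      return("dropoutRate must lie in [0, 1)")
    if (!object@upsampleMode %in% "nearest")
      return("upsampleMode must be 'nearest'")
    TRUE
  })

#' @rdname NetConfig-class
#' @param in_channels,n_classes,base_filters,depth,dropout_rate,upsample_mode
#'   see the class slots.
#' @return \code{netConfig()} returns a \linkS4class{NetConfig}.
#' @export
netConfig <- function(in_channels = 2L, n_classes = 10L, base_filters = 16L,
                      depth = 4L, dropout_rate = 0.1,
                      upsample_mode = "nearest") {
  new("NetConfig", inChannels = as.integer(in_channels),
      nClasses = as.integer(n_classes),
      baseFilters = as.integer(base_filters), depth = as.integer(depth),
      dropoutRate = dropout_rate, upsampleMode = upsample_mode)
}

#' TrainConfig: optimization settings
#'
#' @slot epochs training epochs.
#' @slot batchSize frames per optimizer step (gradients averaged).
#' @slot learningRate Adam step size.
#' @slot lossWeights per-class loss weights, length nClasses; the three
#'   plaque morphologies are equally weighted by default.
#' @slot ceDiceMix mixing weight in [0, 1]:
#'   \code{mix * CE + (1 - mix) * (1 - softDice)}.
#' @slot seed integer seed fixing initialization, data order and dropout.
#' @slot checkpointMetric \code{"plaque_dice"} (mean soft Dice over plaque
#'   classes on validation, maximized) or \code{"val_loss"} (minimized).
#' @aliases TrainConfig-class
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", lossWeights = "numeric",
                 ceDiceMix = "numeric", seed = "integer",
                 checkpointMetric = "character"),
  validity = function(object) {
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (object@ceDiceMix < 0 || object@ceDiceMix > 1)
      return("ceDiceMix must lie in [0, 1]")
    if (any(object@lossWeights < 0))
      return("loss weights must be nonnegative")
    if (!object@checkpointMetric %in% c("plaque_dice", "val_loss"))
      return("checkpointMetric must be plaque_dice or val_loss")
    TRUE
  })

#' @rdname TrainConfig-class
#' @param epochs,batch_size,learning_rate,loss_weights,ce_dice_mix,seed,
#'   checkpoint_metric see the class slots.
#' @return \code{trainConfig()} returns a \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(epochs = 10L, batch_size = 4L, learning_rate = 1e-3,
                        loss_weights = rep(1, 10), ce_dice_mix = 0.5,
                        seed = 1L, checkpoint_metric = "plaque_dice") {
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batch_size), learningRate = learning_rate,
      lossWeights = loss_weights, ceDiceMix = ce_dice_mix,
      seed = as.integer(seed), checkpointMetric = checkpoint_metric)
}

#' SegNet: a UNet-like pixel segmenter with its weights
#'
#' @slot config the \linkS4class{NetConfig}.
#' @slot weights list with elements \code{W} (one \code{(k*k*cin) x cout}
#'   matrix per convolution, in layer order) and \code{b} (bias vectors).
#' @aliases SegNet-class
#' @exportClass SegNet
setClass("SegNet",
  representation(config = "NetConfig", weights = "list"))

setMethod("show", "SegNet", function(object) {
  cfg <- object@config
  f <- cfg@baseFilters * 2^(seq_len(cfg@depth) - 1)
  cat(sprintf("SegNet: %d -> %d channels, depth %d, encoder filters (%s)\n",
              cfg@inChannels, cfg@nClasses, cfg@depth,
              paste(f, collapse = ", ")))
  cat(sprintf("  %d convolutions, %d trainable parameters\n",
              length(object@weights$W), parameterCount(object)))
})

# (cin, cout, k) for every convolution, in the order the forward pass
# consumes weights: encoder pairs, bottleneck pair, decoder (up, merge)
# pairs from the deepest level up, then the 1x1 head
.convLayout <- function(cfg) {
  f <- cfg@baseFilters * 2^(seq_len(cfg@depth) - 1)
  rows <- list()
  cin <- cfg@inChannels
  for (k in seq_len(cfg@depth)) {
    rows[[length(rows) + 1L]] <- c(cin, f[k], 3)
    rows[[length(rows) + 1L]] <- c(f[k], f[k], 3)
    cin <- f[k]
  }
  fb <- cfg@baseFilters * 2^cfg@depth
  rows[[length(rows) + 1L]] <- c(cin, fb, 3)
  rows[[length(rows) + 1L]] <- c(fb, fb, 3)
  cin <- fb
  for (k in rev(seq_len(cfg@depth))) {
    rows[[length(rows) + 1L]] <- c(cin, f[k], 3)       # post-upsample conv
    rows[[length(rows) + 1L]] <- c(2 * f[k], f[k], 3)  # after skip concat
    cin <- f[k]
  }
  rows[[length(rows) + 1L]] <- c(cin, cfg@nClasses, 1)  # 1x1 head
  m <- do.call(rbind, rows)
  data.frame(cin = m[, 1], cout = m[, 2], k = m[, 3])
}

#' Build (initialize) a segmentation network
#'
#' He-normal initialization of every convolution, seeded for exact
#' reproducibility.
#'
#' @param cfg a \linkS4class{NetConfig}.
#' @param seed integer seed.
#' @return A \linkS4class{SegNet}.
#' @examples
#' net <- buildNetwork(netConfig(base_filters = 4, depth = 2), seed = 1)
#' parameterCount(net)
#' @export
buildNetwork <- function(cfg = netConfig(), seed = 1L) {
  validObject(cfg)
  layout <- .convLayout(cfg)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  W <- vector("list", nrow(layout)); b <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    fan_in <- layout$k[i]^2 * layout$cin[i]
    W[[i]] <- matrix(stats::rnorm(fan_in * layout$cout[i],
                                  sd = sqrt(2 / fan_in)),
                     fan_in, layout$cout[i])
    b[[i]] <- rep(0, layout$cout[i])
  }
  new("SegNet", config = cfg, weights = list(W = W, b = b))
}

#' Number of trainable parameters
#'
#' @param net a \linkS4class{SegNet}.
#' @return Total count of weight and bias elements.
#' @export
parameterCount <- function(net) {
  sum(vapply(net@weights$W, length, numeric(1))) +
    sum(vapply(net@weights$b, length, numeric(1)))
}

.checkSpatial <- function(net, x) {
  d <- dim(x)
  div <- 2^net@config@depth
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop("input height and width must be divisible by ", div)
  if (d[3] != net@config@inChannels)
    stop("input has ", d[3], " channels; network expects ",
         net@config@inChannels)
}

#' Per-pixel class probabilities for one preprocessed frame
#'
#' @param net a \linkS4class{SegNet}.
#' @param x numeric array (H x W x inChannels), H and W divisible by
#'   \code{2^depth}.
#' @return Array (H x W x nClasses); probabilities sum to 1 per pixel.
#' @export
predictProbs <- function(net, x) {
  .checkSpatial(net, x)
  cfg <- net@config
  .cpp_unet_forward(x, net@weights, cfg@depth)
}

#' Hard segmentation (argmax labels) for one preprocessed frame
#'
#' @inheritParams predictProbs
#' @return Integer matrix of 0-based class codes.
#' @export
segmentFrame <- function(net, x) {
  p <- predictProbs(net, x)
  matrix(max.col(matrix(p, ncol = dim(p)[3])) - 1L, dim(p)[1], dim(p)[2])
}

#' Segment every frame of a pullback
#'
#' Preprocesses each polar frame into the two-channel tensor and runs the
#' network; returns the argmax label map.
#'
#' @param net a \linkS4class{SegNet}.
#' @param pullback a \linkS4class{PullbackImage}.
#' @param pre a \linkS4class{PreprocessConfig}.
#' @return A \linkS4class{LabelMap} of predicted classes.
#' @export
segmentPullback <- function(net, pullback, pre = preprocessConfig()) {
  out <- array(0L, dim = dim(frames(pullback)))
  for (k in seq_len(nFrames(pullback))) {
    x <- preprocessFrame(getFrame(pullback, k), radialRes(pullback), pre)
    out[, , k] <- segmentFrame(net, x)
  }
  LabelMap(out)
}

#' Segmentation training objective
#'
#' Class-weighted mix of cross-entropy and soft-Dice:
#' \code{mix * CE + (1 - mix) * (1 - softDice)}. CE is the mean over pixels
#' of \code{w[y] * -log p[y]}; softDice is the loss-weight-averaged per-class
#' soft Dice \code{(2 sum(p t) + eps) / (sum p + sum t + eps)}. The loss is
#' nonnegative and vanishes exactly when the prediction equals the one-hot
#' target.
#'
#' @param probs probability array (H x W x C) or matrix (pixels x C).
#' @param target integer matrix/vector of 0-based class codes.
#' @param class_weights per-class weights (default: equal).
#' @param mix CE weight in [0, 1].
#' @return List: \code{loss}, \code{ce}, \code{dice_term}.
#' @export
segLoss <- function(probs, target, class_weights = NULL, mix = 0.5) {
  if (length(dim(probs)) == 3L) {
    nc <- dim(probs)[3]
    probs <- matrix(probs, ncol = nc)
  } else nc <- ncol(probs)
  if (is.null(class_weights)) class_weights <- rep(1, nc)
  y <- as.integer(target)
  if (length(y) != nrow(probs)) stop("target and probs shapes differ")
  if (any(y < 0L | y >= nc)) stop("target classes out of range")
  .cpp_unet_loss(probs, y, class_weights, mix)
}

.plaqueSoftDice <- function(acc) {
  # acc: list of per-class running (2*sum_pt, sum_p + sum_t)
  d <- (2 * acc$pt + 1e-6) / (acc$pq + 1e-6)
  mean(d[octPlaqueClasses() + 1L])
}

#' Train the segmenter on preprocessed frames
#'
#' Adam optimization of the CE + soft-Dice objective, with a strict
#' pullback-level train/validation split: every sample carries a pullback
#' identifier, and any identifier appearing in both splits is an error, so
#' validation frames always come from pullbacks the optimizer never saw.
#' Per-epoch training loss, validation loss and validation plaque Dice are
#' recorded, and the weights achieving the best checkpoint metric are
#' returned. A fixed seed fixes initialization, shuffling and dropout.
#'
#' @param samples list of training samples; each is a list with \code{x}
#'   (H x W x 2 preprocessed tensor), \code{y} (integer matrix of 0-based
#'   class codes) and \code{pullback} (identifier).
#' @param val_pullbacks identifiers held out for validation.
#' @param net_cfg a \linkS4class{NetConfig}.
#' @param train_cfg a \linkS4class{TrainConfig}.
#' @param train_pullbacks identifiers to train on; defaults to every
#'   pullback not in the validation set. Any overlap with
#'   \code{val_pullbacks} is an error.
#' @param verbose print per-epoch progress.
#' @return List: \code{net} (best-checkpoint \linkS4class{SegNet}),
#'   \code{history} (data.frame: epoch, train_loss, val_loss, val_plaque_dice),
#'   \code{best_epoch}.
#' @export
trainSegNet <- function(samples, val_pullbacks, net_cfg = netConfig(),
                        train_cfg = trainConfig(), train_pullbacks = NULL,
                        verbose = FALSE) {
  ids <- vapply(samples, function(s) as.character(s$pullback), character(1))
  val_ids <- as.character(val_pullbacks)
  tr_ids <- if (is.null(train_pullbacks)) setdiff(unique(ids), val_ids)
    else as.character(train_pullbacks)
  if (length(intersect(tr_ids, val_ids)))
    stop("pullback present in both train and validation splits: ",
         paste(intersect(tr_ids, val_ids), collapse = ", "))
  va_idx <- which(ids %in% val_ids)
  tr_idx <- which(ids %in% tr_ids)
  if (!length(va_idx)) stop("empty validation split")
  if (!length(tr_idx)) stop("empty training split")

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(train_cfg@seed)

  net <- buildNetwork(net_cfg, seed = train_cfg@seed)
  w <- net@weights
  mstate <- lapply(w$W, function(m) m * 0)
  vstate <- lapply(w$W, function(m) m * 0)
  mb <- lapply(w$b, function(m) m * 0)
  vb <- lapply(w$b, function(m) m * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  lr <- train_cfg@learningRate
  cw <- train_cfg@lossWeights
  mix <- train_cfg@ceDiceMix
  pc <- octPlaqueClasses()
  step <- 0L

  eval_val <- function(w) {
    netv <- new("SegNet", config = net_cfg, weights = w)
    tot <- 0; acc <- list(pt = rep(0, net_cfg@nClasses),
                          pq = rep(0, net_cfg@nClasses))
    for (i in va_idx) {
      p <- predictProbs(netv, samples[[i]]$x)
      l <- segLoss(p, samples[[i]]$y, cw, mix)
      tot <- tot + l$loss
      pm <- matrix(p, ncol = net_cfg@nClasses)
      y <- as.integer(samples[[i]]$y)
      for (cl in seq_len(net_cfg@nClasses) - 1L) {
        tcl <- y == cl
        acc$pt[cl + 1] <- acc$pt[cl + 1] + 2 * sum(pm[tcl, cl + 1])
        acc$pq[cl + 1] <- acc$pq[cl + 1] + sum(pm[, cl + 1]) + sum(tcl)
      }
    }
    list(loss = tot / length(va_idx), dice = .plaqueSoftDice(acc))
  }

  history <- data.frame()
  best <- list(metric = -Inf, w = w, epoch = 0L)
  for (ep in seq_len(train_cfg@epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0
    nb <- 0L
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + train_cfg@batchSize - 1L, length(ord))]
      i <- i + train_cfg@batchSize
      gW <- lapply(w$W, function(m) m * 0)
      gb <- lapply(w$b, function(m) m * 0)
      bl <- 0
      for (s in batch) {
        step <- step + 1L
        g <- .cpp_unet_grad(samples[[s]]$x,
                            matrix(as.integer(samples[[s]]$y),
                                   nrow(samples[[s]]$y)),
                            w, net_cfg@depth, cw, mix,
                            net_cfg@dropoutRate,
                            (train_cfg@seed * 1009 + step) %% 2147483647)
        for (j in seq_along(gW)) {
          gW[[j]] <- gW[[j]] + g$dW[[j]]
          gb[[j]] <- gb[[j]] + g$db[[j]]
        }
        bl <- bl + g$loss
      }
      n <- length(batch)
      t <- t + 1
      corr <- sqrt(1 - b2^t) / (1 - b1^t)
      for (j in seq_along(gW)) {
        gWj <- gW[[j]] / n; gbj <- gb[[j]] / n
        mstate[[j]] <- b1 * mstate[[j]] + (1 - b1) * gWj
        vstate[[j]] <- b2 * vstate[[j]] + (1 - b2) * gWj^2
        w$W[[j]] <- w$W[[j]] - lr * corr * mstate[[j]] /
          (sqrt(vstate[[j]]) + eps)
        mb[[j]] <- b1 * mb[[j]] + (1 - b1) * gbj
        vb[[j]] <- b2 * vb[[j]] + (1 - b2) * gbj^2
        w$b[[j]] <- w$b[[j]] - lr * corr * mb[[j]] / (sqrt(vb[[j]]) + eps)
      }
      ep_loss <- ep_loss + bl / n
      nb <- nb + 1L
    }
    vres <- eval_val(w)
    metric <- if (train_cfg@checkpointMetric == "plaque_dice") vres$dice
      else -vres$loss
    if (metric > best$metric) best <- list(metric = metric, w = w, epoch = ep)
    history <- rbind(history, data.frame(
      epoch = ep, train_loss = ep_loss / nb, val_loss = vres$loss,
      val_plaque_dice = vres$dice))
    if (verbose)
      message(sprintf("epoch %d: train %.4f, val %.4f, plaque dice %.4f",
                      ep, ep_loss / nb, vres$loss, vres$dice))
  }
  list(net = new("SegNet", config = net_cfg, weights = best$w),
       history = history, best_epoch = best$epoch)
}

#' Save / load a network checkpoint
#'
#' Checkpoints are plain JSON (config plus flattened weights), so they are
#' portable text files.
#'
#' @param net a \linkS4class{SegNet}.
#' @param path file path.
#' @return \code{loadCheckpoint} returns the \linkS4class{SegNet}.
#' @export
saveCheckpoint <- function(net, path) {
  cfg <- net@config
  obj <- list(
    config = list(in_channels = cfg@inChannels, n_classes = cfg@nClasses,
                  base_filters = cfg@baseFilters, depth = cfg@depth,
                  dropout_rate = cfg@dropoutRate,
                  upsample_mode = cfg@upsampleMode),
    W = lapply(net@weights$W, function(m)
      list(dim = dim(m), data = as.numeric(m))),
    b = net@weights$b)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- netConfig(obj$config$in_channels, obj$config$n_classes,
                   obj$config$base_filters, obj$config$depth,
                   obj$config$dropout_rate, obj$config$upsample_mode)
  W <- lapply(seq_len(nrow(obj$W)), function(i)
    matrix(obj$W$data[[i]], obj$W$dim[[i]][1], obj$W$dim[[i]][2]))
  b <- lapply(obj$b, as.numeric)
  new("SegNet", config = cfg, weights = list(W = W, b = b))
}
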