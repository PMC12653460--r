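#' ROC curve and trapezoidal AUC
#'
#' Builds the ROC curve of a score against a binary truth over candidate
#' thresholds placed at midpoints between consecutive distinct scores
#' (plus sentinels below the minimum and above the maximum), and computes the
#' AUC both by trapezoidal integration and as the Mann-Whitney rank
#' statistic; the two agree identically for the midpoint-threshold curve.
#'
#' @param scores numeric vector.
#' @param truth logical or 0/1 vector; must contain at least one positive
#'   and one negative.
#' @return List with \code{auc}, and the curve as a data.frame
#'   \code{(threshold, sensitivity, specificity)}; a prediction is positive
#'   when \code{score >= threshold}.
#' @export
rocCurve <- function(scores, truth) {
  truth <- as.logical(truth)
  if (!any(truth) || all(truth))
    stop("ROC requires at least one positive and one negative")
  pos <- scores[truth]; neg <- scores[!truth]
  np <- as.numeric(length(pos)); nn <- as.numeric(length(neg))
  u <- sort(unique(scores))
  k <- length(u)
  thr <- if (k > 1) c(u[1] - 1, (u[-1] + u[-k]) / 2, u[k] + 1)
    else c(u - 1, u + 1)
  # counts per distinct score, cumulated once: sensitivity at the midpoint
  # after u[i] is P(pos >= u[i+1]); specificity there is P(neg <= u[i])
  pos_at <- tabulate(match(pos, u), nbins = k)
  neg_at <- tabulate(match(neg, u), nbins = k)
  pos_ge <- rev(cumsum(rev(pos_at)))
  neg_le <- cumsum(neg_at)
  sens <- c(np, pos_ge[-1], 0) / np
  spec <- c(0, neg_le[-k], nn) / nn
  # Mann-Whitney: P(pos > neg) + 0.5 P(tie)
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  list(auc = auc,
       curve = data.frame(threshold = thr, sensitivity = sens,
                          specificity = spec))
}

#' @rdname rocCurve
#' @return \code{rocAuc} returns the AUC alone.
#' @export
rocAuc <- function(scores, truth) rocCurve(scores, truth)$auc

#' Youden-optimal threshold
#'
#' The threshold maximizing Youden's J = sensitivity + specificity - 1 on a
#' ROC curve; ties are broken toward the lower threshold. For perfectly
#' separated scores this is the midpoint of the gap between the two classes.
#'
#' @param roc the result of \code{\link{rocCurve}}, or its \code{curve}
#'   data.frame.
#' @return The optimal threshold.
#' @export
youdenThreshold <- function(roc) {
  curve <- if (is.data.frame(roc)) roc else roc$curve
  if (!nrow(curve)) stop("empty ROC curve")
  j <- curve$sensitivity + curve$specificity - 1
  curve$threshold[which.max(j)]   # which.max returns the first (lowest)
}

#' 3x3 plaque confusion matrix with per-class statistics
#'
#' Restricted to pixels that carry one of the three plaque morphologies in
#' both the ground truth and the prediction, counts predicted-vs-true class
#' pairs (rows = truth, columns = prediction) and derives overall accuracy
#' (trace over total) and per-class precision (column), recall (row) and F1.
#' Row sums equal the ground-truth class pixel counts on the evaluated
#' subset.
#'
#' @param pred_labels,true_labels integer class arrays of equal shape.
#' @param plaque_classes named codes of the plaque classes (order fixes the
#'   matrix layout).
#' @return List with \code{confusion} (3x3 matrix), \code{overall_accuracy},
#'   and \code{stats} (data.frame: class, precision, recall, f1).
#' @export
plaqueConfusion <- function(pred_labels, true_labels,
                            plaque_classes = octPlaqueClasses()) {
  if (!identical(dim(pred_labels), dim(true_labels)) &&
      length(pred_labels) != length(true_labels))
    stop("prediction and truth shapes differ")
  keep <- true_labels %in% plaque_classes & pred_labels %in% plaque_classes
  if (!any(keep)) stop("no plaque pixels shared by truth and prediction")
  tr <- factor(true_labels[keep], levels = plaque_classes,
               labels = names(plaque_classes))
  pr <- factor(pred_labels[keep], levels = plaque_classes,
               labels = names(plaque_classes))
  cm <- table(truth = tr, prediction = pr)
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(truth = names(plaque_classes),
                               prediction = names(plaque_classes)))
  acc <- sum(diag(cm)) / sum(cm)
  prec <- diag(cm) / pmax(colSums(cm), 1)
  rec <- diag(cm) / pmax(rowSums(cm), 1)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(confusion = cm, overall_accuracy = acc,
       stats = data.frame(class = names(plaque_classes), precision = prec,
                          recall = rec, f1 = f1, row.names = NULL))
}

#' One-dimensional (angular) Dice coefficient
#'
#' Overlap of two arcs discretized on a circle of \code{n_bins} angular bins:
#' 2|A and B| / (|A| + |B|). Two empty arcs are in perfect agreement (1).
#'
#' @param arc_a,arc_b logical membership vectors over the same bins, or
#'   integer bin-index sets (1-based).
#' @param n_bins circle resolution when bin indices are given (default 360,
#'   one-degree bins).
#' @return Dice coefficient in [0, 1].
#' @examples
#' dice1D(1:90, 46:135)   # 0.5
#' @export
dice1D <- function(arc_a, arc_b, n_bins = 360L) {
  tobins <- function(a) {
    if (is.logical(a)) return(a)
    b <- logical(n_bins); b[a] <- TRUE; b
  }
  a <- tobins(arc_a); b <- tobins(arc_b)
  if (length(a) != length(b)) stop("arc bin vectors differ in length")
  if (!any(a) && !any(b)) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

# ICC(2,1): two-way random effects, absolute agreement, single measure,
# with F-distribution 95% CI on the underlying mean squares.
.icc21 <- function(x, y, conf = 0.95) {
  m <- cbind(x, y)
  n <- nrow(m); k <- ncol(m)
  mrow <- rowMeans(m); mcol <- colMeans(m); mu <- mean(m)
  msr <- k * sum((mrow - mu)^2) / (n - 1)
  msc <- n * sum((mcol - mu)^2) / (k - 1)
  sse <- sum((m - outer(mrow, rep(1, k)) - outer(rep(1, n), mcol) + mu)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # Shrout-Fleiss F-based interval
  fj <- msc / mse
  a <- k * icc / (n * (1 - icc)); b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  if (!is.finite(v) || v <= 0)
    return(c(icc = icc, lower = NA_real_, upper = NA_real_))
  fl <- stats::qf(1 - (1 - conf) / 2, n - 1, v)
  fu <- stats::qf(1 - (1 - conf) / 2, v, n - 1)
  lo <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  c(icc = icc, lower = lo, upper = hi)
}

#' Correlation and agreement between paired measurements
#'
#' Pearson product-moment and Spearman rank correlations with Fisher-z 95%
#' confidence intervals, plus the intraclass correlation coefficient in its
#' two-way random-effects, absolute-agreement, single-measure form (ICC(2,1))
#' with an F-distribution interval. Absolute agreement penalizes systematic
#' shifts: y = 2x + 1 has r = 1 but ICC < 1.
#'
#' @param x,y paired finite numeric vectors, n >= 3, each with nonzero
#'   variance.
#' @param conf confidence level (default 0.95).
#' @return List: \code{pearson_r}, \code{pearson_ci}, \code{spearman_rho},
#'   \code{icc}, \code{icc_ci}, \code{n}.
#' @export
agreementStats <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3) stop("agreement requires n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  n <- length(x)
  r <- stats::cor(x, y)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  rci <- tanh(c(z - q * se, z + q * se))
  rho <- stats::cor(x, y, method = "spearman")
  icc <- .icc21(x, y, conf)
  list(pearson_r = r, pearson_ci = rci, spearman_rho = rho,
       icc = icc[["icc"]], icc_ci = c(icc[["lower"]], icc[["upper"]]),
       n = n)
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Computes, per pixel class present in the truth: one-vs-rest ROC AUC of
#' the predicted class probability and the Youden-optimal probability
#' threshold; plus the 3x3 plaque confusion matrix of the argmax labels.
#'
#' @param probs numeric array (radial x angular x 10) of class probabilities
#'   for one frame, or a list of such arrays for a stack.
#' @param true_labels integer label matrix or array aligned with
#'   \code{probs}.
#' @param classes integer codes to evaluate (default: all present in truth).
#' @return An \linkS4class{EvalReport}.
#' @export
evaluateSegmentation <- function(probs, true_labels,
                                 classes = NULL) {
  if (is.list(probs)) {
    nc <- dim(probs[[1]])[3]
    flat <- do.call(rbind, lapply(probs, function(p) {
      matrix(p, ncol = nc)
    }))
    truth_vec <- as.integer(true_labels)
    pred_lab <- max.col(flat) - 1L
  } else {
    nc <- dim(probs)[3]
    flat <- matrix(probs, ncol = nc)
    truth_vec <- as.integer(true_labels)
    pred_lab <- max.col(flat) - 1L
  }
  present <- sort(unique(truth_vec))
  if (is.null(classes)) classes <- present
  classes <- intersect(classes, present)
  nms <- octClassNames()
  auc <- thr <- stats::setNames(numeric(0), character(0))
  for (cl in classes) {
    tr <- truth_vec == cl
    if (all(tr) || !any(tr)) next
    roc <- rocCurve(flat[, cl + 1L], tr)
    auc[nms[cl + 1L]] <- roc$auc
    thr[nms[cl + 1L]] <- youdenThreshold(roc)
  }
  pc <- octPlaqueClasses()
  conf <- if (any(truth_vec %in% pc))
    tryCatch(plaqueConfusion(pred_lab, truth_vec), error = function(e) NULL)
  else NULL
  if (!is.null(conf)) {
    new("EvalReport", perClassAuc = auc, youdenThreshold = thr,
        confusion = conf$confusion, perClassStats = conf$stats,
        overallAccuracy = conf$overall_accuracy, dice1d = numeric(0),
        agreement = list())
  } else {
    new("EvalReport", perClassAuc = auc, youdenThreshold = thr,
        confusion = matrix(0L, 0, 0), perClassStats = data.frame(),
        overallAccuracy = numeric(0), dice1d = numeric(0),
        agreement = list())
  }
}
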