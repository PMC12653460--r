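# brute-force rank oracle: (#concordant + 0.5 #ties) / (P * N)
.aucOracle <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("AUC equals the pairwise rank oracle on random instances", {
  expect_equal(rocAuc(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T)), 1.0)
  expect_equal(rocAuc(rep(5, 8), c(T, T, F, F, T, F, F, T)), 0.5)
  set.seed(19)
  for (rep in 1:25) {
    n <- 12
    scores <- round(runif(n), 2)   # rounding forces ties
    truth <- sample(c(TRUE, FALSE), n, TRUE)
    if (all(truth) || !any(truth)) truth[1:2] <- c(TRUE, FALSE)
    expect_lt(abs(rocAuc(scores, truth) - .aucOracle(scores, truth)), 1e-9)
  }
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "positive and one negative")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(23)
  scores <- runif(30); truth <- sample(c(TRUE, FALSE), 30, TRUE)
  truth[1:2] <- c(TRUE, FALSE)
  a0 <- rocAuc(scores, truth)
  expect_equal(rocAuc(exp(3 * scores), truth), a0)
  expect_equal(rocAuc(rank(scores), truth), a0)
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  scores <- round(runif(200), 2)
  truth <- runif(200) < plogis(6 * (scores - 0.5))
  truth[1:2] <- c(TRUE, FALSE)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(truth, scores,
                                                         quiet = TRUE))))
  expect_equal(rocAuc(scores, truth), ref, tolerance = 1e-12)
})

test_that("Youden threshold equals exhaustive search, ties to the low side", {
  # exhaustive search over every distinct classification a threshold can
  # induce: one candidate inside each gap between consecutive unique scores,
  # plus sentinels; J computed by direct counting
  youdenOracle <- function(scores, truth) {
    u <- sort(unique(scores))
    cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
              u[length(u)] + 1)
    j <- vapply(cand, function(t)
      sum(scores[truth] >= t) / sum(truth) +
        sum(scores[!truth] < t) / sum(!truth) - 1, numeric(1))
    cand[j >= max(j) - 1e-12][1]
  }
  set.seed(37)
  for (rep in 1:20) {
    scores <- round(runif(15), 1)
    truth <- sample(c(TRUE, FALSE), 15, TRUE)
    truth[1:2] <- c(TRUE, FALSE)
    roc <- rocCurve(scores, truth)
    got <- youdenThreshold(roc)
    best <- max(roc$curve$sensitivity + roc$curve$specificity - 1)
    jg <- mean(scores[truth] >= got) + mean(scores[!truth] < got) - 1
    expect_equal(jg, best)                       # achieves the optimum
    expect_equal(got, youdenOracle(scores, truth), tolerance = 1e-9)
  }
  # perfect separation: the midpoint of the gap
  roc <- rocCurve(c(1, 2, 8, 9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(youdenThreshold(roc), 5)
  expect_error(youdenThreshold(data.frame()), "empty")
})

test_that("the plaque confusion matrix matches per-pixel counting", {
  # identical labels: identity pattern
  t1 <- matrix(c(7L, 8L, 9L, 7L), 2, 2)
  c1 <- plaqueConfusion(t1, t1)
  expect_equal(c1$overall_accuracy, 1.0)
  expect_true(all(c1$confusion[upper.tri(c1$confusion)] == 0))
  expect_true(all(c1$stats$f1 == 1))
  # everything predicted calcium, truth uniform
  tr <- rep(c(7L, 8L, 9L), each = 12)
  pr <- rep(7L, 36)
  c2 <- plaqueConfusion(pr, tr)
  expect_equal(c2$overall_accuracy, 1 / 3)
  expect_equal(c2$stats$recall[c2$stats$class == "calcium"], 1)
  expect_equal(c2$stats$precision[c2$stats$class == "calcium"], 1 / 3)
  # random case against a hand-counted oracle
  set.seed(41)
  tr <- matrix(sample(c(0L, 6L, 7L, 8L, 9L), 100, TRUE), 10, 10)
  pr <- matrix(sample(c(0L, 6L, 7L, 8L, 9L), 100, TRUE), 10, 10)
  keep <- tr %in% 7:9 & pr %in% 7:9
  oracle <- matrix(0L, 3, 3)
  for (i in which(keep))
    oracle[tr[i] - 6L, pr[i] - 6L] <- oracle[tr[i] - 6L, pr[i] - 6L] + 1L
  c3 <- plaqueConfusion(pr, tr)
  expect_equal(unname(c3$confusion), oracle)
  expect_equal(c3$overall_accuracy, sum(diag(oracle)) / sum(oracle))
  # row sums equal ground-truth class counts on the evaluated subset
  expect_equal(unname(rowSums(c3$confusion)),
               as.integer(table(factor(tr[keep], levels = 7:9))))
})

test_that("the angular Dice coefficient counts bins", {
  expect_equal(dice1D(1:90, 1:90), 1.0)
  expect_equal(dice1D(1:90, 91:180), 0.0)
  expect_equal(dice1D(1:90, 46:135), 0.5)    # direct bin counting: 45/90
  expect_equal(dice1D(integer(0), integer(0)), 1)
  # symmetry and joint-rotation invariance
  set.seed(43)
  for (rep in 1:10) {
    a <- sample(360, sample(10:120, 1))
    b <- sample(360, sample(10:120, 1))
    expect_equal(dice1D(a, b), dice1D(b, a))
    s <- sample(359, 1)
    ra <- ((a - 1 + s) %% 360) + 1
    rb <- ((b - 1 + s) %% 360) + 1
    expect_equal(dice1D(ra, rb), dice1D(a, b))
  }
})

test_that("agreement statistics behave on canonical cases", {
  x <- c(1, 2, 3, 4, 5, 6, 8, 10)
  a <- agreementStats(x, x)
  expect_equal(a$pearson_r, 1)
  expect_equal(a$spearman_rho, 1)
  expect_equal(a$icc, 1)
  expect_equal(agreementStats(x, -x)$pearson_r, -1)
  # systematic shift: perfect correlation but imperfect absolute agreement
  b <- agreementStats(x, 2 * x + 1)
  expect_equal(b$pearson_r, 1)
  expect_lt(b$icc, 1)
  expect_error(agreementStats(x, rep(1, 8)), "variance")
  expect_error(agreementStats(1:2, 1:2), "n >= 3")
})

test_that("ICC(2,1) matches the ANOVA-decomposition oracle", {
  iccOracle <- function(x, y) {
    m <- cbind(x, y); n <- nrow(m); k <- 2
    g <- data.frame(v = c(m), subj = factor(rep(seq_len(n), k)),
                    rater = factor(rep(seq_len(k), each = n)))
    av <- stats::anova(stats::aov(v ~ subj + rater, data = g))
    msr <- av["subj", "Mean Sq"]; msc <- av["rater", "Mean Sq"]
    mse <- av["Residuals", "Mean Sq"]
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
  set.seed(47)
  for (rep in 1:5) {
    x <- rnorm(12); y <- 0.8 * x + rnorm(12, 0.3, 0.4)
    expect_equal(agreementStats(x, y)$icc, iccOracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("evaluateSegmentation reports AUC 1 for a perfect prediction", {
  lab <- paintSector(blankLabels(32, 64), 100, 90, 10, 20)
  probs <- array(0, dim = c(32, 64, 10))
  for (cl in 0:9) probs[, , cl + 1][lab == cl] <- 1
  rep <- evaluateSegmentation(list(probs), lab)
  expect_true(all(abs(rep@perClassAuc - 1) < 1e-12))
  expect_equal(rep@overallAccuracy, 1)
})
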