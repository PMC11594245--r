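test_that("confusion counts match a hand count and ignore sample order", {
  truth <- c(1, 1, 1, 1, 1, 1, 1, 2, 2, 2)
  pred  <- c(1, 1, 1, 1, 1, 1, 2, 2, 2, 1)
  cm <- confusionMatrix(truth, pred)
  # class 2 positive: TP = 2, FP = 1, FN = 1, TN = 6
  expect_identical(unname(cm), rbind(c(6L, 1L), c(1L, 2L)))
  set.seed(1); perm <- sample(10)
  expect_identical(confusionMatrix(truth[perm], pred[perm]), cm)
  expect_identical(unname(confusionMatrix(c(1, 2), c(1, 2))),
                   diag(1L, 2))
  expect_error(confusionMatrix(c(1, 2), c(1, 3), classes = 1:2),
               "input error")
})

test_that("balanced accuracy and macro F1 match their definitions", {
  # recalls 1.0 and 0.5 -> B.Acc 0.75
  cm <- rbind(c(4L, 0L), c(2L, 2L))
  expect_equal(balancedAccuracy(cm), 0.75)

  # binary identity: B.Acc = (sensitivity + specificity) / 2
  set.seed(33)
  for (r in 1:20) {
    truth <- c(1, 2, sample(1:2, 30, replace = TRUE))
    pred <- sample(1:2, 32, replace = TRUE)
    cm <- confusionMatrix(truth, pred)
    ss <- sensSpec(cm)
    expect_equal(balancedAccuracy(cm),
                 (ss$sensitivity[1] + ss$specificity[1]) / 2,
                 tolerance = 1e-12)
    # per-class F1 matches the 2PR/(P+R) loop oracle
    for (k in 1:2) {
      tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
      prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
      rec <- tp / (tp + fn)
      f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
      rep <- evalReport(truth, pred)
      expect_equal(perClassMetrics(rep)$f1[k], f1, tolerance = 1e-12)
    }
  }
  # duplicating majority test instances leaves B.Acc unchanged
  truth <- c(1, 1, 1, 1, 2, 2); pred <- c(1, 1, 2, 1, 2, 1)
  cmDup <- confusionMatrix(c(truth, truth[truth == 1]),
                           c(pred, pred[truth == 1]))
  expect_equal(balancedAccuracy(cmDup),
               balancedAccuracy(confusionMatrix(truth, pred)))
  expect_error(balancedAccuracy(rbind(c(2L, 0L), c(0L, 0L))),
               "undefined-metric")
})

test_that("macro AUROC matches the all-pairs oracle and handles extremes", {
  pairOracle <- function(s, pos) {
    tot <- 0; n <- 0
    for (i in which(pos)) for (j in which(!pos)) {
      tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j]); n <- n + 1
    }
    tot / n
  }
  set.seed(55)
  for (r in 1:10) {
    N <- sample(20:200, 1); C <- sample(2:4, 1)
    labels <- c(1:C, sample(1:C, N - C, replace = TRUE))
    scores <- matrix(round(rnorm(N * C), 1), N, C)  # rounding forces ties
    want <- mean(sapply(1:C, function(k) pairOracle(scores[, k], labels == k)))
    expect_lt(abs(macroAUROC(scores, labels) - want), 1e-12)
  }
  # perfect and anti-ordered scores
  lab <- rep(1:2, each = 5)
  sc <- cbind(c(rep(1, 5), rep(0, 5)), c(rep(0, 5), rep(1, 5)))
  expect_equal(macroAUROC(sc, lab), 1)
  expect_equal(macroAP(sc, lab), 1)
  expect_equal(macroAUROC(sc[, 2:1], lab), 0)
  expect_error(macroAUROC(sc, rep(1L, 10), classes = 1:2),
               "undefined-metric")

  # random scores on a large binary sample hover around 0.5
  set.seed(7)
  lab <- sample(1:2, 200, replace = TRUE)
  sc <- matrix(runif(400), 200, 2)
  expect_lt(abs(macroAUROC(sc, lab) - 0.5), 0.1)
})

test_that("average precision agrees with an independent reference", {
  set.seed(91)
  s <- rnorm(60)
  pos <- runif(60) < 0.3; pos[1:2] <- c(TRUE, FALSE)
  got <- ProtoDS:::aurocBinary(s, pos)
  ref <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = s,
                                        quiet = TRUE, direction = "<")))
  expect_equal(got, ref, tolerance = 1e-12)
  # AP: step-wise sum oracle written out longhand
  o <- order(s, decreasing = TRUE)
  y <- pos[o]
  ap <- 0; tp <- 0
  for (i in seq_along(y)) {
    if (y[i]) { tp <- tp + 1; ap <- ap + tp / i }
  }
  ap <- ap / sum(pos)
  expect_equal(ProtoDS:::apBinary(s, pos), ap, tolerance = 1e-12)
})

test_that("ratio-scaled minority counts follow half-up rounding", {
  counts <- c(maj = 197L, mid = 104L, low = 40L)
  # note: with these three classes 'maj' is the majority and is kept whole
  expect_identical(unname(scaleMinorityCounts(counts, 5)),
                   c(NA_integer_, 13L, 5L))
  full <- c(a = 1267L, b = 197L, c = 104L, d = 40L)
  for (n in c(1L, 5L, 10L, 15L, 20L)) {
    got <- scaleMinorityCounts(full, n)
    expect_true(is.na(got[1]))
    expect_identical(unname(got[2:4]),
                     as.integer(floor(n * c(197, 104, 40) / 40 + 0.5)))
  }
})

test_that("imbalanced splits keep the test set fixed across n", {
  man <- data.frame(instance_id = sprintf("i%03d", 1:116),
                    label = rep(c(1L, 2L, 3L), c(60, 36, 20)))
  s5 <- buildImbalancedSplit(man, n = 5, testFraction = 0.5, seed = 4)
  s2 <- buildImbalancedSplit(man, n = 2, testFraction = 0.5, seed = 4)
  expect_identical(s5$test, s2$test)
  # training side floored, test side gets the remainder
  expect_identical(sum(s5$test$label == 1), 30L)
  # majority untouched, least minority = n, intermediate ratio-scaled
  trainCounts <- table(s5$train$label)
  expect_identical(as.integer(trainCounts[["1"]]), 30L)
  expect_identical(as.integer(trainCounts[["3"]]), 5L)
  expect_identical(as.integer(trainCounts[["2"]]),
                   as.integer(floor(5 * 36 / 20 + 0.5)))
  expect_error(buildImbalancedSplit(man, n = 50, seed = 1), "spec error")

  # binary dataset: minority exactly n, majority whole
  man2 <- data.frame(instance_id = sprintf("b%03d", 1:90),
                     label = rep(c(1L, 2L), c(50, 40)))
  s <- buildImbalancedSplit(man2, n = 20, testFraction = 0.5, seed = 9)
  expect_identical(as.integer(table(s$train$label)[["2"]]), 20L)
  expect_identical(as.integer(table(s$train$label)[["1"]]), 25L)
})

test_that("the ablation grid runner emits a deterministic long table", {
  factory <- function(n, seed) {
    sd <- smallDataset(seed = seed + 100, majority = 6, minority = n,
                       testPerClass = 2, nBands = 24)
    list(train = sd$train, test = sd$test)
  }
  ssl <- sslConfig(B = 4, epochs = 2, instancesPerStep = 6)
  ft <- finetuneConfig(epochs = 2, batchSize = 32)
  netCfg <- networkConfig(length(selectBands(seq(900, 1700,
                                                 length.out = 24))),
                          hiddenDim = 8, nBlocks = 1)
  g1 <- runAblation(factory, nValues = 2, variants = "no_ssl_no_dice",
                    seeds = 1L, netCfg = netCfg, sslCfg = ssl, ftCfg = ft)
  expect_identical(nrow(g1), 1L)
  expect_true(is.na(g1$error[1]))
  expect_true(is.finite(g1$bAcc[1]))
  g2 <- runAblation(factory, nValues = 2, variants = "no_ssl_no_dice",
                    seeds = 1L, netCfg = netCfg, sslCfg = ssl, ftCfg = ft)
  expect_identical(g1$bAcc, g2$bAcc)
  # failures are recorded, not fatal
  gBad <- runAblation(function(n, seed) stop("boom"), nValues = 1,
                      variants = "full", seeds = 1L)
  expect_match(gBad$error[1], "boom")
})

test_that("Gaussian-overlap separability behaves at its extremes and converges", {
  set.seed(12)
  base <- matrix(rnorm(60 * 3), 60, 3)
  # identical samples under two labels: regions coincide, IOU = 1
  emb <- rbind(base, base)
  lab <- rep(1:2, each = 60)
  r <- separabilityIOU(emb, lab, gridRes = 120)
  expect_gte(r$iou[1, 2], 0.98)

  # far-separated clusters: IOU = 0
  emb2 <- rbind(base, sweep(base, 2, c(50, 50, 0), `+`))
  r2 <- separabilityIOU(emb2, lab, gridRes = 120)
  expect_equal(r2$iou[1, 2], 0)

  # moderate overlap: doubling the grid changes IOU by <= 0.01
  set.seed(13)
  emb3 <- rbind(matrix(rnorm(80 * 3), 80, 3),
                matrix(rnorm(80 * 3, mean = 1), 80, 3))
  lab3 <- rep(1:2, each = 80)
  a <- separabilityIOU(emb3, lab3, gridRes = 150)$iou[1, 2]
  b <- separabilityIOU(emb3, lab3, gridRes = 300)$iou[1, 2]
  expect_lte(abs(a - b), 0.01)
  expect_identical(dim(r$projection), c(120L, 2L))
  # a collapsed class covariance is regularised with a warning
  degen <- rbind(matrix(1, 5, 3), matrix(rnorm(15), 5, 3))
  expect_warning(separabilityIOU(degen, rep(1:2, each = 5), gridRes = 60),
                 "singular covariance")
})
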