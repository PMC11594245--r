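test_that("Dice loss matches its closed forms", {
  # perfect probabilities: DSC = 1 per class -> loss 0
  Y <- oneHot(c(1L, 2L, 1L), 1:2)
  expect_equal(diceLoss(Y, Y), 0)

  # single sample, C = 2, p = (0.5, 0.5), true class 1:
  # class-1 term 1 - 2*0.5/(0.5 + 1) = 0.2; class-2 term 1 - 0 = 1
  expect_equal(diceLoss(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1)), 0.6,
               tolerance = 1e-12)

  # hard predictions, TP = 2, FP = 1, FN = 1 on the positive class:
  # DSC = 2*2/(4 + 1 + 1) = 2/3, i.e. the F1 score
  truth <- c(1L, 1L, 1L, 2L)
  pred <- c(1L, 1L, 2L, 1L)
  P <- oneHot(pred, 1:2); Yh <- oneHot(truth, 1:2)
  classTerm1 <- 1 - 2 * sum(P[, 1] * Yh[, 1]) /
    (sum(P[, 1]^2) + sum(Yh[, 1]^2))
  expect_equal(1 - classTerm1, 2 / 3, tolerance = 1e-12)
  expect_equal(diceLoss(P, Yh), mean(c(classTerm1,
    1 - 2 * sum(P[, 2] * Yh[, 2]) / (sum(P[, 2]^2) + sum(Yh[, 2]^2)))))
  expect_error(diceLoss(P[0, , drop = FALSE], Yh[0, , drop = FALSE]),
               "input error")
})

test_that("per-class (1 - Dice term) equals one-vs-rest F1 for hard predictions", {
  set.seed(99)
  for (r in 1:200) {
    C <- sample(2:5, 1)
    N <- sample(C:40, 1)
    truth <- c(seq_len(C), sample(seq_len(C), max(N - C, 0), replace = TRUE))
    pred <- sample(seq_len(C), length(truth), replace = TRUE)
    P <- oneHot(pred, seq_len(C)); Y <- oneHot(truth, seq_len(C))
    dsc <- 1 - (1 - 2 * colSums(P * Y) / (colSums(P^2) + colSums(Y^2)))
    cm <- confusionMatrix(truth, pred, seq_len(C))
    tp <- diag(cm); fp <- colSums(cm) - tp; fn <- rowSums(cm) - tp
    f1 <- ifelse(2 * tp + fp + fn == 0, 0, 2 * tp / (2 * tp + fp + fn))
    expect_lt(max(abs(dsc - f1)), 1e-12)
  }
})

test_that("Dice loss stays in [0, 1], is order invariant and handles absent classes", {
  set.seed(17)
  for (r in 1:20) {
    N <- 12; C <- 3
    Z <- matrix(rnorm(N * C), N, C)
    P <- exp(Z) / rowSums(exp(Z))
    Y <- oneHot(sample(1:C, N, replace = TRUE), 1:C)
    d <- diceLoss(P, Y)
    expect_gte(d, 0); expect_lte(d, 1)
    perm <- sample(N)
    expect_equal(diceLoss(P[perm, ], Y[perm, ]), d, tolerance = 1e-12)
  }
  # class 3 absent from the batch truth but predicted: term computed as written
  P <- rbind(c(0.2, 0.2, 0.6), c(0.8, 0.1, 0.1))
  Y <- oneHot(c(1L, 1L), 1:3)
  t3 <- 1 - 0 / (sum(P[, 3]^2) + 0)
  expect_equal(diceLoss(P, Y),
               mean(c(1 - 2 * sum(P[, 1] * Y[, 1]) /
                        (sum(P[, 1]^2) + sum(Y[, 1]^2)), 1, t3)))
  # denominator exactly zero -> the class contributes 0
  Ph <- oneHot(c(1L, 1L), 1:3)
  expect_equal(diceLoss(Ph, Ph), 0)
})

test_that("combined loss reduces to its parts", {
  Y <- oneHot(c(1L, 2L), 1:2)
  expect_equal(as.numeric(combinedLoss(Y, Y)), 0)
  set.seed(2)
  Z <- matrix(rnorm(8), 4, 2)
  P <- exp(Z) / rowSums(exp(Z))
  Yr <- oneHot(sample(1:2, 4, replace = TRUE), 1:2)
  expect_equal(as.numeric(combinedLoss(P, Yr, lambdaCE = 1, lambdaD = 0)),
               mean(-log(rowSums(P * Yr))), tolerance = 1e-12)
  # uniform binary probabilities: CE part = log 2
  U <- matrix(0.5, 4, 2)
  cl <- combinedLoss(U, Yr)
  expect_equal(attr(cl, "ce"), log(2), tolerance = 1e-12)
  expect_equal(as.numeric(cl), log(2) + attr(cl, "dice"), tolerance = 1e-12)
  # clamping keeps the loss finite at zero true-class probability
  expect_true(is.finite(combinedLoss(oneHot(c(2L, 2L), 1:2), Y)))
})

test_that("episodic fine-tuning is reproducible and handles n = 1 minorities", {
  sd <- smallDataset(seed = 44, majority = 6, minority = 1, testPerClass = 2,
                     nBands = 24)
  D <- ncol(spectra(sd$train[[1]]))
  net <- tinyNet(D, seed = 6)
  cfg <- finetuneConfig(epochs = 3, lr = 1e-3, batchSize = 32, seed = 11)
  a <- finetuneNetwork(net, sd$train, cfg)
  b <- finetuneNetwork(net, sd$train, cfg)
  expect_true(netParamsEqual(a$net, b$net))
  expect_identical(a$log, b$log)
  expect_identical(nrow(a$log), 3L)
  expect_true(all(is.finite(a$log$total)))
})

test_that("fine-tuning improves training-query balanced accuracy", {
  sd <- smallDataset(seed = 52, majority = 12, minority = 6, testPerClass = 2,
                     nBands = 32, noiseSd = 0.04, delta = 0.1)
  D <- ncol(spectra(sd$train[[1]]))
  net <- tinyNet(D, hidden = 32, blocks = 2, seed = 13)
  baccOf <- function(net) {
    labels <- vapply(sd$train, instanceLabel, integer(1))
    X <- do.call(rbind, lapply(sd$train, spectra))
    lab <- rep(labels, vapply(sd$train, function(i) nrow(spectra(i)),
                              integer(1)))
    E <- embedSpectra(net, X)
    protos <- computePrototypes(E, lab)
    pred <- classIds(protos)[max.col(protoPosteriors(E, protos),
                                     ties.method = "first")]
    balancedAccuracy(confusionMatrix(lab, pred))
  }
  few <- finetuneNetwork(net, sd$train,
                         finetuneConfig(epochs = 1, lr = 2e-3, seed = 1,
                                        batchSize = 64))
  many <- finetuneNetwork(net, sd$train,
                          finetuneConfig(epochs = 25, lr = 2e-3, seed = 1,
                                         batchSize = 64))
  expect_gte(baccOf(many$net), baccOf(few$net))
})

test_that("the four ablation variants train and checkpoints round-trip", {
  sd <- smallDataset(seed = 61, majority = 6, minority = 3, testPerClass = 2,
                     nBands = 24)
  netCfg <- networkConfig(ncol(spectra(sd$train[[1]])), hiddenDim = 16,
                          nBlocks = 2)
  ssl <- sslConfig(B = 4, epochs = 2, instancesPerStep = 6)
  ft <- finetuneConfig(epochs = 2, batchSize = 32)
  variants <- list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE),
                   c(FALSE, FALSE))
  names <- c("full", "no_dice", "no_ssl", "no_ssl_no_dice")
  for (i in seq_along(variants)) {
    m <- trainProtoDS(sd$train, netCfg = netCfg, sslCfg = ssl, ftCfg = ft,
                      useSSL = variants[[i]][1], useDice = variants[[i]][2],
                      seed = 5)
    expect_identical(m@trainingInfo$ablation, names[i])
    expect_identical(classIds(m@prototypes), 1:2)
  }
  m <- trainProtoDS(sd$train, netCfg = netCfg, sslCfg = ssl, ftCfg = ft,
                    seed = 9)
  p <- file.path(tempdir(), "ckpt.rds")
  saveModel(m, p)
  m2 <- loadModel(p)
  predA <- vapply(sd$test, function(i)
    classifyInstance(m@network, i, m@prototypes)$class, integer(1))
  predB <- vapply(sd$test, function(i)
    classifyInstance(m2@network, i, m2@prototypes)$class, integer(1))
  expect_identical(predA, predB)
  expect_true(file.exists(paste0(p, ".json")))
})

test_that("randomly permuted labels collapse test accuracy towards chance", {
  sd <- smallDataset(seed = 71, majority = 10, minority = 10,
                     testPerClass = 6, nBands = 24, noiseSd = 0.01,
                     delta = 0.2)
  netCfg <- networkConfig(ncol(spectra(sd$train[[1]])), hiddenDim = 16,
                          nBlocks = 2)
  ft <- finetuneConfig(epochs = 8, lr = 1e-3, batchSize = 64)
  mGood <- trainProtoDS(sd$train, netCfg = netCfg, ftCfg = ft,
                        useSSL = FALSE, seed = 3)
  baccGood <- reportMetrics(evaluateModel(mGood, sd$test))[["bAcc"]]
  labels <- vapply(sd$train, instanceLabel, integer(1))
  baccBad <- sapply(1:3, function(s) {
    set.seed(s)
    perm <- sample(labels)   # count-preserving random relabelling
    shuffled <- Map(function(i, l) { i@label <- l; i }, sd$train, perm)
    m <- trainProtoDS(shuffled, netCfg = netCfg, ftCfg = ft,
                      useSSL = FALSE, seed = 3)
    reportMetrics(evaluateModel(m, sd$test))[["bAcc"]]
  })
  expect_gte(baccGood, 0.9)
  expect_lte(mean(baccBad), 0.7)   # collapses towards 1/C = 0.5
})
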