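test_that("prototypes are per-class embedding means, order invariant", {
  emb <- rbind(c(0, 2), c(2, 0), c(5, 5))
  lab <- c(1L, 1L, 2L)
  p <- computePrototypes(emb, lab)
  expect_equal(unname(prototypeMatrix(p)), rbind(c(1, 1), c(5, 5)))
  expect_identical(classIds(p), c(1L, 2L))

  # single sample per class: prototype equals the embedding
  p1 <- computePrototypes(emb, c(1L, 2L, 3L))
  expect_equal(unname(prototypeMatrix(p1)), emb)

  # permuting rows leaves prototypes unchanged
  set.seed(4)
  emb2 <- matrix(rnorm(30), 10, 3)
  lab2 <- sample(1:3, 10, replace = TRUE); lab2[1:3] <- 1:3
  perm <- sample(10)
  expect_equal(prototypeMatrix(computePrototypes(emb2, lab2)),
               prototypeMatrix(computePrototypes(emb2[perm, ], lab2[perm])))

  expect_error(computePrototypes(emb, lab, classes = 1:3), "support error")
})

test_that("prototype/posterior computations match loop-based oracles", {
  set.seed(77)
  for (rep in 1:5) {
    N <- 20; M <- 6; C <- 3
    emb <- matrix(rnorm(N * M), N, M)
    lab <- c(1:C, sample(1:C, N - C, replace = TRUE))
    protos <- computePrototypes(emb, lab)
    oracleProto <- matrix(NA_real_, C, M)
    for (k in 1:C) {
      acc <- rep(0, M); cnt <- 0
      for (i in 1:N) if (lab[i] == k) { acc <- acc + emb[i, ]; cnt <- cnt + 1 }
      oracleProto[k, ] <- acc / cnt
    }
    expect_lt(max(abs(prototypeMatrix(protos) - oracleProto)), 1e-12)

    q <- rnorm(M)
    post <- protoPosteriors(q, protos)[1, ]
    d2 <- sapply(1:C, function(k) sum((q - oracleProto[k, ])^2))
    oraclePost <- exp(-d2 - max(-d2)) / sum(exp(-d2 - max(-d2)))
    expect_lt(max(abs(post - oraclePost)), 1e-12)
    expect_equal(sum(post), 1, tolerance = 1e-9)
  }
})

test_that("posteriors have the closed-form, symmetry and invariance properties", {
  # 1-D: q = 0, c1 = 1, c2 = 2 with squared Euclidean distance
  p <- computePrototypes(matrix(c(1, 2), 2, 1), c(1L, 2L))
  post <- protoPosteriors(0, p)[1, ]
  expect_equal(unname(post[1]), exp(-1) / (exp(-1) + exp(-4)),
               tolerance = 1e-12)
  expect_equal(unname(post[1]), 0.9526, tolerance = 1e-4)

  # equidistant query -> uniform posterior
  sq <- computePrototypes(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)), 1:4)
  expect_equal(unname(protoPosteriors(c(0, 0), sq)[1, ]), rep(0.25, 4))

  # translation invariance
  set.seed(12)
  pm <- matrix(rnorm(12), 4, 3)
  q <- rnorm(3); shift <- rnorm(3)
  a <- protoPosteriors(q, computePrototypes(pm, 1:4))
  b <- protoPosteriors(q + shift,
                       computePrototypes(sweep(pm, 2, shift, `+`), 1:4))
  expect_lt(max(abs(a - b)), 1e-9)

  # monotonicity: moving the query towards c1 strictly raises p(1)
  pA <- protoPosteriors(c(0.9, 0), computePrototypes(pmax <- rbind(c(1, 0), c(-1, 0)), 1:2))[1, 1]
  pB <- protoPosteriors(c(0.5, 0), computePrototypes(rbind(c(1, 0), c(-1, 0)), 1:2))[1, 1]
  expect_gt(pA, pB)

  # extreme distances stay normalised thanks to max-logit stabilisation
  far <- computePrototypes(rbind(c(0, 0), c(400, 0)), 1:2)
  postFar <- protoPosteriors(c(0, 0), far)[1, ]
  expect_equal(sum(postFar), 1)
  expect_false(any(is.nan(postFar)))
})

test_that("set pooling is the row mean with its invariances", {
  set.seed(5)
  E <- matrix(rnorm(21), 7, 3)
  pooled <- setPool(E)
  oracle <- sapply(1:3, function(j) { s <- 0; for (i in 1:7) s <- s + E[i, j]; s / 7 })
  expect_lt(max(abs(pooled - oracle)), 1e-12)
  expect_equal(setPool(E[2, , drop = FALSE]), E[2, ])        # N = 1 identity
  expect_equal(setPool(rbind(E, E, E)), pooled)              # duplication
  expect_error(setPool(E[0, , drop = FALSE]), "degenerate-instance")
})

test_that("instance classification is exact on noiseless separated data", {
  sd <- smallDataset(seed = 30, nClasses = 3, majority = 4, minority = 4,
                     testPerClass = 3, noiseSd = 0, delta = 0.2, shadow = 0,
                     illumJitterSd = 0, pixelJitterSd = 0)
  # zero generator noise: even an untrained network separates the classes
  net <- tinyNet(ncol(spectra(sd$train[[1]])), seed = 2)
  emb <- embedSpectra(net, do.call(rbind, lapply(sd$train, spectra)))
  lab <- rep(vapply(sd$train, instanceLabel, integer(1)),
             vapply(sd$train, function(i) nrow(spectra(i)), integer(1)))
  protos <- computePrototypes(emb, lab)
  for (inst in sd$test) {
    res <- classifyInstance(net, inst, protos)
    expect_identical(res$class, instanceLabel(inst))
    expect_equal(sum(res$posterior), 1, tolerance = 1e-9)
  }
  # all pixels identical -> instance prediction equals single-pixel query
  inst1 <- sd$test[[1]]
  single <- protoPosteriors(embedSpectra(net, spectra(inst1)[1, ]), protos)
  whole <- classifyInstance(net, inst1, protos)$posterior
  expect_lt(max(abs(single[1, ] - whole)), 1e-9)
})

test_that("pixel probability maps cover exactly the effective pixels", {
  model <- signatureModel(2, nBands = 32, delta = 0.1)
  set.seed(40)
  sig <- makeSignatures(model)
  cfg <- simConfig(pixels = c(5, 5), shadowFraction = 0.2, noiseSd = 0.01)
  cube <- simulateInstance(sig[1, ], model$wavelengths, cfg)
  idx <- selectBands(model$wavelengths)
  setMask(cube) <- effectiveMask(cube, idx)
  inst <- cubeToInstance(cube, idx, label = 1L)
  net <- tinyNet(length(idx), seed = 3)
  emb <- embedSpectra(net, spectra(inst))
  protos <- computePrototypes(rbind(emb[1, ], emb[1, ] + 5), 1:2)
  map <- pixelProbabilityMap(net, cube, idx, protos, 1)
  expect_identical(sum(!is.na(map)), sum(effMask(cube)))
  expect_true(all(map[!is.na(map)] >= 0 & map[!is.na(map)] <= 1))

  # constant-input cube -> constant map values
  cfg0 <- simConfig(pixels = c(4, 4), illumJitterSd = 0, pixelJitterSd = 0,
                    noiseSd = 0, shadowFraction = 0)
  cube0 <- simulateInstance(sig[1, ], model$wavelengths, cfg0)
  setMask(cube0) <- effectiveMask(cube0, idx)
  map0 <- pixelProbabilityMap(net, cube0, idx, protos, 2)
  expect_lt(diff(range(map0)), 1e-6)
})
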