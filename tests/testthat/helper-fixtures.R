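# Shared fixture builders; everything is generated in code, seeded.

# constant-valued cube
constantCube <- function(value, H = 2, W = 2, wl = c(1000, 1200, 1400)) {
  hyperCube(array(value, c(H, W, length(wl))), wl)
}

calibratedCube <- function(values, wl) {
  new("CalibratedCube", values = values, wavelengths = wl)
}

# a small labelled instance with arbitrary spectra
makeInstance <- function(X, label = 1L, id = "i1", wl = NULL) {
  new("SpectraInstance", instanceId = id, label = as.integer(label),
      spectra = X,
      pixelCoords = cbind(row = seq_len(nrow(X)), col = rep(1L, nrow(X))),
      bandWavelengths = wl %||% numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic small synthetic instance set: nPerClass instances per class,
# pixels 4x4, returns list(train, test) of SpectraInstance
smallDataset <- function(seed = 1, nClasses = 2, majority = 10, minority = 4,
                         testPerClass = 5, pixels = c(4, 4), nBands = 48,
                         noiseSd = 0.02, delta = 0.15, shadow = 0.1,
                         illumJitterSd = 0.1, pixelJitterSd = 0.05) {
  model <- signatureModel(nClasses, nBands = nBands, delta = delta)
  cfg <- simConfig(seed = seed, majorityTrain = majority,
                   minorityTrain = rep(minority, nClasses - 1),
                   testPerClass = testPerClass, pixels = pixels,
                   noiseSd = noiseSd, shadowFraction = shadow,
                   illumJitterSd = illumJitterSd,
                   pixelJitterSd = pixelJitterSd)
  ds <- simulateDataset(model, cfg)
  list(train = splitToInstances(ds$train), test = splitToInstances(ds$test),
       dataset = ds)
}

# tiny network for fast training tests
tinyNet <- function(D, hidden = 16, blocks = 2, seed = 1) {
  initNetwork(networkConfig(D, hiddenDim = hidden, nBlocks = blocks), seed)
}

netParamsEqual <- function(a, b, tol = 0) {
  all(unlist(Map(function(pa, pb)
    all(mapply(function(x, y) max(abs(x - y)) <= tol, pa, pb)),
    a@params, b@params)))
}
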