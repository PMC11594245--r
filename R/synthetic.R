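#' Class-signature model for synthetic NIR data
#'
#' Describes how per-class mean reflectance signatures are drawn: smooth
#' curves over the sensor's wavelength grid built from a baseline plus a sum
#' of Gaussian bumps, constrained to lie strictly inside (0.1, 1.0) so that
#' foreground pixels pass the effective-pixel rule, and mutually separated
#' by at least `delta` (root-mean-square reflectance difference per band).
#'
#' @param nClasses number of classes C.
#' @param nBands number of spectral bands B.
#' @param lambdaRange wavelength range (nm) of the simulated sensor,
#'   inclusive endpoints; bands are uniformly spaced.
#' @param baseline baseline reflectance level.
#' @param nBumps Gaussian bumps per class signature.
#' @param widthRange bump s.d. range (nm).
#' @param ampRange bump amplitude range (reflectance; sign randomised).
#' @param delta minimum pairwise RMS-per-band distance between class mean
#'   signatures. 0 disables the separation constraint.
#' @param maxRetries resampling attempts before giving up on `delta`.
#' @return an object of class `SignatureModel` (a validated list)
#' @export
signatureModel <- function(nClasses, nBands = 256, lambdaRange = c(900, 1700),
                           baseline = 0.45, nBumps = 3,
                           widthRange = c(40, 120), ampRange = c(0.08, 0.30),
                           delta = 0.1, maxRetries = 200L) {
  stopifnot(nClasses >= 1, nBands >= 1, lambdaRange[1] < lambdaRange[2],
            nBumps >= 1, delta >= 0, maxRetries >= 1)
  structure(list(nClasses = as.integer(nClasses), nBands = as.integer(nBands),
                 wavelengths = seq(lambdaRange[1], lambdaRange[2],
                                   length.out = nBands),
                 baseline = baseline, nBumps = as.integer(nBumps),
                 widthRange = widthRange, ampRange = ampRange,
                 delta = delta, maxRetries = as.integer(maxRetries)),
            class = "SignatureModel")
}

drawSignature <- function(model) {
  wl <- model$wavelengths
  s <- rep(model$baseline, model$nBands)
  for (k in seq_len(model$nBumps)) {
    centre <- stats::runif(1, min(wl), max(wl))
    width <- stats::runif(1, model$widthRange[1], model$widthRange[2])
    amp <- stats::runif(1, model$ampRange[1], model$ampRange[2]) *
      sample(c(-1, 1), 1)
    s <- s + amp * exp(-0.5 * ((wl - centre) / width)^2)
  }
  pmin(pmax(s, 0.12), 0.98)  # keep strictly inside (0.1, 1.0)
}

#' Draw separated class mean signatures
#'
#' Samples one smooth signature per class and resamples the whole set until
#' every pair is at least `delta` apart (RMS reflectance difference per
#' band), up to `maxRetries` attempts.
#'
#' @param model a [signatureModel()].
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return C x B numeric matrix of class mean signatures
#' @export
makeSignatures <- function(model, seed = NULL) {
  stopifnot(inherits(model, "SignatureModel"))
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(model$maxRetries)) {
    sig <- t(vapply(seq_len(model$nClasses),
                    function(i) drawSignature(model),
                    numeric(model$nBands)))
    if (model$nClasses < 2L || model$delta == 0) return(sig)
    dmin <- min(stats::dist(sig)) / sqrt(model$nBands)
    if (dmin >= model$delta) return(sig)
  }
  stop(sprintf(paste0("configuration error: could not achieve pairwise ",
                      "signature separation delta = %g after %d attempts"),
               model$delta, model$maxRetries))
}

#' Simulation configuration for synthetic instance cubes
#'
#' The generator emulates the structure the method assumes in real NIR
#' instance data: every pixel of an instance shares the class signature, an
#' instance-level multiplicative illumination factor (lognormal) makes
#' pixels of one instance resemble each other more than pixels of other
#' instances, per-pixel multiplicative jitter and additive Gaussian band
#' noise perturb individual spectra, and a fraction of shadow pixels is
#' scaled low enough to fail the 0.1 effective-pixel rule.
#'
#' @param seed integer RNG seed for [simulateDataset()].
#' @param majorityTrain training instances of class 1 (the majority class).
#' @param minorityTrain integer vector of training instance counts of
#'   classes 2..C (may be 0 to drop a class from training).
#' @param testPerClass test instances per class.
#' @param pixels c(H, W) spatial size of each instance cube.
#' @param illumJitterSd s.d. of the instance-level log-normal illumination
#'   factor.
#' @param pixelJitterSd s.d. of the per-pixel log-normal scale jitter.
#' @param noiseSd s.d. of the additive per-band Gaussian noise.
#' @param shadowFraction fraction of pixels per instance rescaled so their
#'   mean reflectance falls below 0.1 (ineffective pixels).
#' @param rawMode when TRUE also emit raw/dark/white triplets such that
#'   [calibrateCube()] recovers the reflectance cube.
#' @return an object of class `SimConfig` (a validated list)
#' @export
simConfig <- function(seed = 1L, majorityTrain = 100L, minorityTrain = 5L,
                      testPerClass = 30L, pixels = c(6L, 6L),
                      illumJitterSd = 0.10, pixelJitterSd = 0.05,
                      noiseSd = 0.02, shadowFraction = 0.10,
                      rawMode = FALSE) {
  stopifnot(majorityTrain >= 1, all(minorityTrain >= 0), testPerClass >= 1,
            length(pixels) == 2, all(pixels >= 1),
            illumJitterSd >= 0, pixelJitterSd >= 0, noiseSd >= 0,
            shadowFraction >= 0, shadowFraction <= 1)
  structure(list(seed = as.integer(seed),
                 majorityTrain = as.integer(majorityTrain),
                 minorityTrain = as.integer(minorityTrain),
                 testPerClass = as.integer(testPerClass),
                 pixels = as.integer(pixels),
                 illumJitterSd = illumJitterSd,
                 pixelJitterSd = pixelJitterSd,
                 noiseSd = noiseSd, shadowFraction = shadowFraction,
                 rawMode = isTRUE(rawMode)),
            class = "SimConfig")
}

#' Simulate one instance cube from a class signature
#'
#' Pixel p of the cube gets reflectance
#' `clip(scale_p * signature + eps_p, 0, 1.2)` where `scale_p` is the
#' product of an instance-level and a per-pixel log-normal factor and
#' `eps_p` is i.i.d. Gaussian band noise. A `shadowFraction` subset of
#' pixels is instead scaled to a mean reflectance drawn from (0.02, 0.07),
#' guaranteeing they fail the strict 0.1 effective-pixel rule. The ceiling
#' 1.2 allows mild over-white reflectance, as real min-max calibrated data
#' can exceed 1.
#'
#' @param signature numeric length-B mean reflectance curve in (0, 1).
#' @param wavelengths numeric length-B band centres (nm).
#' @param cfg a [simConfig()] (pixel/noise/shadow fields are used; the seed
#'   field is not consulted -- seed the RNG yourself or use
#'   [simulateDataset()]).
#' @return a [CalibratedCube-class] (mask unset)
#' @export
simulateInstance <- function(signature, wavelengths, cfg) {
  stopifnot(inherits(cfg, "SimConfig"), length(signature) == length(wavelengths))
  H <- cfg$pixels[1]; W <- cfg$pixels[2]
  n <- H * W
  B <- length(signature)
  instScale <- exp(stats::rnorm(1, 0, cfg$illumJitterSd))
  scale <- instScale * exp(stats::rnorm(n, 0, cfg$pixelJitterSd))
  nShadow <- round(cfg$shadowFraction * n)
  if (nShadow > 0) {
    shadowIdx <- sample.int(n, nShadow)
    # rescale so the mean reflectance lands well below the 0.1 cutoff
    scale[shadowIdx] <- stats::runif(nShadow, 0.02, 0.07) / mean(signature)
  }
  eps <- matrix(stats::rnorm(n * B, 0, cfg$noiseSd), n, B)
  refl <- scale %o% signature + eps
  refl <- pmin(pmax(refl, 0), 1.2)
  new("CalibratedCube", values = array(refl, c(H, W, B)),
      wavelengths = as.numeric(wavelengths))
}

#' Simulate a seeded train/test hyperspectral dataset
#'
#' Draws class signatures from `model`, then generates exactly the
#' configured number of training and test instance cubes per class. Fully
#' deterministic under `cfg$seed`. With `rawMode` on, per-dataset dark and
#' white reference cubes are emitted together with raw cubes constructed as
#' `raw = dark + reflectance * (white - dark)`, so that [calibrateCube()]
#' recovers the reflectance exactly up to floating point.
#'
#' @param model a [signatureModel()]; its `nClasses` must equal
#'   `1 + length(cfg$minorityTrain)`.
#' @param cfg a [simConfig()].
#' @return list with `signatures` (C x B), `train` and `test` (each a list
#'   of `cubes`, `labels`, `manifest`), and in raw mode `dark`, `white` and
#'   per-split `rawCubes`
#' @export
simulateDataset <- function(model, cfg) {
  stopifnot(inherits(model, "SignatureModel"), inherits(cfg, "SimConfig"))
  C <- model$nClasses
  if (C != 1L + length(cfg$minorityTrain))
    stop("model$nClasses must equal 1 + length(cfg$minorityTrain)")
  set.seed(cfg$seed)
  sig <- makeSignatures(model)
  trainCounts <- c(cfg$majorityTrain, cfg$minorityTrain)
  genSplit <- function(counts, prefix) {
    labels <- rep(seq_len(C), counts)
    cubes <- vector("list", length(labels))
    ids <- character(length(labels))
    for (i in seq_along(labels)) {
      cubes[[i]] <- simulateInstance(sig[labels[i], ], model$wavelengths, cfg)
      ids[i] <- sprintf("%s_%03d_c%d", prefix, i, labels[i])
    }
    list(cubes = cubes, labels = labels,
         manifest = data.frame(instance_id = ids, label = labels,
                               cube_path = NA_character_,
                               stringsAsFactors = FALSE))
  }
  train <- genSplit(trainCounts, "train")
  test <- genSplit(rep(cfg$testPerClass, C), "test")
  out <- list(signatures = sig, train = train, test = test, config = cfg)
  if (cfg$rawMode) {
    H <- cfg$pixels[1]; W <- cfg$pixels[2]; B <- model$nBands
    dark <- hyperCube(array(100, c(H, W, B)), model$wavelengths)
    white <- hyperCube(array(4000, c(H, W, B)), model$wavelengths)
    toRaw <- function(cube)
      hyperCube(dark@values + cube@values * (white@values - dark@values),
                model$wavelengths)
    out$dark <- dark
    out$white <- white
    out$train$rawCubes <- lapply(train$cubes, toRaw)
    out$test$rawCubes <- lapply(test$cubes, toRaw)
  }
  out
}

#' Convert generated cubes to spectra instances
#'
#' Applies band retention, effective-pixel masking and instance extraction
#' (the same chain as [preprocessManifest()]) to an in-memory list of
#' calibrated cubes, e.g. one split of [simulateDataset()].
#'
#' @param split a list with `cubes`, `labels`, `manifest` as produced by
#'   [simulateDataset()].
#' @param lo,hi retained wavelength interval (nm).
#' @param threshold effective-pixel cutoff.
#' @return list of [SpectraInstance-class]
#' @export
splitToInstances <- function(split, lo = 1000, hi = 1600, threshold = 0.1) {
  bandIdx <- selectBands(split$cubes[[1]]@wavelengths, lo, hi)
  lapply(seq_along(split$cubes), function(i) {
    cube <- split$cubes[[i]]
    setMask(cube) <- effectiveMask(cube, bandIdx, threshold)
    cubeToInstance(cube, bandIdx, label = split$labels[i],
                   id = split$manifest$instance_id[i])
  })
}

#' Write a simulated dataset to disk
#'
#' Writes each cube (ENVI by default, `.rds` container with
#' `format = "rds"`), the train/test manifests as CSV, and a provenance
#' JSON echoing the seed and configuration.
#'
#' @param dataset result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @param format "envi" or "rds".
#' @return invisible list of manifest paths
#' @export
writeDataset <- function(dataset, dir, format = c("envi", "rds")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "envi") ".raw" else ".rds"
  writeSplit <- function(split, name) {
    man <- split$manifest
    for (i in seq_len(nrow(man))) {
      p <- file.path(dir, paste0(man$instance_id[i], ext))
      writeCube(split$cubes[[i]], p)
      man$cube_path[i] <- p
    }
    mp <- file.path(dir, paste0(name, "_manifest.csv"))
    utils::write.csv(man, mp, row.names = FALSE)
    mp
  }
  paths <- list(train = writeSplit(dataset$train, "train"),
                test = writeSplit(dataset$test, "test"))
  prov <- dataset$config
  class(prov) <- NULL
  jsonlite::write_json(list(generator = "ProtoDS::simulateDataset",
                            config = prov),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
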