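#' @import methods
NULL

#' Hyperspectral data cube
#'
#' An H x W x B array of per-pixel spectra together with the band-centre
#' wavelengths. A `HyperCube` holds raw sensor counts (or any uncalibrated
#' intensities); the calibrated counterpart is [CalibratedCube-class].
#'
#' @slot values numeric H x W x B array, non-negative intensities.
#' @slot wavelengths numeric length-B vector of band centres in nanometres,
#'   strictly increasing.
#'
#' @seealso [calibrateCube()], [readENVI()], [writeENVI()]
#' @export
setClass("HyperCube",
  representation(values = "array", wavelengths = "numeric"))

setValidity("HyperCube", function(object) {
  v <- object@values
  wl <- object@wavelengths
  if (length(dim(v)) != 3L)
    return("values must be a 3-dimensional H x W x B array")
  if (any(dim(v) < 1L))
    return("all cube dimensions must be >= 1")
  if (length(wl) != dim(v)[3L])
    return(sprintf("length(wavelengths) [%d] must equal the band count [%d]",
                   length(wl), dim(v)[3L]))
  if (length(wl) > 1L && any(diff(wl) <= 0))
    return("wavelengths must be strictly increasing")
  TRUE
})

#' Calibrated reflectance cube
#'
#' A [HyperCube-class] whose values are dimensionless reflectance obtained by
#' dark/white min-max calibration, plus an optional H x W effective-pixel
#' mask. The mask is empty (0 x 0) until set by [effectiveMask()] /
#' [setMask()].
#'
#' @slot mask logical H x W matrix of effective pixels, or a 0 x 0 matrix
#'   when no mask has been computed yet.
#'
#' @seealso [calibrateCube()], [effectiveMask()], [cubeToInstance()]
#' @export
setClass("CalibratedCube", contains = "HyperCube",
  representation(mask = "matrix"),
  prototype(mask = matrix(logical(0), 0, 0)))

setValidity("CalibratedCube", function(object) {
  m <- object@mask
  if (length(m) == 0L) return(TRUE)
  if (!is.logical(m))
    return("mask must be a logical matrix")
  if (!identical(dim(m), dim(object@values)[1:2]))
    return("mask dimensions must equal the cube's spatial dimensions")
  TRUE
})

#' One physical instance as a matrix of effective-pixel spectra
#'
#' All effective-pixel spectra of a single physical sample (a coffee bean, a
#' dried peel, ...), restricted to the retained bands: an N x D matrix with
#' one row per effective pixel, the integer class label, and the pixel
#' coordinates needed to paint per-pixel results back onto the image plane.
#'
#' @slot instanceId character scalar identifier.
#' @slot label integer class index in 1..C (NA allowed for unlabeled data).
#' @slot spectra numeric N x D matrix, one spectrum per row, all finite.
#' @slot pixelCoords integer N x 2 matrix of (row, col) image coordinates.
#' @slot bandWavelengths numeric length-D retained band centres (nm).
#'
#' @seealso [cubeToInstance()], [classifyInstance()]
#' @export
setClass("SpectraInstance",
  representation(instanceId = "character", label = "integer",
                 spectra = "matrix", pixelCoords = "matrix",
                 bandWavelengths = "numeric"))

setValidity("SpectraInstance", function(object) {
  s <- object@spectra
  if (nrow(s) < 1L) return("an instance must contain at least one spectrum")
  if (!all(is.finite(s))) return("spectra must be finite")
  if (nrow(object@pixelCoords) != nrow(s) || ncol(object@pixelCoords) != 2L)
    return("pixelCoords must be an N x 2 matrix matching spectra rows")
  if (length(object@bandWavelengths) > 0L &&
      length(object@bandWavelengths) != ncol(s))
    return("bandWavelengths length must equal the spectral dimension D")
  if (length(object@label) != 1L)
    return("label must be a single integer (possibly NA)")
  if (!is.na(object@label) && object@label < 1L)
    return("label must be >= 1")
  TRUE
})

#' Embedding network f: R^D -> R^M
#'
#' A stack of blocks, each batch-normalisation -> linear -> leaky-ReLU,
#' mapping a pixel spectrum to an M-dimensional embedding. The first batch
#' norm rescales the D-dimensional input; the first linear layer maps D to
#' the hidden width, subsequent ones hidden to hidden. Parameters live in
#' `params` (per block: `gamma`, `beta`, `runMean`, `runVar`, `W`, `b`).
#'
#' @slot config list as produced by [networkConfig()].
#' @slot params list of per-block parameter lists.
#' @slot step integer; number of optimiser updates applied so far.
#'
#' @seealso [initNetwork()], [embedSpectra()], [pretrainNetwork()]
#' @export
setClass("EmbeddingNetwork",
  representation(config = "list", params = "list", step = "integer"),
  prototype(step = 0L))

setValidity("EmbeddingNetwork", function(object) {
  cfg <- object@config
  if (is.null(cfg$inputDim) || cfg$inputDim < 1L)
    return("config$inputDim must be >= 1")
  if (length(object@params) != cfg$nBlocks)
    return("params must hold one entry per block")
  TRUE
})

#' Class prototypes in the embedding space
#'
#' One M-vector per class, the arithmetic mean of that class's support
#' embeddings. Classification is by softmax over negative distances to these
#' prototypes.
#'
#' @slot classIds integer vector of class labels, one per prototype row.
#' @slot prototypes numeric C x M matrix.
#'
#' @seealso [computePrototypes()], [protoPosteriors()]
#' @export
setClass("PrototypeSet",
  representation(classIds = "integer", prototypes = "matrix"))

setValidity("PrototypeSet", function(object) {
  if (length(object@classIds) != nrow(object@prototypes))
    return("one classId per prototype row required")
  if (anyDuplicated(object@classIds))
    return("classIds must be unique")
  if (!all(is.finite(object@prototypes)))
    return("prototypes must be finite")
  TRUE
})

#' Trained Proto-DS model
#'
#' The result of [trainProtoDS()]: the fine-tuned embedding network, final
#' class prototypes extracted from all training pixel spectra in inference
#' mode, and bookkeeping needed to preprocess and classify new cubes.
#'
#' @slot network an [EmbeddingNetwork-class].
#' @slot prototypes a [PrototypeSet-class].
#' @slot bandWavelengths numeric retained band centres (nm); may be empty.
#' @slot trainingInfo list: configs used, loss traces, ablation flags.
#'
#' @seealso [trainProtoDS()], [classifyInstance()], [saveModel()]
#' @export
setClass("ProtoDSModel",
  representation(network = "EmbeddingNetwork", prototypes = "PrototypeSet",
                 bandWavelengths = "numeric", trainingInfo = "list"))

#' Evaluation report for an imbalanced classification run
#'
#' Confusion matrix plus the imbalance-aware summary metrics: balanced
#' accuracy (mean per-class recall), macro F1, macro one-vs-rest AUROC,
#' macro average precision, and per-class sensitivity/specificity.
#'
#' @slot confusion integer C x C matrix, rows = true class, cols = predicted.
#' @slot metrics named numeric vector (bAcc, macroF1, macroAUROC, macroAP).
#' @slot perClass data.frame with columns class, sensitivity, specificity,
#'   f1, auroc, ap.
#' @slot metadata list of free-form run descriptors (n minority, seed, ...).
#'
#' @seealso [evaluateModel()], [evalReport()]
#' @export
setClass("EvalReport",
  representation(confusion = "matrix", metrics = "numeric",
                 perClass = "data.frame", metadata = "list"))

setValidity("EvalReport", function(object) {
  if (nrow(object@confusion) != ncol(object@confusion))
    return("confusion matrix must be square")
  if (any(object@confusion < 0))
    return("confusion counts must be non-negative")
  ok <- is.finite(object@metrics)
  if (any(object@metrics[ok] < -1e-9 | object@metrics[ok] > 1 + 1e-9))
    return("metrics must be rates in [0, 1]")
  TRUE
})
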