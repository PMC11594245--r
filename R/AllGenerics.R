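#' @rdname HyperCube-class
#' @param object,x a ProtoDS object
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname HyperCube-class
#' @export
setGeneric("cubeValues", function(x) standardGeneric("cubeValues"))

#' @rdname CalibratedCube-class
#' @param x a [CalibratedCube-class]
#' @export
setGeneric("effMask", function(x) standardGeneric("effMask"))

#' @rdname CalibratedCube-class
#' @param value logical H x W matrix
#' @export
setGeneric("setMask<-", function(x, value) standardGeneric("setMask<-"))

#' @rdname SpectraInstance-class
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname SpectraInstance-class
#' @export
setGeneric("instanceLabel", function(x) standardGeneric("instanceLabel"))

#' @rdname SpectraInstance-class
#' @export
setGeneric("instanceId", function(x) standardGeneric("instanceId"))

#' @rdname SpectraInstance-class
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))

#' @rdname PrototypeSet-class
#' @export
setGeneric("prototypeMatrix", function(x) standardGeneric("prototypeMatrix"))

#' @rdname PrototypeSet-class
#' @export
setGeneric("classIds", function(x) standardGeneric("classIds"))

#' @rdname EvalReport-class
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @rdname EvalReport-class
#' @export
setGeneric("reportMetrics", function(x) standardGeneric("reportMetrics"))

#' @rdname EvalReport-class
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

# -- accessors -----------------------------------------------------------

#' @rdname HyperCube-class
#' @export
setMethod("wavelengths", "HyperCube", function(x) x@wavelengths)

#' @rdname HyperCube-class
#' @export
setMethod("cubeValues", "HyperCube", function(x) x@values)

#' @rdname CalibratedCube-class
#' @export
setMethod("effMask", "CalibratedCube", function(x) {
  if (length(x@mask) == 0L)
    stop("no effective-pixel mask set; call effectiveMask() first")
  x@mask
})

#' @rdname CalibratedCube-class
#' @export
setReplaceMethod("setMask", "CalibratedCube", function(x, value) {
  x@mask <- value
  validObject(x)
  x
})

#' Does the cube carry an effective-pixel mask?
#' @param x a [CalibratedCube-class]
#' @return logical scalar
#' @export
hasMask <- function(x) length(x@mask) > 0L

#' @rdname SpectraInstance-class
#' @export
setMethod("spectra", "SpectraInstance", function(x) x@spectra)

#' @rdname SpectraInstance-class
#' @export
setMethod("instanceLabel", "SpectraInstance", function(x) x@label)

#' @rdname SpectraInstance-class
#' @export
setMethod("instanceId", "SpectraInstance", function(x) x@instanceId)

#' @rdname SpectraInstance-class
#' @export
setMethod("pixelCoords", "SpectraInstance", function(x) x@pixelCoords)

#' @rdname PrototypeSet-class
#' @export
setMethod("prototypeMatrix", "PrototypeSet", function(x) x@prototypes)

#' @rdname PrototypeSet-class
#' @export
setMethod("classIds", "PrototypeSet", function(x) x@classIds)

#' @rdname EvalReport-class
#' @export
setMethod("confusionCounts", "EvalReport", function(x) x@confusion)

#' @rdname EvalReport-class
#' @export
setMethod("reportMetrics", "EvalReport", function(x) x@metrics)

#' @rdname EvalReport-class
#' @export
setMethod("perClassMetrics", "EvalReport", function(x) x@perClass)

# -- show methods --------------------------------------------------------

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s: %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              class(object), d[1], d[2], d[3],
              min(object@wavelengths), max(object@wavelengths)))
  if (is(object, "CalibratedCube") && hasMask(object))
    cat(sprintf("  effective pixels: %d / %d\n",
                sum(object@mask), length(object@mask)))
})

setMethod("show", "SpectraInstance", function(object) {
  cat(sprintf("SpectraInstance '%s': %d effective-pixel spectra x %d bands, label %s\n",
              object@instanceId, nrow(object@spectra), ncol(object@spectra),
              ifelse(is.na(object@label), "<NA>", object@label)))
})

setMethod("show", "EmbeddingNetwork", function(object) {
  cfg <- object@config
  cat(sprintf("EmbeddingNetwork: %d -> %s -> %d (%d blocks, BN->Linear->LeakyReLU), %d optimiser steps\n",
              cfg$inputDim, cfg$hiddenDim, cfg$embeddingDim, cfg$nBlocks,
              object@step))
})

setMethod("show", "PrototypeSet", function(object) {
  cat(sprintf("PrototypeSet: %d classes (%s), embedding dim %d\n",
              nrow(object@prototypes),
              paste(object@classIds, collapse = ", "),
              ncol(object@prototypes)))
})

setMethod("show", "ProtoDSModel", function(object) {
  cat("ProtoDSModel\n")
  show(object@network)
  show(object@prototypes)
  ti <- object@trainingInfo
  if (!is.null(ti$ablation))
    cat(sprintf("  variant: %s\n", ti$ablation))
})

setMethod("show", "EvalReport", function(object) {
  m <- object@metrics
  cat(sprintf("EvalReport (%d classes, %d instances)\n",
              nrow(object@confusion), sum(object@confusion)))
  cat(sprintf("  B.Acc %.4f | M.F1 %.4f | M.AUROC %s | M.AP %s\n",
              m[["bAcc"]], m[["macroF1"]],
              ifelse(is.na(m[["macroAUROC"]]), "NA", sprintf("%.4f", m[["macroAUROC"]])),
              ifelse(is.na(m[["macroAP"]]), "NA", sprintf("%.4f", m[["macroAP"]]))))
})
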