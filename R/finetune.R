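# Step 2: episodic supervised fine-tuning with the combined Dice +
# cross-entropy objective, and end-to-end two-step training.

#' One-hot encode labels
#'
#' @param labels integer vector in `classes`.
#' @param classes class ids defining the column order.
#' @return N x C 0/1 matrix
#' @export
oneHot <- function(labels, classes = sort(unique(labels))) {
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  colnames(Y) <- classes
  Y
}

#' Multiclass soft Dice loss
#'
#' Per class c: `1 - 2 * sum_i(p_ic y_ic) / (sum_i p_ic^2 + sum_i y_ic^2)`,
#' averaged over the C classes. The second factor is the soft
#' Dice-Sorensen coefficient (DSC); for hard 0/1 predictions the per-class
#' DSC equals the one-vs-rest F1 score, which is why minimising this loss
#' directly counters majority-class domination: true negatives never enter.
#' A class whose denominator is exactly 0 (absent from both predictions and
#' truth) contributes 0.
#'
#' @param probs N x C matrix of predicted probabilities (rows sum to 1).
#' @param onehot N x C 0/1 ground-truth matrix.
#' @return scalar in \[0, 1\]
#' @examples
#' p <- matrix(c(0.5, 0.5), 1)
#' y <- matrix(c(1, 0), 1)
#' diceLoss(p, y)  # (0.2 + 1) / 2 = 0.6
#' @export
diceLoss <- function(probs, onehot) {
  stopifnot(identical(dim(probs), dim(onehot)))
  if (nrow(probs) < 1L) stop("input error: empty prediction batch")
  num <- 2 * colSums(probs * onehot)
  den <- colSums(probs^2) + colSums(onehot^2)
  terms <- ifelse(den == 0, 0, 1 - num / den)
  mean(terms)
}

# gradient of diceLoss w.r.t. probs; a class absent from the batch truth
# has S_c = 0 identically, so its term is constant in p and its gradient
# exactly 0 (computing it as 0/den^2 would NaN when den underflows)
diceLossGrad <- function(probs, onehot) {
  C <- ncol(probs)
  S <- colSums(probs * onehot)
  den <- colSums(probs^2) + colSums(onehot^2)
  g <- matrix(0, nrow(probs), C)
  nz <- colSums(onehot) > 0
  if (any(nz)) {
    # d/dp_ic [1 - 2 S_c / D_c] = -2 (y_ic D_c - 2 p_ic S_c) / D_c^2
    Yn <- onehot[, nz, drop = FALSE]
    Pn <- probs[, nz, drop = FALSE]
    g[, nz] <- -2 * sweep(sweep(Yn, 2L, den[nz], `*`) - 2 * Pn %*%
                            diag(S[nz], nrow = sum(nz)),
                          2L, den[nz]^2, `/`)
  }
  g / C
}

#' Combined cross-entropy + Dice objective
#'
#' `lambdaCE * mean(-log p_true) + lambdaD * diceLoss(probs, onehot)`.
#' With `lambdaD = 0` this reduces to the original prototypical-network
#' objective (negative log probability of the true class). Probabilities
#' are clamped at 1e-12 before the log.
#'
#' @param probs N x C predicted probabilities.
#' @param onehot N x C one-hot ground truth.
#' @param lambdaCE,lambdaD non-negative loss weights (not both 0).
#' @return scalar loss (attributes `ce` and `dice` carry the components)
#' @export
combinedLoss <- function(probs, onehot, lambdaCE = 1, lambdaD = 1) {
  stopifnot(lambdaCE >= 0, lambdaD >= 0, lambdaCE + lambdaD > 0)
  if (nrow(probs) < 1L) stop("input error: empty prediction batch")
  pTrue <- rowSums(probs * onehot)
  ce <- mean(-log(pmax(pTrue, 1e-12)))
  dc <- diceLoss(probs, onehot)
  structure(lambdaCE * ce + lambdaD * dc, ce = ce, dice = dc)
}

#' Fine-tuning configuration
#'
#' @param epochs fine-tuning epochs.
#' @param lr Adam learning rate.
#' @param supportFraction fraction of each class's training instances
#'   subsampled per epoch to extract the prototypes (minimum 1 instance).
#' @param lambdaCE,lambdaD weights of the cross-entropy and Dice terms.
#' @param batchSize query pixel spectra per optimiser step.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return config list of class `FinetuneConfig`
#' @export
finetuneConfig <- function(epochs = 50L, lr = 1e-4, supportFraction = 0.5,
                           lambdaCE = 1, lambdaD = 1, batchSize = 256L,
                           seed = NULL) {
  stopifnot(epochs >= 1, lr > 0, supportFraction > 0, supportFraction <= 1,
            lambdaCE >= 0, lambdaD >= 0, lambdaCE + lambdaD > 0,
            batchSize >= 1)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 supportFraction = supportFraction, lambdaCE = lambdaCE,
                 lambdaD = lambdaD, batchSize = as.integer(batchSize),
                 seed = seed),
            class = "FinetuneConfig")
}

# gradient of the combined loss w.r.t. the distance logits z (N x C),
# where probs = softmax(z)
combinedLossGradLogits <- function(probs, onehot, lambdaCE, lambdaD) {
  N <- nrow(probs)
  dZ <- matrix(0, N, ncol(probs))
  if (lambdaCE > 0)
    dZ <- dZ + lambdaCE * (probs - onehot) / N
  if (lambdaD > 0) {
    gP <- diceLossGrad(probs, onehot)
    # softmax Jacobian: dz = p * (g - rowSums(g * p))
    dZ <- dZ + lambdaD * probs * (gP - rowSums(gP * probs))
  }
  dZ
}

# gradient of logits w.r.t. query embeddings for fixed prototypes
logitsGradEmb <- function(emb, protoMat, dZ, distance) {
  if (distance == "euclidean") {
    d2 <- pairwiseSqDist(emb, protoMat)
    d <- sqrt(pmax(d2, 1e-12))
    # z_k = -d_k ; dz_k/de = (c_k - e)/d_k
    W <- dZ / d
    W %*% protoMat - emb * rowSums(W)
  } else {
    # z_k = -||e - c_k||^2 ; dz_k/de = 2 (c_k - e)
    2 * (dZ %*% protoMat - emb * rowSums(dZ))
  }
}

#' Episodic fine-tuning of a (pre)trained embedding network
#'
#' Every epoch: a random support subset of each class's instances
#' (`supportFraction`, at least one instance; a single-instance minority
#' class is always fully in support) is embedded and averaged into
#' per-class prototypes; then all training pixel spectra serve as queries,
#' processed in mini-batches, each yielding softmax-distance posteriors
#' against the epoch's prototypes and one Adam update of the combined
#' Dice + cross-entropy loss. Prototypes are treated as constants within an
#' epoch (stop-gradient); batch norm runs in training mode throughout.
#'
#' @param net an [EmbeddingNetwork-class].
#' @param instances list of labelled [SpectraInstance-class].
#' @param cfg a [finetuneConfig()].
#' @return list with `net` and `log` (data.frame: epoch, ce, dice, total)
#' @export
finetuneNetwork <- function(net, instances, cfg = finetuneConfig()) {
  force(net); force(instances)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  labels <- vapply(instances, instanceLabel, integer(1))
  if (anyNA(labels)) stop("support error: all training instances need labels")
  classes <- sort(unique(labels))
  distance <- net@config$distance
  pool <- poolFromInstances(instances)
  pixLabels <- labels[pool$instOf]
  state <- adamInit(net)
  log <- data.frame(epoch = seq_len(cfg$epochs), ce = NA_real_,
                    dice = NA_real_, total = NA_real_)
  for (ep in seq_len(cfg$epochs)) {
    supIdx <- unlist(lapply(classes, function(k) {
      ks <- which(labels == k)
      nSup <- max(1L, round(cfg$supportFraction * length(ks)))
      if (length(ks) == 1L) ks else sample(ks, nSup)
    }))
    supRows <- which(pool$instOf %in% supIdx)
    supFwd <- networkForward(net, pool$X[supRows, , drop = FALSE], train = TRUE)
    net <- supFwd$net
    protos <- computePrototypes(supFwd$out, pixLabels[supRows], classes)
    ord <- sample(nrow(pool$X))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batchSize))
    ceAcc <- dcAcc <- totAcc <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      rows <- batches[[bi]]
      fwd <- networkForward(net, pool$X[rows, , drop = FALSE], train = TRUE)
      net <- fwd$net
      emb <- fwd$out
      Z <- distLogits(emb, protos@prototypes, distance)
      P <- softmaxRows(Z)
      Y <- oneHot(pixLabels[rows], classes)
      loss <- combinedLoss(P, Y, cfg$lambdaCE, cfg$lambdaD)
      if (!is.finite(loss))
        stop(sprintf("training error: non-finite loss at epoch %d", ep))
      dZ <- combinedLossGradLogits(P, Y, cfg$lambdaCE, cfg$lambdaD)
      dEmb <- logitsGradEmb(emb, protos@prototypes, dZ, distance)
      grads <- networkBackward(net, fwd, dEmb)
      upd <- adamStep(net, grads, state, lr = cfg$lr)
      net <- upd$net; state <- upd$state
      ceAcc[bi] <- attr(loss, "ce"); dcAcc[bi] <- attr(loss, "dice")
      totAcc[bi] <- as.numeric(loss)
    }
    log$ce[ep] <- mean(ceAcc); log$dice[ep] <- mean(dcAcc)
    log$total[ep] <- mean(totAcc)
  }
  list(net = net, log = log)
}

#' Two-step Proto-DS training
#'
#' Step 1 (optional): instance-wise spectral contrastive pretraining on the
#' unlabeled pixel spectra. Step 2: episodic fine-tuning with the combined
#' Dice + cross-entropy objective (Dice optional). Finally the class
#' prototypes are extracted from all training pixel spectra with the fully
#' trained network in inference mode. The four ablation variants are
#' selected by the two flags: full Proto-DS, w/o Dice, w/o SSL, and the
#' vanilla prototypical network (w/o SSL + Dice).
#'
#' @param instances labelled training [SpectraInstance-class] list.
#' @param netCfg a [networkConfig()]; `NULL` derives the input dimension
#'   from the data and uses the architecture defaults.
#' @param sslCfg an [sslConfig()].
#' @param ftCfg a [finetuneConfig()].
#' @param useSSL run the contrastive pretraining step.
#' @param useDice keep the Dice term in the fine-tuning objective (when
#'   FALSE, `lambdaD` is forced to 0).
#' @param seed master seed for initialisation, pretraining and fine-tuning.
#' @return a [ProtoDSModel-class]
#' @export
trainProtoDS <- function(instances, netCfg = NULL, sslCfg = sslConfig(),
                         ftCfg = finetuneConfig(), useSSL = TRUE,
                         useDice = TRUE, seed = 1L) {
  stopifnot(length(instances) >= 1L)
  D <- ncol(spectra(instances[[1]]))
  if (is.null(netCfg)) netCfg <- networkConfig(D)
  if (netCfg$inputDim != D)
    stop(sprintf("input error: network expects D = %d but spectra have D = %d",
                 netCfg$inputDim, D))
  if (!is.null(seed)) set.seed(seed)
  net <- initNetwork(netCfg)
  sslTrace <- numeric(0)
  if (useSSL) {
    pre <- pretrainNetwork(net, instances, sslCfg)
    net <- pre$net
    sslTrace <- pre$lossTrace
  }
  if (!useDice) ftCfg$lambdaD <- 0
  ft <- finetuneNetwork(net, instances, ftCfg)
  net <- ft$net
  labels <- vapply(instances, instanceLabel, integer(1))
  pool <- poolFromInstances(instances)
  emb <- embedSpectra(net, pool$X, train = FALSE)
  protos <- computePrototypes(emb, labels[pool$instOf])
  variant <- if (useSSL && useDice) "full"
             else if (useSSL) "no_dice"
             else if (useDice) "no_ssl"
             else "no_ssl_no_dice"
  new("ProtoDSModel", network = net, prototypes = protos,
      bandWavelengths = instances[[1]]@bandWavelengths,
      trainingInfo = list(ablation = variant, seed = seed,
                          sslLossTrace = sslTrace, finetuneLog = ft$log,
                          sslConfig = unclass(sslCfg),
                          finetuneConfig = unclass(ftCfg)))
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS serialisation of the [ProtoDSModel-class]
#' (opaque parameter blob) plus a human-readable JSON sidecar
#' (`<path>.json`) echoing the architecture, class ids and prototype
#' matrix.
#'
#' @param model a [ProtoDSModel-class].
#' @param path checkpoint path (conventionally `.rds`).
#' @return `loadModel()` returns the model; `saveModel()` the path,
#'   invisibly
#' @name model-io
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "ProtoDSModel"))
  saveRDS(model, path)
  side <- list(config = model@network@config,
               classIds = model@prototypes@classIds,
               prototypes = model@prototypes@prototypes,
               bandWavelengths = model@bandWavelengths,
               variant = model@trainingInfo$ablation)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname model-io
#' @export
loadModel <- function(path) {
  m <- readRDS(path)
  if (!is(m, "ProtoDSModel"))
    stop(sprintf("format error: '%s' does not contain a ProtoDSModel", path))
  m
}
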