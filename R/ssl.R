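# Step 1: instance-wise spectral contrastive pretraining. The pretext task
# never reads class labels: two effective-pixel spectra of the same physical
# instance form a positive pair, pixels of other instances are negatives.

#' Self-supervised pretraining configuration
#'
#' @param B negative-set size per query.
#' @param tau softmax temperature of the contrastive loss.
#' @param epochs training epochs (one pass over all instances as query
#'   sources per epoch).
#' @param lr Adam learning rate.
#' @param instancesPerStep instances (hence queries) per optimiser step.
#' @param similarity `"neg_sq_euclidean"` (default) or `"cosine"`; the
#'   similarity whose softmax the loss normalises.
#' @param negativesIncludeOwnInstance when TRUE negatives are drawn from the
#'   whole pixel pool including the query's own instance; the default
#'   excludes it, matching the hypothesis that same-instance spectra should
#'   embed nearby.
#' @param positivePoolSize number of same-instance pixels pooled (mean
#'   embedding) into the positive key; 1 uses a single pixel.
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return config list of class `SSLConfig`
#' @export
sslConfig <- function(B = 16L, tau = 1, epochs = 200L, lr = 1e-4,
                      instancesPerStep = 16L,
                      similarity = c("neg_sq_euclidean", "cosine"),
                      negativesIncludeOwnInstance = FALSE,
                      positivePoolSize = 1L, seed = NULL) {
  stopifnot(B >= 1, tau > 0, epochs >= 0, lr > 0, instancesPerStep >= 1,
            positivePoolSize >= 1)
  structure(list(B = as.integer(B), tau = tau, epochs = as.integer(epochs),
                 lr = lr, instancesPerStep = as.integer(instancesPerStep),
                 similarity = match.arg(similarity),
                 negativesIncludeOwnInstance = isTRUE(negativesIncludeOwnInstance),
                 positivePoolSize = as.integer(positivePoolSize),
                 seed = seed),
            class = "SSLConfig")
}

poolFromInstances <- function(instances) {
  X <- do.call(rbind, lapply(instances, spectra))
  instOf <- rep(seq_along(instances),
                vapply(instances, function(i) nrow(spectra(i)), integer(1)))
  list(X = X, instOf = instOf)
}

#' Sample one contrastive batch
#'
#' For each sampled instance: a query pixel and a distinct positive pixel
#' (or `positivePoolSize` positive pixels) from the same instance, plus `B`
#' negative pixels drawn uniformly from the pixel pool of the other
#' instances (or the whole pool, per the config). Class labels are never
#' consulted. Instances with a single effective pixel are skipped with a
#' warning.
#'
#' @param instances list of [SpectraInstance-class].
#' @param cfg an [sslConfig()].
#' @param queryIdx integer indices of the instances to use as query sources
#'   (default: all).
#' @return list with matrices `query`, `pos` (stacked positive-pool rows),
#'   `neg` (nq*B x D, grouped by query), `queryInstance` indices, and
#'   `posPerQuery`
#' @export
sampleContrastiveBatch <- function(instances, cfg = sslConfig(),
                                   queryIdx = seq_along(instances)) {
  pool <- poolFromInstances(instances)
  sizes <- vapply(instances, function(i) nrow(spectra(i)), integer(1))
  usable <- queryIdx[sizes[queryIdx] >= 2L]
  if (length(usable) < length(queryIdx))
    warning(sprintf("skipped %d instance(s) with fewer than 2 effective pixels",
                    length(queryIdx) - length(usable)))
  if (length(instances) < 2L)
    stop("dataset error: contrastive pretraining needs at least 2 instances")
  if (length(usable) < 1L)
    stop("dataset error: no usable query instances in this batch")
  pp <- cfg$positivePoolSize
  qRows <- integer(length(usable)); posRows <- integer(length(usable) * pp)
  negRows <- integer(length(usable) * cfg$B)
  for (j in seq_along(usable)) {
    i <- usable[j]
    local <- which(pool$instOf == i)
    pick <- sample(local, min(1L + pp, length(local)))
    qRows[j] <- pick[1L]
    posPick <- pick[-1L]
    if (length(posPick) < pp)  # tiny instance: reuse positives
      posPick <- sample(rep(posPick, length.out = pp))
    posRows[(j - 1L) * pp + seq_len(pp)] <- posPick
    negPool <- if (cfg$negativesIncludeOwnInstance) seq_len(nrow(pool$X))
               else which(pool$instOf != i)
    negRows[(j - 1L) * cfg$B + seq_len(cfg$B)] <-
      sample(negPool, cfg$B, replace = length(negPool) < cfg$B)
  }
  list(query = pool$X[qRows, , drop = FALSE],
       pos = pool$X[posRows, , drop = FALSE],
       neg = pool$X[negRows, , drop = FALSE],
       queryInstance = pool$instOf[qRows], posPerQuery = pp)
}

simPair <- function(A, Bm, similarity) {
  # rowwise similarity between matched rows of A and Bm
  if (similarity == "cosine") {
    rowSums(A * Bm) / (sqrt(rowSums(A^2)) * sqrt(rowSums(Bm^2)))
  } else {
    -rowSums((A - Bm)^2)
  }
}

#' Instance-wise contrastive (InfoNCE) loss
#'
#' `-log[ exp(s+ / tau) / (exp(s+ / tau) + sum_j exp(s-_j / tau)) ]`, where
#' `s` is the similarity between embeddings (negative squared Euclidean
#' distance by default) and the sum runs over the B negatives. Computed in
#' log-sum-exp stabilised form. Vectorised over queries; returns the mean.
#'
#' @param qEmb query embedding: M-vector or N x M matrix.
#' @param posEmb positive-key embedding(s), same shape as `qEmb`.
#' @param negEmb negative embeddings: B x M matrix for a single query, or
#'   (N*B) x M grouped by query.
#' @param tau temperature, > 0.
#' @param similarity `"neg_sq_euclidean"` or `"cosine"`.
#' @return mean loss (scalar, >= 0)
#' @examples
#' # one negative at the same similarity as the positive: loss = log(2)
#' contrastiveLoss(c(0, 0), c(1, 0), matrix(c(1, 0), 1), tau = 1)
#' @export
contrastiveLoss <- function(qEmb, posEmb, negEmb, tau = 1,
                            similarity = c("neg_sq_euclidean", "cosine")) {
  similarity <- match.arg(similarity)
  stopifnot(tau > 0)
  if (is.null(dim(qEmb))) qEmb <- matrix(qEmb, nrow = 1L)
  if (is.null(dim(posEmb))) posEmb <- matrix(posEmb, nrow = 1L)
  nq <- nrow(qEmb)
  if (!all(is.finite(qEmb)) || !all(is.finite(posEmb)) ||
      !all(is.finite(negEmb)))
    stop("numeric error: non-finite embeddings in contrastive loss")
  B <- nrow(negEmb) / nq
  stopifnot(B == round(B), B >= 1)
  sPos <- simPair(qEmb, posEmb, similarity)
  qRep <- qEmb[rep(seq_len(nq), each = B), , drop = FALSE]
  sNeg <- matrix(simPair(qRep, negEmb, similarity), nq, B, byrow = TRUE)
  a <- cbind(sPos, sNeg) / tau
  amax <- apply(a, 1L, max)
  lse <- amax + log(rowSums(exp(a - amax)))
  mean(lse - a[, 1L])
}

# loss + gradients w.r.t. the three embedding groups (mean over queries)
contrastiveLossGrad <- function(qEmb, posEmb, negEmb, tau, similarity,
                                posPerQuery = 1L) {
  nq <- nrow(qEmb)
  B <- nrow(negEmb) / nq
  pp <- posPerQuery
  # positive key = mean embedding of the positive pool
  key <- if (pp == 1L) posEmb else {
    grp <- rep(seq_len(nq), each = pp)
    rowsum(posEmb, grp) / pp
  }
  sPos <- simPair(qEmb, key, similarity)
  qRep <- qEmb[rep(seq_len(nq), each = B), , drop = FALSE]
  sNeg <- matrix(simPair(qRep, negEmb, similarity), nq, B, byrow = TRUE)
  a <- cbind(sPos, sNeg) / tau
  amax <- apply(a, 1L, max)
  E <- exp(a - amax)
  sm <- E / rowSums(E)
  loss <- mean((amax + log(rowSums(E))) - a[, 1L])
  # d loss / d a: (softmax - e1)/nq ; then through s = a * tau
  W <- sm; W[, 1L] <- W[, 1L] - 1
  W <- W / (nq * tau)
  if (similarity == "cosine") {
    gradPair <- function(Am, Bm, w) {
      na <- sqrt(rowSums(Am^2)); nb <- sqrt(rowSums(Bm^2))
      cosv <- rowSums(Am * Bm) / (na * nb)
      dA <- (Bm / (na * nb) - Am * (cosv / na^2)) * w
      dB <- (Am / (na * nb) - Bm * (cosv / nb^2)) * w
      list(dA = dA, dB = dB)
    }
  } else {
    gradPair <- function(Am, Bm, w) {
      diff <- Am - Bm
      list(dA = -2 * diff * w, dB = 2 * diff * w)
    }
  }
  gp <- gradPair(qEmb, key, W[, 1L])
  dQ <- gp$dA
  dKey <- gp$dB
  wNeg <- as.vector(t(W[, -1L, drop = FALSE]))  # grouped by query
  gn <- gradPair(qRep, negEmb, wNeg)
  dQ <- dQ + rowsum(gn$dA, rep(seq_len(nq), each = B))
  dNeg <- gn$dB
  dPos <- if (pp == 1L) dKey
          else dKey[rep(seq_len(nq), each = pp), , drop = FALSE] / pp
  list(loss = loss, dQ = dQ, dPos = dPos, dNeg = dNeg)
}

#' Contrastive pretraining of the embedding network
#'
#' Optimises the instance-wise contrastive loss with Adam over resampled
#' batches: each epoch visits every training instance once as a query
#' source, in chunks of `instancesPerStep` instances per optimiser step.
#' Batch norm runs in training mode (batch statistics, running estimates
#' updated). Labels are never consulted.
#'
#' @param net an [EmbeddingNetwork-class].
#' @param instances list of [SpectraInstance-class] (labels ignored).
#' @param cfg an [sslConfig()].
#' @return list with `net` (trained network) and `lossTrace` (mean loss per
#'   epoch)
#' @export
pretrainNetwork <- function(net, instances, cfg = sslConfig()) {
  force(net)   # evaluate before seeding so inline constructors cannot
  force(cfg)   # perturb the training RNG stream
  if (length(instances) < 2L)
    stop("dataset error: contrastive pretraining needs at least 2 instances")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (cfg$epochs == 0L) return(list(net = net, lossTrace = numeric(0)))
  sizes <- vapply(instances, function(i) nrow(spectra(i)), integer(1))
  usableAll <- which(sizes >= 2L)
  if (length(usableAll) < length(instances))
    warning(sprintf("skipped %d instance(s) with fewer than 2 effective pixels",
                    length(instances) - length(usableAll)))
  if (length(usableAll) < 2L)
    stop("dataset error: fewer than 2 instances with >= 2 effective pixels")
  state <- adamInit(net)
  lossTrace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(usableAll)
    steps <- split(ord, ceiling(seq_along(ord) / cfg$instancesPerStep))
    stepLoss <- numeric(length(steps))
    for (si in seq_along(steps)) {
      batch <- sampleContrastiveBatch(instances, cfg, queryIdx = steps[[si]])
      nq <- nrow(batch$query)
      pp <- batch$posPerQuery
      Xb <- rbind(batch$query, batch$pos, batch$neg)
      fwd <- networkForward(net, Xb, train = TRUE)
      net <- fwd$net   # running stats updated
      emb <- fwd$out
      qE <- emb[seq_len(nq), , drop = FALSE]
      pE <- emb[nq + seq_len(nq * pp), , drop = FALSE]
      nE <- emb[nq * (1L + pp) + seq_len(nq * cfg$B), , drop = FALSE]
      lg <- contrastiveLossGrad(qE, pE, nE, cfg$tau, cfg$similarity, pp)
      if (!is.finite(lg$loss))
        stop(sprintf("training error: non-finite contrastive loss at epoch %d", ep))
      dEmb <- rbind(lg$dQ, lg$dPos, lg$dNeg)
      grads <- networkBackward(net, fwd, dEmb)
      upd <- adamStep(net, grads, state, lr = cfg$lr)
      net <- upd$net; state <- upd$state
      stepLoss[si] <- lg$loss
    }
    lossTrace[ep] <- mean(stepLoss)
  }
  list(net = net, lossTrace = lossTrace)
}
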