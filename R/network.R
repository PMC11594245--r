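# Embedding network internals: stacked BatchNorm -> Linear -> LeakyReLU
# blocks with a hand-written backward pass and Adam optimiser. Written in
# base R on BLAS matrix ops; batch-norm follows the usual convention
# (biased variance for normalisation, unbiased for the running estimate,
# momentum 0.1, eps 1e-5).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Embedding network configuration
#'
#' Architecture of the spectral embedding network: `nBlocks` stacked blocks
#' of batch normalisation, a fully connected layer and a leaky-ReLU
#' activation. The batch norm sits first in every block so the raw
#' D-dimensional reflectance spectrum is rescaled before the first linear
#' layer; the first linear layer maps D to `hiddenDim`, later ones
#' `hiddenDim` to `hiddenDim`. The embedding dimension M equals `hiddenDim`.
#'
#' @param inputDim spectral dimension D (retained band count).
#' @param hiddenDim hidden width (and embedding dimension M).
#' @param nBlocks number of blocks.
#' @param negSlope leaky-ReLU negative slope.
#' @param distance distance used in the softmax-distance classifier:
#'   `"squared_euclidean"` (default) or `"euclidean"`.
#' @return config list
#' @export
networkConfig <- function(inputDim, hiddenDim = 256L, nBlocks = 4L,
                          negSlope = 0.01,
                          distance = c("squared_euclidean", "euclidean")) {
  stopifnot(inputDim >= 1, hiddenDim >= 1, nBlocks >= 1, negSlope >= 0)
  list(inputDim = as.integer(inputDim), hiddenDim = as.integer(hiddenDim),
       nBlocks = as.integer(nBlocks), embeddingDim = as.integer(hiddenDim),
       negSlope = negSlope, distance = match.arg(distance))
}

#' Initialise an embedding network
#'
#' He-style Gaussian initialisation of the linear weights
#' (sd = sqrt(2 / fanIn)), zero biases; batch-norm gain 1, shift 0, running
#' mean 0, running variance 1. Deterministic under `seed`.
#'
#' @param config a [networkConfig()].
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return an [EmbeddingNetwork-class]
#' @export
initNetwork <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- vector("list", config$nBlocks)
  for (b in seq_len(config$nBlocks)) {
    din <- if (b == 1L) config$inputDim else config$hiddenDim
    dout <- config$hiddenDim
    params[[b]] <- list(
      gamma = rep(1, din), beta = rep(0, din),
      runMean = rep(0, din), runVar = rep(1, din),
      W = matrix(stats::rnorm(din * dout, 0, sqrt(2 / din)), din, dout),
      b = rep(0, dout))
  }
  new("EmbeddingNetwork", config = config, params = params, step = 0L)
}

# forward pass; train = TRUE uses batch statistics and (optionally) updates
# running estimates; returns the output plus the cache needed for backward.
networkForward <- function(net, X, train = FALSE, updateRunning = train) {
  cfg <- net@config
  if (ncol(X) != cfg$inputDim)
    stop(sprintf("input error: spectra have %d columns, network expects %d",
                 ncol(X), cfg$inputDim))
  params <- net@params
  caches <- vector("list", cfg$nBlocks)
  A <- X
  N <- nrow(X)
  for (bi in seq_len(cfg$nBlocks)) {
    p <- params[[bi]]
    if (train) {
      mu <- colMeans(A)
      ctr <- sweep(A, 2L, mu)
      varb <- colMeans(ctr^2)             # biased, used for normalisation
      if (updateRunning) {
        varu <- if (N > 1L) varb * N / (N - 1L) else varb
        p$runMean <- (1 - BN_MOMENTUM) * p$runMean + BN_MOMENTUM * mu
        p$runVar <- (1 - BN_MOMENTUM) * p$runVar + BN_MOMENTUM * varu
        params[[bi]] <- p
      }
    } else {
      mu <- p$runMean
      ctr <- sweep(A, 2L, mu)
      varb <- p$runVar
    }
    invStd <- 1 / sqrt(varb + BN_EPS)
    xhat <- sweep(ctr, 2L, invStd, `*`)
    bnOut <- sweep(sweep(xhat, 2L, p$gamma, `*`), 2L, p$beta, `+`)
    Z <- bnOut %*% p$W
    Z <- sweep(Z, 2L, p$b, `+`)
    A2 <- ifelse(Z > 0, Z, cfg$negSlope * Z)
    caches[[bi]] <- list(xhat = xhat, invStd = invStd, bnOut = bnOut, Z = Z)
    A <- A2
  }
  net@params <- params
  list(out = A, caches = caches, net = net, train = train)
}

# backward pass for dLoss/dOut; returns per-block gradients (and dX).
networkBackward <- function(net, fwd, dOut) {
  cfg <- net@config
  params <- fwd$net@params
  grads <- vector("list", cfg$nBlocks)
  dA <- dOut
  for (bi in rev(seq_len(cfg$nBlocks))) {
    p <- params[[bi]]
    cc <- fwd$caches[[bi]]
    dZ <- dA * ifelse(cc$Z > 0, 1, cfg$negSlope)
    gW <- crossprod(cc$bnOut, dZ)
    gb <- colSums(dZ)
    dBnOut <- tcrossprod(dZ, p$W)
    gGamma <- colSums(dBnOut * cc$xhat)
    gBeta <- colSums(dBnOut)
    dXhat <- sweep(dBnOut, 2L, p$gamma, `*`)
    if (fwd$train) {
      N <- nrow(dXhat)
      # full batch-norm backward through batch statistics
      t1 <- N * dXhat
      t2 <- matrix(colSums(dXhat), N, ncol(dXhat), byrow = TRUE)
      t3 <- cc$xhat * matrix(colSums(dXhat * cc$xhat), N, ncol(dXhat),
                             byrow = TRUE)
      dA <- sweep(t1 - t2 - t3, 2L, cc$invStd / N, `*`)
    } else {
      dA <- sweep(dXhat, 2L, cc$invStd, `*`)
    }
    grads[[bi]] <- list(gamma = gGamma, beta = gBeta, W = gW, b = gb)
  }
  list(blocks = grads, dX = dA)
}

#' Embed pixel spectra
#'
#' Maps an N x D matrix of spectra to N x M embeddings. In inference mode
#' (the default) batch normalisation uses the stored running statistics, so
#' the embedding of a spectrum does not depend on what else is in the
#' batch; training mode uses batch statistics.
#'
#' @param net an [EmbeddingNetwork-class].
#' @param X numeric N x D matrix (a bare vector is taken as one spectrum).
#' @param train logical; use batch statistics (TRUE) or running statistics.
#' @return N x M embedding matrix
#' @export
embedSpectra <- function(net, X, train = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  networkForward(net, X, train = train, updateRunning = FALSE)$out
}

# ---- Adam --------------------------------------------------------------

adamInit <- function(net) {
  lapply(net@params, function(p)
    list(m = lapply(p[c("gamma", "beta", "W", "b")],
                    function(x) x * 0),
         v = lapply(p[c("gamma", "beta", "W", "b")],
                    function(x) x * 0)))
}

adamStep <- function(net, grads, state, lr = 1e-4, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  net@step <- net@step + 1L
  t <- net@step
  for (bi in seq_along(net@params)) {
    for (nm in c("gamma", "beta", "W", "b")) {
      g <- grads$blocks[[bi]][[nm]]
      st <- state[[bi]]
      st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
      st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
      mhat <- st$m[[nm]] / (1 - beta1^t)
      vhat <- st$v[[nm]] / (1 - beta2^t)
      net@params[[bi]][[nm]] <- net@params[[bi]][[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[bi]] <- st
    }
  }
  list(net = net, state = state)
}
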