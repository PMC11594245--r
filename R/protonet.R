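#' Class prototypes from labelled embeddings
#'
#' The prototype of class k is the arithmetic mean of the embeddings of
#' that class's support samples.
#'
#' @param embeddings numeric N x M matrix.
#' @param labels integer vector of length N.
#' @param classes optional integer vector of required classes; an empty
#'   class raises a support error.
#' @return a [PrototypeSet-class]
#' @export
computePrototypes <- function(embeddings, labels, classes = sort(unique(labels))) {
  stopifnot(nrow(embeddings) == length(labels))
  missing <- setdiff(classes, labels)
  if (length(missing) > 0L)
    stop(sprintf("support error: no support samples for class(es) %s",
                 paste(missing, collapse = ", ")))
  protos <- matrix(0, length(classes), ncol(embeddings))
  for (j in seq_along(classes))
    protos[j, ] <- colMeans(embeddings[labels == classes[j], , drop = FALSE])
  new("PrototypeSet", classIds = as.integer(classes), prototypes = protos)
}

# squared Euclidean distances between rows of Q (n x M) and rows of P (C x M)
pairwiseSqDist <- function(Q, P) {
  qn <- rowSums(Q^2)
  pn <- rowSums(P^2)
  d2 <- outer(qn, pn, `+`) - 2 * tcrossprod(Q, P)
  pmax(d2, 0)
}

distLogits <- function(Q, P, distance) {
  d2 <- pairwiseSqDist(Q, P)
  if (distance == "euclidean") -sqrt(d2) else -d2
}

softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Softmax-distance posteriors over class prototypes
#'
#' p(y = k | x) = exp(-d(f(x), c_k)) / sum_k' exp(-d(f(x), c_k')), with d
#' the squared Euclidean distance by default (configurable to plain
#' Euclidean). Computed with max-logit stabilisation.
#'
#' @param queryEmb numeric M-vector or N x M matrix of query embeddings.
#' @param protos a [PrototypeSet-class].
#' @param distance "squared_euclidean" (default) or "euclidean".
#' @return N x C matrix of probabilities (columns named by class id); a
#'   single query still yields a 1 x C matrix
#' @examples
#' p <- computePrototypes(matrix(c(1, 2), 2, 1), c(1, 2))
#' protoPosteriors(0, p)  # exp(-1)/(exp(-1)+exp(-4)) for class 1
#' @export
protoPosteriors <- function(queryEmb, protos,
                            distance = c("squared_euclidean", "euclidean")) {
  distance <- match.arg(distance)
  if (is.null(dim(queryEmb))) queryEmb <- matrix(queryEmb, nrow = 1L)
  stopifnot(ncol(queryEmb) == ncol(protos@prototypes))
  P <- softmaxRows(distLogits(queryEmb, protos@prototypes, distance))
  colnames(P) <- protos@classIds
  P
}

#' Set pooling: permutation-invariant instance summary
#'
#' Averages the embeddings of all pixel spectra of one instance into a
#' single M-vector, making the instance representation invariant to the
#' number and order of its effective pixels.
#'
#' @param embeddings numeric N x M matrix, N >= 1.
#' @return numeric M-vector
#' @export
setPool <- function(embeddings) {
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, nrow = 1L)
  if (nrow(embeddings) == 0L)
    stop("degenerate-instance error: cannot pool an empty embedding set")
  colMeans(embeddings)
}

#' Classify one instance
#'
#' Embeds every effective-pixel spectrum of the instance in inference mode,
#' set-pools the embeddings to one vector, and classifies it by softmax
#' distance to the prototypes. Ties are broken towards the lowest class id.
#'
#' @param net an [EmbeddingNetwork-class].
#' @param instance a [SpectraInstance-class].
#' @param protos a [PrototypeSet-class].
#' @param distance distance convention (defaults to the network config).
#' @return list with `class` (predicted id), `posterior` (named length-C
#'   vector), `pooled` (the pooled embedding)
#' @export
classifyInstance <- function(net, instance, protos,
                             distance = net@config$distance) {
  emb <- embedSpectra(net, instance@spectra, train = FALSE)
  pooled <- setPool(emb)
  post <- protoPosteriors(pooled, protos, distance)[1L, ]
  k <- protos@classIds[which.max(post)]   # which.max takes the first maximum
  list(class = k, posterior = post, pooled = pooled)
}

#' Per-pixel class probability map
#'
#' Classifies every effective pixel of a masked cube on its own (no set
#' pooling) and paints the posterior probability of class `k` onto the
#' image plane. Ineffective pixels carry `NA`.
#'
#' @param net an [EmbeddingNetwork-class].
#' @param cube a [CalibratedCube-class] with mask set.
#' @param bandIdx retained-band indices used at training time.
#' @param protos a [PrototypeSet-class].
#' @param k class id whose probability is mapped.
#' @param distance distance convention (defaults to the network config).
#' @return H x W numeric matrix in \[0,1\] with NA at ineffective pixels
#' @export
pixelProbabilityMap <- function(net, cube, bandIdx, protos, k,
                                distance = net@config$distance) {
  stopifnot(k %in% protos@classIds)
  inst <- cubeToInstance(cube, bandIdx, id = "probmap")
  emb <- embedSpectra(net, inst@spectra, train = FALSE)
  post <- protoPosteriors(emb, protos, distance)
  out <- matrix(NA_real_, dim(cube@values)[1], dim(cube@values)[2])
  out[inst@pixelCoords] <- post[, as.character(k)]
  out
}
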