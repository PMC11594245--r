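# Imbalanced-learning evaluation harness: confusion-based metrics, ranking
# metrics, the ratio-scaled minority downsampling protocol, the ablation
# runner and the PCA Gaussian-overlap separability diagnostic.

#' Confusion matrix
#'
#' @param truth,pred integer label vectors of equal length.
#' @param classes class ids fixing row/column order (default: union).
#' @return C x C integer matrix, rows = true class, columns = predicted
#' @export
confusionMatrix <- function(truth, pred, classes = sort(unique(c(truth, pred)))) {
  stopifnot(length(truth) == length(pred))
  if (!all(truth %in% classes) || !all(pred %in% classes))
    stop("input error: labels outside the class set")
  cm <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

perClassCounts <- function(cm) {
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- sum(cm) - tp - fn - fp
  data.frame(class = rownames(cm) %||% seq_len(nrow(cm)),
             tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Balanced accuracy
#'
#' Mean per-class recall; immune to class prevalence and equal to
#' (sensitivity + specificity)/2 for binary problems.
#'
#' @param cm confusion matrix (rows true, columns predicted).
#' @return rate in \[0, 1\]
#' @export
balancedAccuracy <- function(cm) {
  rs <- rowSums(cm)
  if (any(rs == 0))
    stop("undefined-metric error: a true class has no evaluated instances")
  mean(diag(cm) / rs)
}

#' Macro F1 score
#'
#' Mean one-vs-rest F1 over classes (F1 of a class with no predicted and no
#' true positives is taken as 0).
#'
#' @param cm confusion matrix.
#' @return rate in \[0, 1\]
#' @export
macroF1 <- function(cm) {
  cc <- perClassCounts(cm)
  f1 <- ifelse(2 * cc$tp + cc$fp + cc$fn == 0, 0,
               2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn))
  mean(f1)
}

#' Per-class sensitivity and specificity
#'
#' One-vs-rest: sensitivity of class k is its recall; specificity of class
#' k is the recall of the pooled remaining classes against k.
#'
#' @param cm confusion matrix.
#' @return data.frame with columns class, sensitivity, specificity
#' @export
sensSpec <- function(cm) {
  cc <- perClassCounts(cm)
  data.frame(class = cc$class,
             sensitivity = cc$tp / (cc$tp + cc$fn),
             specificity = cc$tn / (cc$tn + cc$fp))
}

# midrank (Mann-Whitney) AUROC for one binary split
aurocBinary <- function(scores, isPos) {
  nPos <- sum(isPos); nNeg <- sum(!isPos)
  if (nPos == 0 || nNeg == 0) return(NA_real_)
  r <- rank(scores)  # midranks under ties
  (sum(r[isPos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# average precision, summing precision at each recall step (ties handled
# by grouping equal scores into one threshold)
apBinary <- function(scores, isPos) {
  nPos <- sum(isPos)
  if (nPos == 0 || sum(!isPos) == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- as.numeric(isPos[o])
  cumTP <- cumsum(y)
  cumN <- seq_along(y)
  thr <- which(c(diff(s), -1) != 0)  # last index of each tied block
  prec <- cumTP[thr] / cumN[thr]
  rec <- cumTP[thr] / nPos
  dRec <- diff(c(0, rec))
  sum(prec * dRec)
}

#' Macro one-vs-rest AUROC and average precision
#'
#' Each class is scored one-vs-rest with its posterior column; per-class
#' AUROC (midrank/tie-aware) and average precision are averaged with equal
#' class weights. A class with no positive or no negative instance is a
#' degeneracy and raises an error naming the class.
#'
#' @param scores N x C matrix of class scores (columns ordered as
#'   `classes`).
#' @param labels integer true labels of length N.
#' @param classes class ids mapping labels to score columns.
#' @return rate in \[0, 1\]
#' @name macro-ranking
#' @export
macroAUROC <- function(scores, labels, classes = sort(unique(labels))) {
  mean(vapply(seq_along(classes), function(j) {
    a <- aurocBinary(scores[, j], labels == classes[j])
    if (is.na(a))
      stop(sprintf("undefined-metric error: class %s lacks positives or negatives",
                   classes[j]))
    a
  }, numeric(1)))
}

#' @rdname macro-ranking
#' @export
macroAP <- function(scores, labels, classes = sort(unique(labels))) {
  mean(vapply(seq_along(classes), function(j) {
    a <- apBinary(scores[, j], labels == classes[j])
    if (is.na(a))
      stop(sprintf("undefined-metric error: class %s lacks positives or negatives",
                   classes[j]))
    a
  }, numeric(1)))
}

#' Build an evaluation report from predictions
#'
#' @param truth,pred integer label vectors.
#' @param scores optional N x C posterior matrix (enables AUROC/AP).
#' @param classes class ids.
#' @param metadata free-form list stored in the report.
#' @return an [EvalReport-class]
#' @export
evalReport <- function(truth, pred, scores = NULL,
                       classes = sort(unique(c(truth, pred))),
                       metadata = list()) {
  cm <- confusionMatrix(truth, pred, classes)
  ss <- sensSpec(cm)
  cc <- perClassCounts(cm)
  f1 <- ifelse(2 * cc$tp + cc$fp + cc$fn == 0, 0,
               2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn))
  perClass <- data.frame(ss, f1 = f1, auroc = NA_real_, ap = NA_real_)
  metrics <- c(bAcc = balancedAccuracy(cm), macroF1 = macroF1(cm),
               macroAUROC = NA_real_, macroAP = NA_real_)
  if (!is.null(scores)) {
    perClass$auroc <- vapply(seq_along(classes), function(j)
      aurocBinary(scores[, j], truth == classes[j]), numeric(1))
    perClass$ap <- vapply(seq_along(classes), function(j)
      apBinary(scores[, j], truth == classes[j]), numeric(1))
    metrics[["macroAUROC"]] <- macroAUROC(scores, truth, classes)
    metrics[["macroAP"]] <- macroAP(scores, truth, classes)
  }
  new("EvalReport", confusion = cm, metrics = metrics, perClass = perClass,
      metadata = metadata)
}

#' Evaluate a trained model on test instances
#'
#' Classifies every instance (inference mode, set pooling) and summarises
#' the result as an [EvalReport-class]; posteriors feed the ranking
#' metrics.
#'
#' @param model a [ProtoDSModel-class].
#' @param instances labelled test [SpectraInstance-class] list.
#' @param metadata free-form list stored in the report.
#' @return an [EvalReport-class]
#' @export
evaluateModel <- function(model, instances, metadata = list()) {
  classes <- model@prototypes@classIds
  res <- lapply(instances, function(inst)
    classifyInstance(model@network, inst, model@prototypes))
  pred <- vapply(res, `[[`, integer(1) + 0, "class")
  scores <- do.call(rbind, lapply(res, `[[`, "posterior"))
  truth <- vapply(instances, instanceLabel, integer(1))
  metadata$variant <- metadata$variant %||% model@trainingInfo$ablation
  evalReport(truth, as.integer(pred), scores, classes, metadata)
}

# ---- imbalance protocol ------------------------------------------------

halfUp <- function(x) floor(x + 0.5)

#' Ratio-scaled minority training counts
#'
#' Given the full per-class instance counts, the least-represented minority
#' class is set to `n` training instances and every other minority class is
#' scaled in proportion to its original ratio to the least minority class,
#' with half-up rounding; the majority class (largest count) is left
#' untouched (NA in the result).
#'
#' @param counts named integer vector of full per-class counts.
#' @param n training instances for the least minority class.
#' @return named integer vector of target training counts (NA = keep all)
#' @examples
#' scaleMinorityCounts(c(a = 1267, b = 197, c = 104, d = 40), 5)
#' @export
scaleMinorityCounts <- function(counts, n) {
  stopifnot(n >= 1)
  maj <- which.max(counts)
  least <- counts[-maj][which.min(counts[-maj])]
  out <- halfUp(n * counts / least)
  out[maj] <- NA_integer_
  as.integer(out) |> stats::setNames(names(counts))
}

#' Stratified imbalanced train/test split
#'
#' First draws a class-stratified test set (`testFraction` per class,
#' training side floored), identically for every `n` at a fixed seed; the
#' remaining training pool is then downsampled: the majority class is kept
#' whole, the least minority class reduced to `n` and intermediate minority
#' classes to `round(n * count_k / count_least)` (half-up) where the counts
#' are the full-dataset class counts.
#'
#' @param manifest data.frame with columns `instance_id`, `label`.
#' @param n least-minority training count.
#' @param testFraction fraction of each class held out for testing.
#' @param seed integer seed.
#' @return list with `train` and `test` manifest data.frames and
#'   `targetCounts`
#' @export
buildImbalancedSplit <- function(manifest, n, testFraction = 0.5, seed = 1L) {
  stopifnot(all(c("instance_id", "label") %in% names(manifest)), n >= 1)
  classes <- sort(unique(manifest$label))
  counts <- vapply(classes, function(k) sum(manifest$label == k), integer(1))
  names(counts) <- classes
  set.seed(seed)
  testIdx <- unlist(lapply(classes, function(k) {
    ks <- which(manifest$label == k)
    nTrain <- floor(length(ks) * (1 - testFraction))
    sample(ks, length(ks) - nTrain)
  }))
  trainPool <- setdiff(seq_len(nrow(manifest)), testIdx)
  target <- scaleMinorityCounts(counts, n)
  trainIdx <- unlist(lapply(seq_along(classes), function(j) {
    k <- classes[j]
    ks <- intersect(trainPool, which(manifest$label == k))
    if (is.na(target[j])) return(ks)            # majority: keep whole
    if (target[j] > length(ks))
      stop(sprintf(paste0("spec error: class %s needs %d training instances ",
                          "but only %d are available"),
                   k, target[j], length(ks)))
    sample(ks, target[j])
  }))
  list(train = manifest[sort(trainIdx), , drop = FALSE],
       test = manifest[sort(testIdx), , drop = FALSE],
       targetCounts = target)
}

# ---- ablation harness --------------------------------------------------

ablationFlags <- function(variant) {
  switch(variant,
         full = list(useSSL = TRUE, useDice = TRUE),
         no_dice = list(useSSL = TRUE, useDice = FALSE),
         no_ssl = list(useSSL = FALSE, useDice = TRUE),
         no_ssl_no_dice = list(useSSL = FALSE, useDice = FALSE),
         stop(sprintf("unknown ablation variant '%s'", variant)))
}

#' Run the ablation grid
#'
#' Trains each requested variant from scratch for every (n, seed) cell on
#' datasets produced by `datasetFactory`, evaluates on the cell's test
#' instances and collects the metrics in a long-format data.frame. Failed
#' cells are recorded (`error` column) and the run continues.
#'
#' @param datasetFactory function(n, seed) returning a list with `train`
#'   and `test` lists of labelled [SpectraInstance-class].
#' @param nValues minority training sizes to sweep.
#' @param variants subset of `c("full", "no_dice", "no_ssl",
#'   "no_ssl_no_dice")`.
#' @param seeds integer vector of training/simulation seeds.
#' @param netCfg,sslCfg,ftCfg configs passed to [trainProtoDS()].
#' @return data.frame: n, variant, seed, bAcc, macroF1, macroAUROC,
#'   macroAP, error; the full [EvalReport-class] objects are attached as
#'   `attr(, "reports")`
#' @export
runAblation <- function(datasetFactory, nValues, variants = c("full",
                          "no_ssl_no_dice"), seeds = 1L, netCfg = NULL,
                        sslCfg = sslConfig(), ftCfg = finetuneConfig()) {
  grid <- expand.grid(n = nValues, variant = variants, seed = seeds,
                      stringsAsFactors = FALSE)
  grid$bAcc <- grid$macroF1 <- grid$macroAUROC <- grid$macroAP <- NA_real_
  grid$error <- NA_character_
  reports <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    flags <- ablationFlags(grid$variant[i])
    res <- tryCatch({
      ds <- datasetFactory(grid$n[i], grid$seed[i])
      model <- trainProtoDS(ds$train, netCfg = netCfg, sslCfg = sslCfg,
                            ftCfg = ftCfg, useSSL = flags$useSSL,
                            useDice = flags$useDice, seed = grid$seed[i])
      evaluateModel(model, ds$test,
                    metadata = list(n = grid$n[i], seed = grid$seed[i],
                                    variant = grid$variant[i]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      grid$error[i] <- conditionMessage(res)
    } else {
      m <- reportMetrics(res)
      grid$bAcc[i] <- m[["bAcc"]]; grid$macroF1[i] <- m[["macroF1"]]
      grid$macroAUROC[i] <- m[["macroAUROC"]]; grid$macroAP[i] <- m[["macroAP"]]
      reports[[i]] <- res
    }
  }
  attr(grid, "reports") <- reports
  grid
}

# ---- separability diagnostic -------------------------------------------

#' PCA + 2-D Gaussian overlap (IOU) separability diagnostic
#'
#' Projects embeddings to their first two principal components, fits a mean
#' and covariance per class, takes each class's region to be the
#' `level`-confidence ellipse of that Gaussian, and measures pairwise
#' separability as the Intersection-Over-Union of the ellipse areas on a
#' discretised grid. Lower IOU = better separated classes. A (near)
#' singular class covariance is regularised by `epsReg * I` with a warning.
#'
#' @param embeddings N x M matrix.
#' @param labels integer class labels, >= 3 samples per class.
#' @param gridRes grid resolution per axis.
#' @param level Gaussian confidence level defining the ellipse.
#' @param epsReg ridge added to a singular covariance.
#' @return list: `iou` (C x C symmetric, diagonal 1), `projection` (N x 2
#'   PC scores), `classes`, `means`, `covs`
#' @export
separabilityIOU <- function(embeddings, labels, gridRes = 200L, level = 0.95,
                            epsReg = 1e-9) {
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  if (any(table(labels) < 3L)) stop("need >= 3 samples per class")
  pc <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE, rank. = 2L)
  Y <- pc$x[, 1:2, drop = FALSE]
  q <- stats::qchisq(level, df = 2)
  fits <- lapply(classes, function(k) {
    Yk <- Y[labels == k, , drop = FALSE]
    mu <- colMeans(Yk)
    S <- stats::cov(Yk)
    if (!is.finite(rcond(S)) || rcond(S) < 1e-12) {
      warning(sprintf("singular covariance for class %s; regularised", k))
      S <- S + diag(epsReg, 2)
    }
    list(mu = mu, S = S)
  })
  # bounding box covering every ellipse
  lims <- sapply(fits, function(f) {
    r <- sqrt(q * diag(f$S))  # per-axis extent bound of the ellipse
    c(f$mu[1] - r[1] * 1.2, f$mu[1] + r[1] * 1.2,
      f$mu[2] - r[2] * 1.2, f$mu[2] + r[2] * 1.2)
  })
  gx <- seq(min(lims[1, ]), max(lims[2, ]), length.out = gridRes)
  gy <- seq(min(lims[3, ]), max(lims[4, ]), length.out = gridRes)
  grid <- cbind(rep(gx, times = gridRes), rep(gy, each = gridRes))
  inside <- sapply(fits, function(f)
    stats::mahalanobis(grid, f$mu, f$S) <= q)
  C <- length(classes)
  iou <- diag(1, C)
  for (i in seq_len(C - 1)) for (j in (i + 1):C) {
    un <- sum(inside[, i] | inside[, j])
    iou[i, j] <- iou[j, i] <- if (un == 0) 0 else
      sum(inside[, i] & inside[, j]) / un
  }
  dimnames(iou) <- list(classes, classes)
  list(iou = iou, projection = Y, classes = classes,
       means = lapply(fits, `[[`, "mu"), covs = lapply(fits, `[[`, "S"))
}
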