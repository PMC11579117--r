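# Confusion matrices, macro-averaged metrics, per-organism reporting, the
# cross-species ablation, and the non-adversarial FCNN baselines.

#' Confusion matrix counts
#'
#' Rows are the true class, columns the predicted class. Labels are 0-based
#' integers in `[0, nClasses)`.
#'
#' @param yTrue,yPred integer label vectors of equal length.
#' @param nClasses number of classes.
#' @return nClasses x nClasses count matrix.
#' @export
confusionCounts <- function(yTrue, yPred, nClasses) {
  yTrue <- as.integer(yTrue)
  yPred <- as.integer(yPred)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  if (any(yTrue < 0L | yTrue >= nClasses | yPred < 0L | yPred >= nClasses))
    stop("label out of range [0, ", nClasses, ")")
  m <- matrix(0L, nClasses, nClasses,
              dimnames = list(true = 0:(nClasses - 1L),
                              predicted = 0:(nClasses - 1L)))
  for (i in seq_along(yTrue))
    m[yTrue[i] + 1L, yPred[i] + 1L] <- m[yTrue[i] + 1L, yPred[i] + 1L] + 1L
  m
}

#' Normalized views of a confusion matrix
#'
#' `by = "true-class"` divides each row by its true-class total (the
#' per-true-class accuracy convention); `by = "total"` divides by the grand
#' total; `by = "none"` returns counts.
#'
#' @param m a confusion count matrix (rows = true).
#' @param by normalization mode.
#' @return numeric matrix.
#' @export
normalizeConfusion <- function(m, by = c("none", "true-class", "total")) {
  by <- match.arg(by)
  switch(by,
    none = m,
    "true-class" = {
      rs <- rowSums(m)
      rs[rs == 0] <- 1
      m / rs
    },
    total = m / sum(m))
}

#' Macro-averaged classification metrics
#'
#' Per-class precision, recall and F1 with the 0/0 -> 0 convention (a
#' never-predicted class gets precision 0, with a warning), their unweighted
#' (macro) means, accuracy = trace / total, and risk = 1 - accuracy.
#'
#' @param m a square confusion count matrix (rows = true).
#' @return a [MetricsReport-class].
#' @export
classificationMetrics <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  total <- sum(m)
  if (total == 0) stop("all-zero confusion matrix")
  tp <- diag(m)
  colTot <- colSums(m)
  rowTot <- rowSums(m)
  if (any(colTot == 0))
    warning("never-predicted class(es): precision defined as 0")
  precision <- ifelse(colTot > 0, tp / colTot, 0)
  recall <- ifelse(rowTot > 0, tp / rowTot, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  acc <- sum(tp) / total
  new("MetricsReport", confusion = m, accuracy = acc,
      precision = unname(precision), recall = unname(recall),
      f1 = unname(f1), macroPrecision = mean(precision),
      macroRecall = mean(recall), macroF1 = mean(f1), risk = 1 - acc)
}

#' Per-organism evaluation of a joint broad-type model
#'
#' Evaluates the single joint model separately on the mouse and human test
#' rows. An organism absent from the test partition is omitted with a
#' warning.
#'
#' @param model a [DANNModel-class].
#' @param split a normalized [EphysSplit-class].
#' @return named list of [MetricsReport-class] per organism present.
#' @export
evaluatePerDomain <- function(model, split) {
  te <- split@test
  pred <- predictBroad(model, te)
  truth <- broadLabel(te)
  org <- organismLabel(te)
  out <- list()
  for (o in .ORGANISMS) {
    rows <- org == o
    if (!any(rows)) {
      warning("organism '", o, "' absent from the test partition; omitted")
      next
    }
    out[[o]] <- classificationMetrics(
      confusionCounts(truth[rows], pred[rows], 2L))
  }
  out
}

.subsetSplitDomain <- function(split, org) {
  keep <- function(es) es[, organismLabel(es) == org]
  split@train <- keep(split@train)
  split@validation <- keep(split@validation)
  split
}

.metricsOnRows <- function(model, es, rows) {
  classificationMetrics(confusionCounts(
    broadLabel(es)[rows], predictBroad(model, featureMatrix(es)[rows, , drop = FALSE]), 2L))
}

#' Cross-species transfer ablation
#'
#' Trains a plain (non-adversarial, lambda = 0) extractor + label head on
#' one organism's training rows and evaluates on the other organism's test
#' rows, in both directions, reporting the transfer gap against the
#' within-organism test performance. This isolates the domain shift that the
#' adversarial scheme is designed to remove.
#'
#' @param cfg a [DANNConfig-class]; `lambda` is forced to 0.
#' @param split a normalized [EphysSplit-class] containing both organisms.
#' @return list with elements `mouseToHuman` and `humanToMouse`, each a list
#'   of `within` and `transfer` [MetricsReport-class] objects plus `gap`
#'   (within-accuracy minus transfer-accuracy).
#' @export
crossDomainAblation <- function(cfg, split) {
  cfg@lambda <- 0
  directions <- list(mouseToHuman = c("mouse", "human"),
                     humanToMouse = c("human", "mouse"))
  out <- list()
  for (nm in names(directions)) {
    src <- directions[[nm]][1L]
    tgt <- directions[[nm]][2L]
    sub <- .subsetSplitDomain(split, src)
    fit <- trainDANN(cfg, sub)
    te <- split@test
    org <- organismLabel(te)
    within <- .metricsOnRows(fit$model, te, org == src)
    transfer <- .metricsOnRows(fit$model, te, org == tgt)
    out[[nm]] <- list(within = within, transfer = transfer,
                      gap = within@accuracy - transfer@accuracy)
  }
  out
}

.appendOrganismFeature <- function(split) {
  add <- function(es) {
    X <- featureMatrix(es)
    X <- cbind(X, organism_type = as.numeric(organismLabel(es) == "human"))
    out <- EphysSet(X, organism = organismLabel(es),
                    broadLabel = broadLabel(es), lineTag = lineTag(es),
                    subclassLabel = subclassLabel(es),
                    sampleIds = colnames(es))
    out
  }
  split@train <- add(split@train)
  split@validation <- add(split@validation)
  split@test <- add(split@test)
  split@center <- c(split@center, organism_type = 0)
  split@scale <- c(split@scale, organism_type = 1)
  split
}

#' Non-adversarial FCNN baseline
#'
#' Trains the plain counterpart of the adversarial model (same machinery
#' with lambda = 0) on the pooled two-organism data, optionally appending a
#' binary organism-indicator feature (0 = mouse, 1 = human), and reports
#' per-organism test metrics.
#'
#' @param cfg a [DANNConfig-class]; `lambda` is forced to 0.
#' @param split a normalized [EphysSplit-class].
#' @param includeOrganismFeature append the indicator column (input width
#'   becomes D + 1)?
#' @return list with `model` and `metrics` (per-organism
#'   [MetricsReport-class]).
#' @export
fcnnBaseline <- function(cfg, split, includeOrganismFeature = FALSE) {
  cfg@lambda <- 0
  if (includeOrganismFeature) split <- .appendOrganismFeature(split)
  fit <- trainDANN(cfg, split)
  list(model = fit$model, history = fit$history,
       metrics = evaluatePerDomain(fit$model, split))
}

#' Train a small probe classifier for the domain
#'
#' Fits a compact MLP to predict the organism from a representation (raw
#' features or extractor embeddings) and returns its held-out accuracy; the
#' diagnostic for domain invariance of learned embeddings.
#'
#' The probe is trained with inverse-frequency sample weights and scored by
#' domain-balanced accuracy (the mean of the per-domain recalls), so that
#' under the cohort's heavy mouse/human imbalance a probe that degenerates
#' to majority prediction scores 0.5, not the majority rate.
#'
#' @param xTrain,dTrain training representation and 0/1 domain labels.
#' @param xTest,dTest held-out representation and labels.
#' @param hidden probe hidden widths.
#' @param epochs,learningRate,batchSize training settings.
#' @param seed integer seed.
#' @return held-out balanced accuracy in \[0, 1\].
#' @export
domainProbe <- function(xTrain, dTrain, xTest, dTest, hidden = 32L,
                        epochs = 150L, learningRate = 0.005,
                        batchSize = 64L, seed = 1L) {
  set.seed(as.integer(seed))
  xTrain <- as.matrix(xTrain)
  xTest <- as.matrix(xTest)
  d1 <- as.integer(dTrain) + 1L
  freq <- tabulate(d1, 2L)
  w <- (length(d1) / (2 * pmax(freq, 1L)))[d1]
  net <- .mlpInit(ncol(xTrain), c(as.integer(hidden), 2L),
                  c(rep("relu", length(hidden)), "identity"))
  params <- .netParams(net)
  isW <- .netIsWeight(net)
  opt <- .optInit("adam", params)
  n <- nrow(xTrain)
  for (epoch in seq_len(epochs)) {
    for (b in .miniBatches(n, batchSize)) {
      net <- .setNetParams(net, params)
      cache <- .mlpForward(net, xTrain[b, , drop = FALSE])
      P <- .softmax(cache$out)
      dLog <- w[b] * (P - .onehot(d1[b], 2L)) / length(b)
      g <- .mlpBackward(net, cache, dLog)
      st <- .optStep(opt, params, .gradParams(g), learningRate, 0, isW)
      opt <- st$opt
      params <- st$params
    }
  }
  net <- .setNetParams(net, params)
  pred <- .argmax0(.mlpForward(net, xTest)$out)
  dTest <- as.integer(dTest)
  mean(c(mean(pred[dTest == 0L] == 0L), mean(pred[dTest == 1L] == 1L)))
}
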