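# Locally sparse gated classification. A gating network psi predicts
# per-sample gate parameters mu = psi(x); stochastic gates
#   z = max(0, min(1, 0.5 + mu + eps)),  eps ~ N(0, sigma^2) (0 at inference)
# sparsify the features seen by the prediction network f_theta(x * z). The
# loss is cross-entropy plus a differentiable surrogate for the expected
# open-gate count, lambda1 * sum_d Phi((mu_d + 0.5) / sigma), plus an
# optional kernel-weighted gate-smoothness term.

#' Construct an LSPIN configuration
#'
#' Defaults reproduce the fitted five-subclass run: prediction net 40/20,
#' gating net 3 x 50, tanh, `lambda1 = 0.01047`, `lambda2 = 0`,
#' `sigma = 0.5`, learning rate 0.0599, 1000 epochs, SGD.
#'
#' @param gatingHidden,predictionHidden hidden widths of the two networks.
#' @param activation activation for both networks (default `"tanh"`).
#' @param sigma gate noise sd during training (> 0 required to train).
#' @param lambda1,lambda2 sparsity and smoothness weights.
#' @param kernelBandwidth RBF bandwidth for the smoothness kernel
#'   (NA = per-batch median heuristic).
#' @param learningRate,epochs,batchSize,optimizer,seed training settings.
#' @return a validated [LSPINConfig-class].
#' @export
lspinConfig <- function(gatingHidden = c(50L, 50L, 50L),
                        predictionHidden = c(40L, 20L),
                        activation = "tanh", sigma = 0.5,
                        lambda1 = 0.01047, lambda2 = 0,
                        kernelBandwidth = NA_real_, learningRate = 0.0599,
                        epochs = 1000L, batchSize = 64L, optimizer = "sgd",
                        seed = 1L) {
  new("LSPINConfig", gatingHidden = as.integer(gatingHidden),
      predictionHidden = as.integer(predictionHidden),
      activation = activation, sigma = sigma, lambda1 = lambda1,
      lambda2 = lambda2, kernelBandwidth = kernelBandwidth,
      learningRate = learningRate, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), optimizer = optimizer,
      seed = as.integer(seed))
}

#' The stochastic gate threshold function
#'
#' `z = max(0, min(1, 0.5 + mu + eps))`, elementwise.
#'
#' @param mu gate parameters (vector or matrix).
#' @param eps noise of the same shape (zero at inference).
#' @return gate values in \[0, 1\], same shape as `mu`.
#' @examples
#' stochasticGate(0.2, 0)    # 0.7
#' stochasticGate(-0.9, 0.1) # 0
#' @export
stochasticGate <- function(mu, eps) {
  if (length(mu) != length(eps))
    stop("shape error: mu and eps must have the same length")
  pmin(pmax(0.5 + mu + eps, 0), 1)
}

#' Sample gate noise
#'
#' Fresh `N(0, sigma^2)` draws for every training forward pass; identically
#' zero when `sigma = 0` (inference mode).
#'
#' @param sigma noise sd, >= 0.
#' @param n,d matrix dimensions (samples x features).
#' @return n x d noise matrix.
#' @export
sampleGateNoise <- function(sigma, n, d) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) matrix(0, n, d)
  else matrix(stats::rnorm(n * d, 0, sigma), n, d)
}

.newLSPINModel <- function(cfg, dIn, classLevels) {
  k <- length(classLevels)
  gatingNet <- .mlpInit(dIn, c(cfg@gatingHidden, dIn),
                        c(rep(cfg@activation, length(cfg@gatingHidden)),
                          "tanh"))
  predictionNet <- .mlpInit(dIn, c(cfg@predictionHidden, k),
                            c(rep(cfg@activation,
                                  length(cfg@predictionHidden)),
                              "identity"))
  new("LSPINModel", gatingNet = gatingNet, predictionNet = predictionNet,
      config = cfg, classLevels = classLevels, dIn = as.integer(dIn))
}

#' Forward pass of the locally sparse network
#'
#' Computes `mu = psi(x)`, gates `z = stochasticGate(mu, eps)` (noise drawn
#' from the ambient RNG in train mode, zero in infer mode) and class scores
#' `f_theta(x * z)`. Inference is deterministic.
#'
#' @param model a [LSPINModel-class].
#' @param x numeric matrix of normalized features.
#' @param mode `"infer"` (default) or `"train"`.
#' @return list with `scores` (n x classes), `gates` (n x features) and
#'   `mu`.
#' @export
lspinForward <- function(model, x, mode = c("infer", "train")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (ncol(x) != model@dIn)
    stop("shape error: ", ncol(x), " features but the model expects ",
         model@dIn)
  mu <- .mlpForward(model@gatingNet, x)$out
  eps <- if (mode == "train")
    sampleGateNoise(model@config@sigma, nrow(x), ncol(x))
  else matrix(0, nrow(x), ncol(x))
  z <- stochasticGate(mu, eps)
  scores <- .mlpForward(model@predictionNet, x * z)$out
  list(scores = scores, gates = z, mu = mu)
}

#' Sparsity penalty (expected open-gate count surrogate)
#'
#' `lambda1 * mean_i sum_d Phi((mu_d + 0.5) / sigma)`, the exact expectation
#' of the number of nonzero gates under the gate noise, and a differentiable
#' surrogate for the L0 gate norm.
#'
#' @param mu matrix of gate parameters (samples x features) or a vector.
#' @param sigma gate noise sd, > 0.
#' @param lambda1 sparsity weight.
#' @return scalar penalty.
#' @export
sparsityPenalty <- function(mu, sigma, lambda1) {
  if (lambda1 == 0) return(0)
  if (sigma <= 0) stop("sigma must be > 0 for the sparsity surrogate")
  mu <- rbind(mu)
  lambda1 * mean(rowSums(stats::pnorm((mu + 0.5) / sigma)))
}

#' Gate smoothness penalty
#'
#' `lambda2 * mean_i sum_j K[i, j] * ||z_i - z_j||^2` over the rows of the
#' gate matrix; zero when all rows coincide, and zero by definition with
#' `lambda2 = 0` (the fitted setting).
#'
#' @param z gate matrix (samples x features).
#' @param K non-negative kernel matrix (samples x samples).
#' @param lambda2 smoothness weight.
#' @return scalar penalty.
#' @export
smoothnessPenalty <- function(z, K, lambda2) {
  if (lambda2 == 0) return(0)
  if (any(K < 0)) stop("kernel entries must be >= 0")
  z <- rbind(z)
  sq <- rowSums(z^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(z)
  lambda2 * mean(rowSums(K * pmax(d2, 0)))
}

.rbfKernel <- function(x, bandwidth = NA_real_) {
  sq <- rowSums(x^2)
  d2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(x), 0)
  if (is.na(bandwidth)) {
    off <- sqrt(d2[upper.tri(d2)])
    bandwidth <- stats::median(off)
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  exp(-d2 / (2 * bandwidth^2))
}

#' Full gated training loss
#'
#' Cross-entropy of the gated predictions plus the sparsity and smoothness
#' penalties, batch-averaged. With `eps = NULL` the gates are evaluated at
#' their deterministic (inference) values.
#'
#' @param model a [LSPINModel-class].
#' @param x numeric feature matrix.
#' @param y class labels (factor or character matching the model's
#'   `classLevels`, or 1-based integer indices).
#' @param eps optional explicit gate noise matrix.
#' @return scalar loss.
#' @export
lspinLoss <- function(model, x, y, eps = NULL) {
  cfg <- model@config
  x <- as.matrix(x)
  yIdx <- .classIndex(y, model@classLevels)
  mu <- .mlpForward(model@gatingNet, x)$out
  if (is.null(eps)) eps <- matrix(0, nrow(x), ncol(x))
  z <- stochasticGate(mu, eps)
  P <- .softmax(.mlpForward(model@predictionNet, x * z)$out)
  ce <- .crossEntropy(P, yIdx)
  sp <- if (cfg@lambda1 > 0) sparsityPenalty(mu, cfg@sigma, cfg@lambda1) else 0
  sm <- if (cfg@lambda2 > 0)
    smoothnessPenalty(z, .rbfKernel(x, cfg@kernelBandwidth), cfg@lambda2)
  else 0
  ce + sp + sm
}

.classIndex <- function(y, levels) {
  if (is.numeric(y)) {
    y <- as.integer(y)
    if (any(y < 1L | y > length(levels)))
      stop("unknown class label: index out of range")
    return(y)
  }
  idx <- match(as.character(y), levels)
  if (anyNA(idx))
    stop("unknown class label: ",
         paste(unique(as.character(y)[is.na(idx)]), collapse = ", "))
  idx
}

# one training step: returns grads for both networks plus loss components
.lspinGrads <- function(model, x, yIdx, cfg) {
  n <- nrow(x)
  D <- ncol(x)
  k <- length(model@classLevels)
  cg <- .mlpForward(model@gatingNet, x)
  mu <- cg$out
  eps <- sampleGateNoise(cfg@sigma, n, D)
  pre <- 0.5 + mu + eps
  z <- pmin(pmax(pre, 0), 1)
  xg <- x * z
  cp <- .mlpForward(model@predictionNet, xg)
  P <- .softmax(cp$out)
  ce <- .crossEntropy(P, yIdx)
  dLog <- (P - .onehot(yIdx, k)) / n
  bp <- .mlpBackward(model@predictionNet, cp, dLog)
  # back through the Hadamard product into the gates
  dZ <- bp$dIn * x
  if (cfg@lambda2 > 0) {
    K <- .rbfKernel(x, cfg@kernelBandwidth)
    KS <- K + t(K)
    dZ <- dZ + (cfg@lambda2 / n) * 2 *
      (rowSums(KS) * z - KS %*% z)
    sm <- smoothnessPenalty(z, K, cfg@lambda2)
  } else sm <- 0
  active <- (pre > 0) & (pre < 1)   # clip derivative
  dMu <- dZ * active
  if (cfg@lambda1 > 0) {
    dMu <- dMu + (cfg@lambda1 / n) *
      stats::dnorm((mu + 0.5) / cfg@sigma) / cfg@sigma
    sp <- sparsityPenalty(mu, cfg@sigma, cfg@lambda1)
  } else sp <- 0
  bg <- .mlpBackward(model@gatingNet, cg, dMu)
  list(loss = ce + sp + sm, ce = ce, sparsity = sp, smoothness = sm,
       gradPrediction = .gradParams(bp), gradGating = .gradParams(bg))
}

#' Train the locally sparse classifier
#'
#' Jointly minimizes the gated loss over the gating and prediction networks
#' with seeded minibatch updates. Training requires `sigma > 0` (the gates
#' need noise for the continuous relaxation); inference is deterministic.
#'
#' @param cfg an [LSPINConfig-class].
#' @param split a normalized [EphysSplit-class] whose train partition has
#'   subclass labels with at least two classes.
#' @return list with `model` (a [LSPINModel-class]) and `history` (per-epoch
#'   loss components and validation accuracy when a validation partition is
#'   present).
#' @export
trainLSPIN <- function(cfg, split) {
  validObject(cfg)
  if (cfg@sigma <= 0)
    stop("sigma must be > 0 during training: the stochastic gates need ",
         "noise for the continuous relaxation")
  if (!split@normalized)
    stop("split must be normalized (normalizeSplit) before training")
  es <- split@train
  x <- featureMatrix(es)
  lab <- subclassLabel(es)
  if (anyNA(lab)) stop("train partition has missing subclass labels")
  classLevels <- .SUBCLASS_LEVELS[.SUBCLASS_LEVELS %in% unique(lab)]
  if (!length(classLevels)) classLevels <- sort(unique(lab))
  if (length(classLevels) < 2L)
    stop("need at least two classes to train")
  yIdx <- .classIndex(lab, classLevels)
  n <- nrow(x)
  set.seed(cfg@seed)
  model <- .newLSPINModel(cfg, ncol(x), classLevels)
  params <- c(.netParams(model@gatingNet), .netParams(model@predictionNet))
  isW <- c(.netIsWeight(model@gatingNet), .netIsWeight(model@predictionNet))
  ng <- length(.netParams(model@gatingNet))
  opt <- .optInit(cfg@optimizer, params)
  hasVal <- ncol(split@validation) > 0L &&
    !anyNA(subclassLabel(split@validation))
  hist <- data.frame(epoch = seq_len(cfg@epochs), loss = NA_real_,
                     crossEntropy = NA_real_, sparsity = NA_real_,
                     smoothness = NA_real_, valAccuracy = NA_real_)
  unpack <- function(params) {
    model@gatingNet <- .setNetParams(model@gatingNet, params[seq_len(ng)])
    model@predictionNet <- .setNetParams(model@predictionNet,
                                         params[-seq_len(ng)])
    model
  }
  for (epoch in seq_len(cfg@epochs)) {
    sl <- sce <- ssp <- ssm <- 0
    for (b in .miniBatches(n, cfg@batchSize)) {
      model <- unpack(params)
      g <- .lspinGrads(model, x[b, , drop = FALSE], yIdx[b], cfg)
      st <- .optStep(opt, params, c(g$gradGating, g$gradPrediction),
                     cfg@learningRate, 0, isW)
      opt <- st$opt
      params <- st$params
      w <- length(b)
      sl <- sl + g$loss * w
      sce <- sce + g$ce * w
      ssp <- ssp + g$sparsity * w
      ssm <- ssm + g$smoothness * w
    }
    hist$loss[epoch] <- sl / n
    hist$crossEntropy[epoch] <- sce / n
    hist$sparsity[epoch] <- ssp / n
    hist$smoothness[epoch] <- ssm / n
    if (hasVal) {
      model <- unpack(params)
      pv <- predictSubclass(model, split@validation)
      hist$valAccuracy[epoch] <-
        mean(as.character(pv) == subclassLabel(split@validation))
    }
  }
  list(model = unpack(params), history = hist)
}

#' Predict subclasses with a trained gated model
#'
#' Deterministic inference-mode argmax (ties resolve to the first class).
#'
#' @param model a [LSPINModel-class].
#' @param x numeric matrix or [EphysSet-class].
#' @return factor of predicted subclass labels.
#' @export
predictSubclass <- function(model, x) {
  if (is(x, "EphysSet")) x <- featureMatrix(x)
  fw <- lspinForward(model, x, mode = "infer")
  factor(model@classLevels[.argmax0(fw$scores) + 1L],
         levels = model@classLevels)
}

#' Inference-time gate matrix
#'
#' The samples x features matrix of deterministic gate values
#' `z = clip(0.5 + psi(x))`; the model's interpretability surface. Gates near
#' 0 mute a feature for that sample, gates near 1 pass it through.
#'
#' @param model a [LSPINModel-class].
#' @param x numeric matrix or [EphysSet-class].
#' @return numeric matrix with entries in \[0, 1\].
#' @export
gateMatrix <- function(model, x) {
  ids <- NULL
  if (is(x, "EphysSet")) {
    ids <- colnames(x)
    x <- featureMatrix(x)
  }
  fw <- lspinForward(model, x, mode = "infer")
  Z <- fw$gates
  rownames(Z) <- if (!is.null(ids)) ids else rownames(x)
  colnames(Z) <- colnames(x)
  Z
}

#' Hierarchically cluster a gate matrix
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of the
#' rows (samples) and columns (features), for heatmap rendering.
#'
#' @param z gate matrix.
#' @return list with `rowOrder`, `colOrder` (leaf orders) and
#'   `rowDendrogram`, `colDendrogram` (hclust objects, or NULL for a single
#'   row/column).
#' @export
clusterGateMatrix <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) == 0L) stop("empty gate matrix")
  clus <- function(m) {
    if (nrow(m) < 2L) return(list(order = seq_len(nrow(m)), hc = NULL))
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "average")
    list(order = hc$order, hc = hc)
  }
  rowC <- clus(z)
  colC <- clus(t(z))
  list(rowOrder = rowC$order, colOrder = colC$order,
       rowDendrogram = rowC$hc, colDendrogram = colC$hc)
}
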