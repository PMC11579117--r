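# Domain-adversarial training: one feature extractor feeds a 2-class label
# head and a 2-domain head. The saddle-point objective
#   E = mean(L_y) - lambda * mean(L_d)
# is optimized with the three update rules
#   theta_f <- theta_f - mu (dL_y/dtheta_f - lambda dL_d/dtheta_f)
#   theta_y <- theta_y - mu  dL_y/dtheta_y
#   theta_d <- theta_d - mu lambda dL_d/dtheta_d,
# implemented as identity-forward / negate-and-scale-backward on the
# extractor -> domain-head edge (gradient reversal).

#' Construct a DANN configuration
#'
#' @param hidden extractor hidden widths (default `c(32, 16)`).
#' @param headHidden hidden widths of both heads (default 16; `integer(0)`
#'   gives linear heads).
#' @param activations per-layer activations (recycled; default `"relu"`).
#' @param lambda adversarial weight (>= 0).
#' @param learningRate,dropout,weightDecay,batchSize,epochs,optimizer
#'   training settings; see [DANNConfig-class] for the admissible ranges.
#' @param lambdaSchedule `"fixed"` or `"ramp"`.
#' @param useTargetLabels include target-domain labels in the label loss
#'   (default TRUE: the joint classifier is supervised on both organisms).
#' @param checkpoint `"final"` or `"best"` (validation label accuracy).
#' @param clipNorm global gradient-norm clip per minibatch (`Inf` disables).
#' @param domainWeighting `"none"` or `"balanced"` (inverse-frequency weights
#'   in the domain loss).
#' @param seed integer seed.
#' @return a validated [DANNConfig-class].
#' @export
dannConfig <- function(hidden = c(32L, 16L), headHidden = 16L,
                       activations = "relu",
                       lambda = 0, learningRate = 0.05, dropout = 0,
                       weightDecay = 0, batchSize = 64L, epochs = 100L,
                       optimizer = "sgd", lambdaSchedule = "fixed",
                       useTargetLabels = TRUE, checkpoint = "final",
                       clipNorm = 5, domainWeighting = "none", seed = 1L) {
  new("DANNConfig", hidden = as.integer(hidden),
      headHidden = as.integer(headHidden),
      activations = rep_len(activations, length(hidden)),
      lambda = lambda, learningRate = learningRate, dropout = dropout,
      weightDecay = weightDecay, batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), optimizer = optimizer,
      lambdaSchedule = lambdaSchedule, useTargetLabels = useTargetLabels,
      checkpoint = checkpoint, clipNorm = clipNorm,
      domainWeighting = domainWeighting, seed = as.integer(seed))
}

.newDANNModel <- function(cfg, dIn) {
  extractor <- .mlpInit(dIn, cfg@hidden, cfg@activations)
  headW <- c(cfg@headHidden, 2L)
  headA <- c(rep("relu", length(cfg@headHidden)), "identity")
  labelHead <- .mlpInit(cfg@hidden[length(cfg@hidden)], headW, headA)
  domainHead <- .mlpInit(cfg@hidden[length(cfg@hidden)], headW, headA)
  new("DANNModel", extractor = extractor, labelHead = labelHead,
      domainHead = domainHead, config = cfg, dIn = as.integer(dIn))
}

.checkBatch <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model@dIn)
    stop("shape error: batch has ", ncol(x), " features but the model expects ",
         model@dIn)
  if (nrow(x) == 0L) stop("empty batch")
  x
}

# One combined forward/backward pass. labelMask: logical, rows contributing
# to the label loss (all by default). Returns losses and the gradient blocks
# needed by the three update rules; the extractor gradient is already the
# reversed combination dL_y/dtheta_f - lambda dL_d/dtheta_f.
.dannGrads <- function(model, x, y, d, lambda, dropout = 0,
                       training = FALSE, labelMask = NULL,
                       domainWeights = NULL) {
  n <- nrow(x)
  fc <- .mlpForward(model@extractor, x, dropout = dropout,
                    training = training)
  H <- fc$out
  cy <- .mlpForward(model@labelHead, H)
  Py <- .softmax(cy$out)
  cd <- .mlpForward(model@domainHead, H)
  Pd <- .softmax(cd$out)
  if (is.null(labelMask)) labelMask <- rep(TRUE, n)
  nlab <- sum(labelMask)
  Ly <- if (nlab) .crossEntropy(Py[labelMask, , drop = FALSE],
                                y[labelMask]) else 0
  if (is.null(domainWeights)) domainWeights <- rep(1, n)
  Ld <- sum(domainWeights *
              -log(pmax(Pd[cbind(seq_len(n), d)], 1e-300))) / n
  dLogY <- (Py - .onehot(y, 2L))
  dLogY[!labelMask, ] <- 0
  dLogY <- dLogY / max(nlab, 1L)
  dLogD <- domainWeights * (Pd - .onehot(d, 2L)) / n
  by <- .mlpBackward(model@labelHead, cy, dLogY)
  bd <- .mlpBackward(model@domainHead, cd, dLogD)
  # gradient reversal on the extractor -> domain-head edge
  bf <- .mlpBackward(model@extractor, fc, by$dIn - lambda * bd$dIn)
  list(labelLoss = Ly, domainLoss = Ld,
       gradF = .gradParams(bf), gradY = .gradParams(by),
       gradD = .gradParams(bd))
}

#' Label and domain cross-entropy losses
#'
#' Mean softmax cross-entropy of the label head `G_y(G_f(x))` against the
#' broad labels, and of the domain head `G_d(G_f(x))` against the organism
#' labels (mouse = 0, human = 1).
#'
#' @param model a [DANNModel-class].
#' @param x numeric matrix (rows = samples, normalized features).
#' @param y integer broad labels (0/1).
#' @param d integer domain labels (0 = mouse, 1 = human).
#' @return scalar loss, >= 0.
#' @export
labelLoss <- function(model, x, y) {
  x <- .checkBatch(model, x)
  H <- .mlpForward(model@extractor, x)$out
  P <- .softmax(.mlpForward(model@labelHead, H)$out)
  .crossEntropy(P, as.integer(y) + 1L)
}

#' @rdname labelLoss
#' @export
domainLoss <- function(model, x, d) {
  x <- .checkBatch(model, x)
  H <- .mlpForward(model@extractor, x)$out
  P <- .softmax(.mlpForward(model@domainHead, H)$out)
  .crossEntropy(P, as.integer(d) + 1L)
}

#' Adversarial objective
#'
#' `E = labelLoss - lambda * domainLoss`, the quantity minimized over the
#' extractor and label head and maximized over the domain head.
#'
#' @inheritParams labelLoss
#' @param d integer domain labels (0/1).
#' @param lambda adversarial weight, >= 0.
#' @return scalar objective value.
#' @export
dannObjective <- function(model, x, y, d, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  labelLoss(model, x, y) - lambda * domainLoss(model, x, d)
}

#' One gradient-reversed update step
#'
#' Applies the three update rules once, with plain (non-adaptive) steps of
#' size `mu`: the extractor descends `dL_y - lambda * dL_d`, the label head
#' descends `dL_y`, and the domain head descends `lambda * dL_d`. With
#' `lambda = 0` this is exactly one step of ordinary joint training; with
#' `mu = 0` the model is returned unchanged.
#'
#' @inheritParams dannObjective
#' @param mu learning rate, >= 0.
#' @return the updated [DANNModel-class].
#' @export
reversedFeatureUpdate <- function(model, x, y, d, lambda, mu) {
  if (mu < 0) stop("mu must be >= 0")
  x <- .checkBatch(model, x)
  g <- .dannGrads(model, x, as.integer(y) + 1L, as.integer(d) + 1L, lambda)
  for (blk in c("gradF", "gradY", "gradD")) {
    if (!all(vapply(g[[blk]], function(t) all(is.finite(t)), TRUE)))
      stop("non-finite gradient in parameter block ", blk)
  }
  step <- function(net, grads, rate) {
    p <- .netParams(net)
    for (i in seq_along(p)) p[[i]] <- p[[i]] - rate * grads[[i]]
    .setNetParams(net, p)
  }
  model@extractor <- step(model@extractor, g$gradF, mu)
  model@labelHead <- step(model@labelHead, g$gradY, mu)
  model@domainHead <- step(model@domainHead, g$gradD, mu * lambda)
  model
}

.lambdaAt <- function(cfg, epoch) {
  if (cfg@lambdaSchedule == "ramp") {
    p <- epoch / cfg@epochs
    cfg@lambda * (2 / (1 + exp(-10 * p)) - 1)
  } else cfg@lambda
}

.splitTensors <- function(split, part = "train") {
  es <- slot(split, part)
  list(x = featureMatrix(es),
       y = as.integer(broadLabel(es)) + 1L,
       d = as.integer(organismLabel(es) == "human") + 1L)
}

#' Train a domain-adversarial classifier
#'
#' Runs `cfg@epochs` of seeded minibatch updates of the three update rules
#' (with the configured optimizer applied to each parameter block's
#' gradient). Mouse is the source domain, human the target. With
#' `lambda = 0` the run is weight-for-weight identical to plain joint
#' training of extractor + label head under the same seed.
#'
#' @param cfg a [DANNConfig-class].
#' @param split a normalized [EphysSplit-class]; the train partition must
#'   contain both organisms whenever `lambda > 0`.
#' @return list with `model` (a [DANNModel-class]) and `history` (one row per
#'   epoch: label loss, domain loss, objective, per-domain validation
#'   accuracy).
#' @export
trainDANN <- function(cfg, split) {
  validObject(cfg)
  if (!split@normalized)
    stop("split must be normalized (normalizeSplit) before training")
  tr <- .splitTensors(split, "train")
  n <- nrow(tr$x)
  if (cfg@lambda > 0 && length(unique(tr$d)) < 2L)
    stop("single-domain training data: the domain loss is undefined as a ",
         "discriminator when lambda > 0")
  labelMask <- if (cfg@useTargetLabels) rep(TRUE, n) else tr$d == 1L
  domainW <- if (cfg@domainWeighting == "balanced") {
    freq <- tabulate(tr$d, 2L)
    (n / (2 * pmax(freq, 1L)))[tr$d]
  } else rep(1, n)
  set.seed(cfg@seed)
  model <- .newDANNModel(cfg, ncol(tr$x))
  params <- c(.netParams(model@extractor), .netParams(model@labelHead),
              .netParams(model@domainHead))
  isW <- c(.netIsWeight(model@extractor), .netIsWeight(model@labelHead),
           .netIsWeight(model@domainHead))
  nf <- length(.netParams(model@extractor))
  ny <- length(.netParams(model@labelHead))
  opt <- .optInit(cfg@optimizer, params)
  hasVal <- ncol(split@validation) > 0L
  va <- if (hasVal) .splitTensors(split, "validation")
  hist <- data.frame(epoch = seq_len(cfg@epochs), labelLoss = NA_real_,
                     domainLoss = NA_real_, objective = NA_real_,
                     valAccuracy = NA_real_, valAccuracyMouse = NA_real_,
                     valAccuracyHuman = NA_real_)
  best <- -Inf
  bestParams <- params
  unpack <- function(params) {
    model@extractor <- .setNetParams(model@extractor, params[seq_len(nf)])
    model@labelHead <- .setNetParams(model@labelHead,
                                     params[nf + seq_len(ny)])
    model@domainHead <- .setNetParams(model@domainHead,
                                      params[nf + ny + seq_len(ny)])
    model
  }
  for (epoch in seq_len(cfg@epochs)) {
    lam <- .lambdaAt(cfg, epoch)
    sly <- sld <- 0
    for (b in .miniBatches(n, cfg@batchSize)) {
      model <- unpack(params)
      g <- .dannGrads(model, tr$x[b, , drop = FALSE], tr$y[b], tr$d[b],
                      lam, dropout = cfg@dropout, training = TRUE,
                      labelMask = labelMask[b],
                      domainWeights = domainW[b])
      grads <- c(g$gradF, g$gradY, lapply(g$gradD, function(t) lam * t))
      grads <- .clipGrads(grads, cfg@clipNorm)
      st <- .optStep(opt, params, grads, cfg@learningRate, cfg@weightDecay,
                     isW)
      opt <- st$opt
      params <- st$params
      sly <- sly + g$labelLoss * length(b)
      sld <- sld + g$domainLoss * length(b)
    }
    hist$labelLoss[epoch] <- sly / n
    hist$domainLoss[epoch] <- sld / n
    hist$objective[epoch] <- hist$labelLoss[epoch] -
      lam * hist$domainLoss[epoch]
    if (hasVal) {
      model <- unpack(params)
      pred <- predictBroad(model, va$x)
      acc <- mean(pred == va$y - 1L)
      hist$valAccuracy[epoch] <- acc
      for (dd in 1:2) {
        rows <- va$d == dd
        if (any(rows)) {
          col <- if (dd == 1L) "valAccuracyMouse" else "valAccuracyHuman"
          hist[[col]][epoch] <- mean(pred[rows] == va$y[rows] - 1L)
        }
      }
      if (cfg@checkpoint == "best" && acc > best) {
        best <- acc
        bestParams <- params
      }
    }
  }
  model <- unpack(if (cfg@checkpoint == "best" && hasVal) bestParams
                  else params)
  list(model = model, history = hist)
}

#' Predict broad type / extract embeddings
#'
#' `predictBroad()` returns the argmax of the label head (0 = excitatory,
#' 1 = inhibitory; ties resolve to the lower class index).
#' `embedFeatures()` returns the extractor output `G_f(x)`, the
#' representation used for domain-invariance diagnostics.
#'
#' @param model a [DANNModel-class].
#' @param x numeric matrix (normalized with the training statistics) or an
#'   [EphysSet-class].
#' @return integer labels, or a matrix of embeddings.
#' @export
predictBroad <- function(model, x) {
  if (is(x, "EphysSet")) x <- featureMatrix(x)
  x <- .checkBatch(model, x)
  H <- .mlpForward(model@extractor, x)$out
  .argmax0(.mlpForward(model@labelHead, H)$out)
}

#' @rdname predictBroad
#' @export
embedFeatures <- function(model, x) {
  if (is(x, "EphysSet")) x <- featureMatrix(x)
  x <- .checkBatch(model, x)
  .mlpForward(model@extractor, x)$out
}

# hyperparameter search ------------------------------------------------------

#' The hyperparameter search grid
#'
#' The searched space for the broad-type classifier: weight decay in
#' \[1e-4, 1\] (log-uniform), six architectures of 3-4 hidden layers,
#' per-layer activations from relu/selu/swish, learning rate in
#' \[0.001, 0.2\] (log-uniform), dropout in \[0, 0.5\], batch size 32 or 64,
#' epochs 500/1000/1500/2000, optimizer SGD/RMSProp/Adam. The adversarial
#' weight lambda is searched over a small candidate set (it is a free
#' hyperparameter of the method).
#'
#' Any entry may be overridden, e.g. a reduced `epochs` set for quick
#' exploratory searches.
#'
#' @param ... named overrides of the default entries.
#' @return a named list describing the space.
#' @export
dannSearchSpace <- function(...) {
  space <- list(
    architectures = list(c(64L, 32L, 16L), c(32L, 16L, 8L),
                         c(64L, 32L, 16L, 8L), c(128L, 64L, 32L),
                         c(50L, 30L, 10L), c(40L, 20L, 10L, 5L)),
    activations = c("relu", "selu", "swish"),
    learningRate = c(0.001, 0.2),
    dropout = c(0, 0.5),
    weightDecay = c(1e-4, 1),
    batchSize = c(32L, 64L),
    epochs = c(500L, 1000L, 1500L, 2000L),
    optimizer = c("sgd", "rmsprop", "adam"),
    lambda = c(0, 0.1, 0.3, 1, 3))
  override <- list(...)
  space[names(override)] <- override
  space
}

.logUnif <- function(lo, hi) exp(stats::runif(1L, log(lo), log(hi)))

#' Sample configurations from the search grid
#'
#' @param space a [dannSearchSpace()] list.
#' @param n number of configurations.
#' @param seed integer seed.
#' @return list of [DANNConfig-class] objects.
#' @export
sampleDANNConfigs <- function(space = dannSearchSpace(), n = 1L, seed = 1L) {
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    hidden <- space$architectures[[sample.int(length(space$architectures), 1L)]]
    dannConfig(
      hidden = hidden,
      activations = sample(space$activations, length(hidden), replace = TRUE),
      lambda = sample(space$lambda, 1L),
      learningRate = .logUnif(space$learningRate[1L], space$learningRate[2L]),
      dropout = stats::runif(1L, space$dropout[1L], space$dropout[2L]),
      weightDecay = .logUnif(space$weightDecay[1L], space$weightDecay[2L]),
      batchSize = sample(space$batchSize, 1L),
      epochs = sample(space$epochs, 1L),
      optimizer = sample(space$optimizer, 1L),
      seed = sample.int(.Machine$integer.max %/% 2L, 1L))
  })
}

#' Seeded random hyperparameter search
#'
#' Samples `budget` configurations from the grid, trains each on the split,
#' and returns the configuration with the highest overall validation label
#' accuracy (target-domain validation accuracy breaks ties).
#'
#' @param space a [dannSearchSpace()] list.
#' @param budget number of trials, >= 1.
#' @param seed integer seed driving both sampling and training.
#' @param split a normalized [EphysSplit-class] with a validation partition.
#' @return list with `config` (the winning [DANNConfig-class]), `model`, and
#'   `trials` (a data.frame of per-trial validation scores).
#' @export
randomSearchDANN <- function(space = dannSearchSpace(), budget, seed, split) {
  if (budget < 1L) stop("budget must be >= 1")
  cfgs <- sampleDANNConfigs(space, n = budget, seed = seed)
  trials <- data.frame(trial = seq_len(budget), valAccuracy = NA_real_,
                       valAccuracyHuman = NA_real_)
  bestFit <- NULL
  bestCfg <- NULL
  for (i in seq_len(budget)) {
    fit <- trainDANN(cfgs[[i]], split)
    last <- fit$history[nrow(fit$history), ]
    trials$valAccuracy[i] <- last$valAccuracy
    trials$valAccuracyHuman[i] <- last$valAccuracyHuman
    better <- is.null(bestCfg) ||
      last$valAccuracy > max(trials$valAccuracy[seq_len(i - 1L)]) ||
      (last$valAccuracy == max(trials$valAccuracy[seq_len(i - 1L)]) &&
         isTRUE(last$valAccuracyHuman >
                  trials$valAccuracyHuman[which.max(
                    trials$valAccuracy[seq_len(i - 1L)])]))
    if (better) {
      bestFit <- fit
      bestCfg <- cfgs[[i]]
    }
  }
  list(config = bestCfg, model = bestFit$model, trials = trials)
}
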