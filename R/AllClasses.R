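#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData colData<-
NULL

# canonical label sets ------------------------------------------------------

.ORGANISMS <- c("mouse", "human")
.SUBCLASS_LEVELS <- c("Glutamatergic", "Pvalb", "Htr3a+|Vip-", "Sst", "Vip")
.EXCITATORY_CLASSES <- c("excitatory", "Glutamatergic")

#' Per-neuron electrophysiological feature table
#'
#' `EphysSet` is a [SummarizedExperiment::SummarizedExperiment] holding one
#' assay `"features"` (features x samples) and per-sample annotations in
#' `colData`: `organism` (`"mouse"` or `"human"`), `broad_label` (0 =
#' excitatory, 1 = inhibitory, possibly `NA`), `line_tag` (transgenic line,
#' possibly `NA`) and `subclass_label` (one of Glutamatergic, Pvalb,
#' Htr3a+|Vip-, Sst, Vip, possibly `NA`).
#'
#' @export
setClass("EphysSet", contains = "SummarizedExperiment")

setValidity("EphysSet", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  cd <- colData(object)
  for (col in c("organism", "broad_label", "line_tag", "subclass_label"))
    if (!col %in% colnames(cd))
      msg <- c(msg, sprintf("colData column '%s' is required", col))
  if ("organism" %in% colnames(cd)) {
    org <- cd$organism
    if (anyNA(org) || !all(org %in% .ORGANISMS))
      msg <- c(msg, "organism must be 'mouse' or 'human' for every sample")
  }
  if ("broad_label" %in% colnames(cd)) {
    bl <- cd$broad_label
    if (!all(bl[!is.na(bl)] %in% c(0L, 1L)))
      msg <- c(msg, "broad_label must be 0, 1 or NA")
  }
  if ("subclass_label" %in% colnames(cd)) {
    sc <- cd$subclass_label
    if (!all(sc[!is.na(sc)] %in% .SUBCLASS_LEVELS))
      msg <- c(msg, sprintf("subclass_label must be one of: %s",
                            paste(.SUBCLASS_LEVELS, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EphysSet
#'
#' @param features numeric matrix, samples x features (it is transposed into
#'   the features x samples assay layout internally).
#' @param organism character vector, `"mouse"` or `"human"` per sample.
#' @param broadLabel integer vector (0 = excitatory, 1 = inhibitory) or `NA`.
#' @param lineTag optional character vector of transgenic-line tags.
#' @param subclassLabel optional character vector of subclass names.
#' @param sampleIds optional sample identifiers (default from rownames or
#'   generated).
#' @return an [EphysSet-class] object.
#' @examples
#' es <- EphysSet(matrix(rnorm(20), 4, 5), organism = rep("mouse", 4),
#'                broadLabel = c(0, 0, 1, 1))
#' @export
EphysSet <- function(features, organism, broadLabel = NA_integer_,
                     lineTag = NA_character_, subclassLabel = NA_character_,
                     sampleIds = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(features))) rownames(features)
                 else sprintf("s%05d", seq_len(n))
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("f%02d", seq_len(ncol(features)) - 1L)
  cd <- DataFrame(
    organism = rep_len(as.character(organism), n),
    broad_label = rep_len(as.integer(broadLabel), n),
    line_tag = rep_len(as.character(lineTag), n),
    subclass_label = rep_len(as.character(subclassLabel), n),
    row.names = sampleIds)
  se <- SummarizedExperiment(assays = list(features = t(features)),
                             colData = cd)
  new("EphysSet", se)
}

#' Domain shift specification
#'
#' Per-feature affine transform `x -> scale * x + offset` applied to the rows
#' of one organism, optionally with an extra per-broad-label offset.
#'
#' @slot offset numeric offset vector (recycled across features).
#' @slot scale numeric scale vector, strictly positive.
#' @slot domain organism receiving the shift (`"human"` by default).
#' @slot labelOffset `NULL`, or a named list mapping broad label ("0"/"1") to
#'   an extra offset vector, for a label-conditional shift component.
#' @export
setClass("DomainShiftSpec",
  representation(offset = "numeric", scale = "numeric", domain = "character",
                 labelOffset = "ANY"),
  prototype(offset = 0, scale = 1, domain = "human", labelOffset = NULL))

setValidity("DomainShiftSpec", function(object) {
  msg <- character()
  if (any(!is.finite(object@scale)) || any(object@scale <= 0))
    msg <- c(msg, "scale entries must be finite and > 0")
  if (length(object@domain) != 1L || !object@domain %in% .ORGANISMS)
    msg <- c(msg, "domain must be a single organism label")
  if (!is.null(object@labelOffset) && !is.list(object@labelOffset))
    msg <- c(msg, "labelOffset must be NULL or a named list")
  if (length(msg)) msg else TRUE
})

#' @param offset,scale numeric vectors (or scalars) defining the affine map.
#' @param domain which organism is shifted.
#' @param labelOffset optional named list ("0"/"1") of extra offsets.
#' @rdname DomainShiftSpec-class
#' @export
domainShiftSpec <- function(offset = 0, scale = 1, domain = "human",
                            labelOffset = NULL) {
  new("DomainShiftSpec", offset = offset, scale = scale, domain = domain,
      labelOffset = labelOffset)
}

#' Synthetic cohort configuration
#'
#' Defines a seeded two-organism cohort with known per-class informative
#' features and a controllable domain shift. Features are standard-normal
#' noise of sd `noiseSd`; each class's mean is offset by
#' `classEffectSize * noiseSd` on that class's informative features only, so
#' class signal is local by construction.
#'
#' @slot counts data.frame with columns `domain`, `class`, `n`.
#' @slot dFeatures number of features (default 41).
#' @slot informativeSets named list: class -> 0-based informative feature
#'   indices.
#' @slot classEffectSize mean offset on informative features, in within-class
#'   standard-deviation units.
#' @slot shift a [DomainShiftSpec-class].
#' @slot noiseSd within-class feature standard deviation, > 0.
#' @slot missingRate per-cell completely-at-random missingness rate in [0,1).
#' @slot seed integer seed; identical configs generate identical cohorts.
#' @export
setClass("SyntheticConfig",
  representation(counts = "data.frame", dFeatures = "integer",
                 informativeSets = "list", classEffectSize = "numeric",
                 shift = "DomainShiftSpec", noiseSd = "numeric",
                 missingRate = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  cnt <- object@counts
  if (!all(c("domain", "class", "n") %in% colnames(cnt)))
    msg <- c(msg, "counts must have columns domain, class, n")
  else {
    if (any(cnt$n < 0) || any(cnt$n != floor(cnt$n)))
      msg <- c(msg, "counts: n must be non-negative integers")
    if (sum(cnt$n) <= 0)
      msg <- c(msg, "counts: total number of samples must be > 0")
    if (!all(cnt$domain %in% .ORGANISMS))
      msg <- c(msg, "counts: domain must be 'mouse' or 'human'")
  }
  if (object@dFeatures < 1L)
    msg <- c(msg, "dFeatures must be >= 1")
  for (cls in names(object@informativeSets)) {
    s <- object@informativeSets[[cls]]
    if (length(s) && (any(s < 0) || any(s >= object@dFeatures)))
      msg <- c(msg, sprintf(
        "informativeSets['%s'] must be 0-based indices below dFeatures", cls))
  }
  if (object@classEffectSize != 0 && nrow(object@counts) > 0) {
    for (cls in unique(object@counts$class))
      if (!length(object@informativeSets[[cls]]))
        msg <- c(msg, sprintf(
          "informativeSets: empty informative set for class '%s' with nonzero classEffectSize", cls))
  }
  if (!is.finite(object@noiseSd) || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic cohort
#'
#' @slot sampleId,domain,classLabel per-sample truth.
#' @slot informativeSets per-class 0-based informative feature indices.
#' @slot shift the [DomainShiftSpec-class] that was applied.
#' @slot missingRows logical; TRUE where a row contains >= 1 missing cell.
#' @export
setClass("GroundTruth",
  representation(sampleId = "character", domain = "character",
                 classLabel = "character", informativeSets = "list",
                 shift = "DomainShiftSpec", missingRows = "logical"))

setValidity("GroundTruth", function(object) {
  n <- length(object@sampleId)
  if (length(object@domain) != n || length(object@classLabel) != n ||
      length(object@missingRows) != n)
    "per-sample slots must have equal length" else TRUE
})

#' Train/validation/test split of an EphysSet
#'
#' Partitions are disjoint and exhaustive; normalization statistics (per
#' feature mean and sd) are computed on the train partition only and applied
#' unchanged to validation and test.
#'
#' @slot train,validation,test [EphysSet-class] partitions.
#' @slot center,scale per-feature normalization statistics (empty before
#'   [normalizeSplit()]).
#' @slot normalized logical flag.
#' @slot fractions,stratifyOn,seed the split request that produced this.
#' @export
setClass("EphysSplit",
  representation(train = "EphysSet", validation = "EphysSet",
                 test = "EphysSet", center = "numeric", scale = "numeric",
                 normalized = "logical", fractions = "numeric",
                 stratifyOn = "character", seed = "integer"))

#' Domain-adversarial network configuration
#'
#' @slot hidden integer vector of extractor hidden-layer widths.
#' @slot headHidden hidden widths of the label and domain heads
#'   (`integer(0)` = linear heads). A nonlinear domain head is a stronger
#'   adversary and yields stronger representation invariance.
#' @slot activations per-layer activation, each of "relu", "selu", "swish".
#' @slot lambda adversarial weight (>= 0) multiplying the reversed domain
#'   gradient.
#' @slot learningRate learning rate mu, in (0, 0.2].
#' @slot dropout extractor dropout rate in [0, 0.5].
#' @slot weightDecay L2 penalty coefficient in [0, 1].
#' @slot batchSize minibatch size.
#' @slot epochs number of training epochs.
#' @slot optimizer one of "sgd", "rmsprop", "adam".
#' @slot lambdaSchedule "fixed" (default) or "ramp"
#'   (`lambda * (2/(1+exp(-10 p)) - 1)` with p the epoch fraction).
#' @slot useTargetLabels if TRUE (default) both organisms' labels enter the
#'   label loss; FALSE gives strictly unsupervised adaptation on the target.
#' @slot checkpoint "final" (default) or "best" validation label accuracy.
#' @slot clipNorm global gradient-norm clip applied per minibatch (default 5;
#'   `Inf` disables). Stabilizes the saddle-point updates at large lambda.
#' @slot domainWeighting "none" (default) or "balanced": inverse-frequency
#'   sample weights in the domain loss, so the scarce organism contributes
#'   equally to the adversarial signal.
#' @slot seed integer seed for initialization, shuffling and dropout.
#' @export
setClass("DANNConfig",
  representation(hidden = "integer", headHidden = "integer",
                 activations = "character",
                 lambda = "numeric", learningRate = "numeric",
                 dropout = "numeric", weightDecay = "numeric",
                 batchSize = "integer", epochs = "integer",
                 optimizer = "character", lambdaSchedule = "character",
                 useTargetLabels = "logical", checkpoint = "character",
                 clipNorm = "numeric", domainWeighting = "character",
                 seed = "integer"))

setValidity("DANNConfig", function(object) {
  msg <- character()
  if (length(object@hidden) < 1L || any(object@hidden < 1L))
    msg <- c(msg, "hidden must be positive layer widths")
  if (length(object@activations) != length(object@hidden))
    msg <- c(msg, "activations must match the number of hidden layers")
  if (!all(object@activations %in% c("relu", "selu", "swish", "tanh")))
    msg <- c(msg, "activations must be relu, selu, swish or tanh")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (object@learningRate <= 0 || object@learningRate > 0.2)
    msg <- c(msg, "learningRate must lie in (0, 0.2]")
  if (object@dropout < 0 || object@dropout > 0.5)
    msg <- c(msg, "dropout must lie in [0, 0.5]")
  if (object@weightDecay < 0 || object@weightDecay > 1)
    msg <- c(msg, "weightDecay must lie in [0, 1]")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (!object@optimizer %in% c("sgd", "rmsprop", "adam"))
    msg <- c(msg, "optimizer must be sgd, rmsprop or adam")
  if (!object@lambdaSchedule %in% c("fixed", "ramp"))
    msg <- c(msg, "lambdaSchedule must be fixed or ramp")
  if (!object@checkpoint %in% c("final", "best"))
    msg <- c(msg, "checkpoint must be final or best")
  if (is.na(object@clipNorm) || object@clipNorm <= 0)
    msg <- c(msg, "clipNorm must be > 0 (Inf disables clipping)")
  if (!object@domainWeighting %in% c("none", "balanced"))
    msg <- c(msg, "domainWeighting must be none or balanced")
  if (length(msg)) msg else TRUE
})

#' Trained domain-adversarial model
#'
#' Holds the feature extractor G_f (weights theta_f), the 2-class label head
#' G_y (theta_y) and the 2-domain head G_d (theta_d). Both heads consume only
#' the extractor output; inference is deterministic (dropout disabled).
#'
#' @slot extractor,labelHead,domainHead internal layer lists (weights,
#'   biases, activations).
#' @slot config the [DANNConfig-class] used for training.
#' @slot dIn input feature count.
#' @export
setClass("DANNModel",
  representation(extractor = "list", labelHead = "list", domainHead = "list",
                 config = "DANNConfig", dIn = "integer"))

#' Locally sparse network configuration
#'
#' Defaults are the fitted five-subclass configuration: prediction network
#' 41-40-20-5 and gating network of 3 x 50 units, tanh activations,
#' lambda1 = 0.01047, lambda2 = 0, sigma = 0.5, learning rate 0.0599,
#' 1000 epochs of SGD.
#'
#' @slot gatingHidden gating-network hidden widths (default 50, 50, 50).
#' @slot predictionHidden prediction-network hidden widths (default 40, 20).
#' @slot activation activation for both networks (default "tanh").
#' @slot sigma gate noise sd during training (must be > 0; inference uses 0).
#' @slot lambda1 sparsity weight on the expected open-gate count.
#' @slot lambda2 gate-smoothness weight; its kernel is an RBF on the input
#'   features with median-heuristic bandwidth unless `kernelBandwidth` is set.
#' @slot kernelBandwidth RBF bandwidth (NA = median heuristic per batch).
#' @slot learningRate,epochs,batchSize,optimizer,seed training settings.
#' @export
setClass("LSPINConfig",
  representation(gatingHidden = "integer", predictionHidden = "integer",
                 activation = "character", sigma = "numeric",
                 lambda1 = "numeric", lambda2 = "numeric",
                 kernelBandwidth = "numeric", learningRate = "numeric",
                 epochs = "integer", batchSize = "integer",
                 optimizer = "character", seed = "integer"))

setValidity("LSPINConfig", function(object) {
  msg <- character()
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (object@lambda1 < 0 || object@lambda2 < 0)
    msg <- c(msg, "lambda1 and lambda2 must be >= 0")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (!object@optimizer %in% c("sgd", "rmsprop", "adam"))
    msg <- c(msg, "optimizer must be sgd, rmsprop or adam")
  if (length(msg)) msg else TRUE
})

#' Trained locally sparse (gated) classifier
#'
#' @slot gatingNet gating network psi (weights Omega) predicting per-sample
#'   gate parameters mu.
#' @slot predictionNet prediction network f_theta on gated inputs.
#' @slot config the [LSPINConfig-class] used.
#' @slot classLevels class labels in output order.
#' @slot dIn input feature count.
#' @export
setClass("LSPINModel",
  representation(gatingNet = "list", predictionNet = "list",
                 config = "LSPINConfig", classLevels = "character",
                 dIn = "integer"))

#' Classification metrics report
#'
#' Confusion counts (rows = true class, columns = predicted) with accuracy,
#' per-class precision/recall/F1, their macro (unweighted) means, and
#' risk = 1 - accuracy (the empirical target risk when computed on the
#' target-domain test partition).
#'
#' @slot confusion true x predicted count matrix.
#' @slot accuracy,risk scalars.
#' @slot precision,recall,f1 per-class vectors (0/0 defined as 0).
#' @slot macroPrecision,macroRecall,macroF1 unweighted class means.
#' @export
setClass("MetricsReport",
  representation(confusion = "matrix", accuracy = "numeric",
                 precision = "numeric", recall = "numeric", f1 = "numeric",
                 macroPrecision = "numeric", macroRecall = "numeric",
                 macroF1 = "numeric", risk = "numeric"))

setValidity("MetricsReport", function(object) {
  m <- object@confusion
  if (nrow(m) != ncol(m)) return("confusion matrix must be square")
  if (any(m < 0)) return("confusion counts must be non-negative")
  TRUE
})
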