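# generics and accessors ----------------------------------------------------

#' Feature matrix of an EphysSet
#'
#' Returns the samples x features numeric matrix (the transpose of the
#' internal assay layout).
#'
#' @param x an [EphysSet-class].
#' @return numeric matrix, one row per neuron.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "EphysSet", function(x) t(assay(x, "features")))

#' Sample annotation accessors
#'
#' `organismLabel()`, `broadLabel()`, `lineTag()` and `subclassLabel()`
#' return the per-sample annotation vectors of an [EphysSet-class].
#'
#' @param x an [EphysSet-class].
#' @return a vector with one entry per sample.
#' @name ephys-accessors
NULL

#' @rdname ephys-accessors
#' @export
setGeneric("organismLabel", function(x) standardGeneric("organismLabel"))
#' @rdname ephys-accessors
#' @export
setMethod("organismLabel", "EphysSet", function(x) colData(x)$organism)

#' @rdname ephys-accessors
#' @export
setGeneric("broadLabel", function(x) standardGeneric("broadLabel"))
#' @rdname ephys-accessors
#' @export
setMethod("broadLabel", "EphysSet", function(x) colData(x)$broad_label)

#' @rdname ephys-accessors
#' @export
setGeneric("lineTag", function(x) standardGeneric("lineTag"))
#' @rdname ephys-accessors
#' @export
setMethod("lineTag", "EphysSet", function(x) colData(x)$line_tag)

#' @rdname ephys-accessors
#' @export
setGeneric("subclassLabel", function(x) standardGeneric("subclassLabel"))
#' @rdname ephys-accessors
#' @export
setMethod("subclassLabel", "EphysSet", function(x) colData(x)$subclass_label)

#' Number of samples in an EphysSet
#'
#' @param x an [EphysSet-class].
#' @return integer count of neurons (assay columns).
#' @export
nSamples <- function(x) ncol(x)

# show methods ---------------------------------------------------------------

setMethod("show", "EphysSet", function(object) {
  org <- table(organismLabel(object))
  cat(sprintf("EphysSet: %d neurons x %d features\n",
              ncol(object), nrow(object)))
  cat("  organisms:", paste(sprintf("%s=%d", names(org), org),
                            collapse = ", "), "\n")
  bl <- broadLabel(object)
  if (any(!is.na(bl)))
    cat(sprintf("  broad labels: excitatory=%d inhibitory=%d NA=%d\n",
                sum(bl == 0L, na.rm = TRUE), sum(bl == 1L, na.rm = TRUE),
                sum(is.na(bl))))
  sc <- subclassLabel(object)
  if (any(!is.na(sc))) {
    tb <- table(factor(sc, levels = .SUBCLASS_LEVELS))
    cat("  subclasses:", paste(sprintf("%s=%d", names(tb), tb),
                               collapse = ", "), "\n")
  }
})

setMethod("show", "EphysSplit", function(object) {
  cat(sprintf("EphysSplit: train=%d validation=%d test=%d (%s)\n",
              ncol(object@train), ncol(object@validation),
              ncol(object@test),
              if (object@normalized) "normalized" else "raw"))
  cat("  stratified on:", paste(object@stratifyOn, collapse = " x "), "\n")
})

setMethod("show", "DANNModel", function(object) {
  cfg <- object@config
  cat(sprintf("DANNModel: extractor %s (%s), 2-class label head, 2-domain head\n",
              paste(c(object@dIn, cfg@hidden), collapse = "-"),
              paste(cfg@activations, collapse = "/")))
  cat(sprintf("  lambda=%.4g lr=%.4g optimizer=%s epochs=%d\n",
              cfg@lambda, cfg@learningRate, cfg@optimizer, cfg@epochs))
})

setMethod("show", "LSPINModel", function(object) {
  cfg <- object@config
  cat(sprintf("LSPINModel: gating %s, prediction %s (%s)\n",
              paste(c(object@dIn, cfg@gatingHidden, object@dIn),
                    collapse = "-"),
              paste(c(object@dIn, cfg@predictionHidden,
                      length(object@classLevels)), collapse = "-"),
              cfg@activation))
  cat(sprintf("  sigma=%.3g lambda1=%.5g lambda2=%.3g lr=%.4g epochs=%d\n",
              cfg@sigma, cfg@lambda1, cfg@lambda2, cfg@learningRate,
              cfg@epochs))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: accuracy=%.4f risk=%.4f\n",
              object@accuracy, object@risk))
  cat(sprintf("  macro precision=%.4f recall=%.4f F1=%.4f\n",
              object@macroPrecision, object@macroRecall, object@macroF1))
  cat("  confusion (rows = true):\n")
  print(object@confusion)
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf("SyntheticConfig: %d samples, %d features, effect=%.2g, seed=%d\n",
              sum(object@counts$n), object@dFeatures,
              object@classEffectSize, object@seed))
  print(object@counts)
})

# metrics accessors ----------------------------------------------------------

#' Accessors for MetricsReport
#'
#' @param x a [MetricsReport-class].
#' @return the requested component.
#' @name metrics-accessors
NULL

#' @rdname metrics-accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
#' @rdname metrics-accessors
#' @export
setMethod("accuracy", "MetricsReport", function(x) x@accuracy)

#' @rdname metrics-accessors
#' @export
setGeneric("macroF1", function(x) standardGeneric("macroF1"))
#' @rdname metrics-accessors
#' @export
setMethod("macroF1", "MetricsReport", function(x) x@macroF1)

#' @rdname metrics-accessors
#' @export
setGeneric("confusionMatrixOf", function(x) standardGeneric("confusionMatrixOf"))
#' @rdname metrics-accessors
#' @export
setMethod("confusionMatrixOf", "MetricsReport", function(x) x@confusion)

#' @rdname metrics-accessors
#' @export
setGeneric("risk", function(x) standardGeneric("risk"))
#' @rdname metrics-accessors
#' @export
setMethod("risk", "MetricsReport", function(x) x@risk)
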