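# Accessor generics and show methods. Slots are never accessed directly by
# user code; these accessors are the supported surface.

#' @name hiwcf-accessors
#' @title Accessors for hiwcf classes
#' @description Small accessor functions for the package's S4 containers.
#' @param x,object an object of the documented class.
#' @param ... unused.
#' @return The requested component.
NULL

#' @rdname hiwcf-accessors
#' @export
setGeneric("responseValues", function(x, ...) standardGeneric("responseValues"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("isObserved", function(x, ...) standardGeneric("isObserved"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("cellLines", function(x, ...) standardGeneric("cellLines"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("drugs", function(x, ...) standardGeneric("drugs"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("measureType", function(x, ...) standardGeneric("measureType"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("exprValues", function(x, ...) standardGeneric("exprValues"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("genes", function(x, ...) standardGeneric("genes"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("fingerprintValues", function(x, ...) standardGeneric("fingerprintValues"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("fingerprintName", function(x, ...) standardGeneric("fingerprintName"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("simValues", function(x, ...) standardGeneric("simValues"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("simSupport", function(x, ...) standardGeneric("simSupport"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("simAxis", function(x, ...) standardGeneric("simAxis"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("simDefinition", function(x, ...) standardGeneric("simDefinition"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("simStage", function(x, ...) standardGeneric("simStage"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("globalMean", function(x, ...) standardGeneric("globalMean"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("cellBias", function(x, ...) standardGeneric("cellBias"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("drugBias", function(x, ...) standardGeneric("drugBias"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("predictedEntries", function(x, ...) standardGeneric("predictedEntries"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("foldIds", function(x, ...) standardGeneric("foldIds"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("drugMetrics", function(x, ...) standardGeneric("drugMetrics"))
#' @rdname hiwcf-accessors
#' @export
setGeneric("cvSummary", function(x, ...) standardGeneric("cvSummary"))

#' @rdname hiwcf-accessors
#' @export
setMethod("responseValues", "ResponseMatrix", function(x, ...) x@values)
#' @rdname hiwcf-accessors
#' @export
setMethod("isObserved", "ResponseMatrix", function(x, ...) x@mask)
#' @rdname hiwcf-accessors
#' @export
setMethod("cellLines", "ResponseMatrix", function(x, ...) rownames(x@values))
#' @rdname hiwcf-accessors
#' @export
setMethod("drugs", "ResponseMatrix", function(x, ...) colnames(x@values))
#' @rdname hiwcf-accessors
#' @export
setMethod("measureType", "ResponseMatrix", function(x, ...) x@measure)
#' @rdname hiwcf-accessors
#' @export
setMethod("dim", "ResponseMatrix", function(x) dim(x@values))

#' @rdname hiwcf-accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x, ...) x@values)
#' @rdname hiwcf-accessors
#' @export
setMethod("genes", "ExpressionMatrix", function(x, ...) rownames(x@values))
#' @rdname hiwcf-accessors
#' @export
setMethod("cellLines", "ExpressionMatrix", function(x, ...) colnames(x@values))

#' @rdname hiwcf-accessors
#' @export
setMethod("fingerprintValues", "FingerprintMatrix", function(x, ...) x@values)
#' @rdname hiwcf-accessors
#' @export
setMethod("drugs", "FingerprintMatrix", function(x, ...) rownames(x@values))
#' @rdname hiwcf-accessors
#' @export
setMethod("fingerprintName", "FingerprintMatrix", function(x, ...) x@fingerprintName)

#' @rdname hiwcf-accessors
#' @export
setMethod("simValues", "SimilarityMatrix", function(x, ...) x@values)
#' @rdname hiwcf-accessors
#' @export
setMethod("simSupport", "SimilarityMatrix", function(x, ...) x@support)
#' @rdname hiwcf-accessors
#' @export
setMethod("simAxis", "SimilarityMatrix", function(x, ...) x@axis)
#' @rdname hiwcf-accessors
#' @export
setMethod("simDefinition", "SimilarityMatrix", function(x, ...) x@definition)
#' @rdname hiwcf-accessors
#' @export
setMethod("simStage", "SimilarityMatrix", function(x, ...) x@stage)

#' @rdname hiwcf-accessors
#' @export
setMethod("globalMean", "BaselineModel", function(x, ...) x@mu)
#' @rdname hiwcf-accessors
#' @export
setMethod("cellBias", "BaselineModel", function(x, ...) x@bCell)
#' @rdname hiwcf-accessors
#' @export
setMethod("drugBias", "BaselineModel", function(x, ...) x@bDrug)

#' @rdname hiwcf-accessors
#' @export
setMethod("predictedEntries", "PredictionResult", function(x, ...) x@entries)

#' @rdname hiwcf-accessors
#' @export
setMethod("foldIds", "FoldAssignment", function(x, ...)
  data.frame(cell = x@cell, drug = x@drug, fold = x@fold))

#' @rdname hiwcf-accessors
#' @export
setMethod("drugMetrics", "CVReport", function(x, ...) x@drugMetrics)
#' @rdname hiwcf-accessors
#' @export
setMethod("cvSummary", "CVReport", function(x, ...) x@summary)

#' @describeIn hiwcf-accessors coerce predictions to a data.frame
#' @export
setMethod("as.data.frame", "PredictionResult",
  function(x, ...) x@entries)

setMethod("show", "ResponseMatrix", function(object) {
  d <- dim(object@values)
  obs <- sum(object@mask)
  cat(sprintf("ResponseMatrix: %d cell lines x %d drugs (%s)\n",
              d[1L], d[2L], object@measure))
  cat(sprintf("  observed: %d / %d entries (%.1f%% complete)\n",
              obs, prod(d), 100 * obs / prod(d)))
})

setMethod("show", "ExpressionMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("ExpressionMatrix: %d genes x %d cell lines\n", d[1L], d[2L]))
})

setMethod("show", "FingerprintMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("FingerprintMatrix: %d drugs x %d bits (%s)\n",
              d[1L], d[2L], object@fingerprintName))
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix: %d x %d %ss, definition=%s, stage=%s\n",
              nrow(object@values), ncol(object@values),
              sub("_", " ", object@axis), object@definition, object@stage))
})

setMethod("show", "BaselineModel", function(object) {
  cat(sprintf("BaselineModel: mu=%.4f, %d cell-line biases, %d drug biases\n",
              object@mu, length(object@bCell), length(object@bDrug)))
  cat(sprintf("  lambda_drug=%g, lambda_cell=%g\n",
              object@lambdaDrug, object@lambdaCell))
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult: %d entries (%d baseline fallbacks)\n",
              nrow(object@entries), sum(object@entries$fallback)))
})

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d entries in %d folds (seed %d)\n",
              length(object@fold), object@folds, object@seed))
})

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport: %d drugs x %d repetition(s)\n",
              length(unique(object@drugMetrics$drug)),
              length(object@seeds)))
  print(object@summary, row.names = FALSE)
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: mu0=%.3f, %d cell lines, %d drugs, rank %d\n",
              object@mu0, length(object@bCell), length(object@bDrug),
              ncol(object@cellFactors)))
})
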