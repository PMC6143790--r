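#' @import methods
NULL

.MEASURES <- c("ic50_log", "activity_area")
.SIM_AXES <- c("cell_line", "drug")
.SIM_DEFINITIONS <- c("coef", "rpcc", "mrpcc")
.SIM_STAGES <- c("raw", "shrunk", "amplified")

.checkLabelled <- function(x, what) {
  msgs <- character()
  if (!is.matrix(x) || !is.numeric(x))
    return(sprintf("%s must be a numeric matrix", what))
  dn <- dimnames(x)
  if (is.null(dn) || is.null(dn[[1L]]) || is.null(dn[[2L]]))
    msgs <- c(msgs, sprintf("%s must have row and column names", what))
  else {
    if (anyDuplicated(dn[[1L]]))
      msgs <- c(msgs, sprintf("duplicated row labels in %s: %s", what,
                              paste(unique(dn[[1L]][duplicated(dn[[1L]])]), collapse = ", ")))
    if (anyDuplicated(dn[[2L]]))
      msgs <- c(msgs, sprintf("duplicated column labels in %s: %s", what,
                              paste(unique(dn[[2L]][duplicated(dn[[2L]])]), collapse = ", ")))
  }
  msgs
}

#' ResponseMatrix: a partially observed cell-line x drug sensitivity matrix
#'
#' Stores the m x n real-valued response matrix (rows = cell lines, columns =
#' drugs), a logical mask of the same shape marking which entries were actually
#' measured, and the sensitivity measure the values are on. Values at
#' unobserved positions are ignored by every downstream computation.
#'
#' @slot values numeric matrix, cell lines x drugs, with dimnames.
#' @slot mask logical matrix of the same shape; `TRUE` = observed.
#' @slot measure `"ic50_log"` (natural-log IC50 in uM; lower = more sensitive)
#'   or `"activity_area"` (higher = more sensitive).
#' @seealso [ResponseMatrix()], [readResponseMatrix()]
#' @name ResponseMatrix-class
#' @aliases ResponseMatrix-class
#' @exportClass ResponseMatrix
setClass("ResponseMatrix",
  slots = c(values = "matrix", mask = "matrix", measure = "character"))

setValidity("ResponseMatrix", function(object) {
  msgs <- .checkLabelled(object@values, "values")
  if (!is.logical(object@mask))
    msgs <- c(msgs, "mask must be a logical matrix")
  if (!identical(dim(object@mask), dim(object@values)))
    msgs <- c(msgs, "mask and values must have identical dimensions")
  if (anyNA(object@mask))
    msgs <- c(msgs, "mask must not contain NA")
  if (length(object@measure) != 1L || !(object@measure %in% .MEASURES))
    msgs <- c(msgs, sprintf("measure must be one of: %s",
                            paste(.MEASURES, collapse = ", ")))
  if (any(!is.finite(object@values[object@mask])))
    msgs <- c(msgs, "observed values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ResponseMatrix
#'
#' @param values numeric matrix of responses, cell lines in rows and drugs in
#'   columns, with row and column names. `NA` entries are treated as missing.
#' @param mask optional logical matrix, `TRUE` where a response was measured;
#'   defaults to `!is.na(values)`.
#' @param measure `"ic50_log"` or `"activity_area"`.
#' @return A [ResponseMatrix-class] object.
#' @examples
#' v <- matrix(c(1, 2, 3, NA), 2, 2,
#'             dimnames = list(c("CL1", "CL2"), c("d1", "d2")))
#' ResponseMatrix(v)
#' @export
ResponseMatrix <- function(values, mask = NULL, measure = "ic50_log") {
  if (is.null(mask)) mask <- !is.na(values)
  v <- values
  if (is.logical(mask) && identical(dim(mask), dim(v)) && !anyNA(mask))
    v[!mask] <- 0  # placeholder; unobserved entries are never read
  new("ResponseMatrix", values = v, mask = mask, measure = measure)
}

#' ExpressionMatrix: gene-expression profiles of the cell-line panel
#'
#' Genes in rows, cell lines in columns. Used to compute the expression-based
#' cell-line similarity (COEF). Rows are conventionally z-scored across cell
#' lines on load (see [readSideMatrix()]).
#'
#' @slot values numeric matrix, genes x cell lines, with dimnames.
#' @name ExpressionMatrix-class
#' @aliases ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", slots = c(values = "matrix"))

setValidity("ExpressionMatrix", function(object) {
  msgs <- .checkLabelled(object@values, "values")
  if (anyNA(object@values) && any(colSums(!is.na(object@values)) == 0L))
    msgs <- c(msgs, "no cell-line column may be entirely missing")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes x cell lines, with dimnames.
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values) new("ExpressionMatrix", values = values)

#' FingerprintMatrix: binary chemical fingerprints of the drug panel
#'
#' Drugs in rows, fingerprint bits in columns; entries are exactly 0 or 1.
#' Used for the Jaccard drug-structure similarity (COEF). All-zero rows are
#' invalid because the Jaccard coefficient is undefined for them.
#'
#' @slot values numeric 0/1 matrix, drugs x bits, with dimnames.
#' @slot fingerprintName free-text name of the fingerprint type.
#' @name FingerprintMatrix-class
#' @aliases FingerprintMatrix-class
#' @exportClass FingerprintMatrix
setClass("FingerprintMatrix",
  slots = c(values = "matrix", fingerprintName = "character"))

setValidity("FingerprintMatrix", function(object) {
  msgs <- .checkLabelled(object@values, "values")
  if (!all(object@values %in% c(0, 1)))
    msgs <- c(msgs, "fingerprint entries must be exactly 0 or 1")
  else if (any(rowSums(object@values) == 0))
    msgs <- c(msgs, sprintf("all-zero fingerprint rows (Jaccard undefined): %s",
      paste(rownames(object@values)[rowSums(object@values) == 0], collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a FingerprintMatrix
#'
#' @param values 0/1 numeric matrix, drugs x fingerprint bits, with dimnames.
#' @param fingerprintName free-text label recording the fingerprint type.
#' @return A [FingerprintMatrix-class] object.
#' @export
FingerprintMatrix <- function(values, fingerprintName = "unspecified")
  new("FingerprintMatrix", values = values, fingerprintName = fingerprintName)

#' SimilarityMatrix: pairwise similarities over cell lines or drugs
#'
#' A square symmetric similarity matrix tagged with the axis it lives on
#' (cell lines or drugs), the definition that produced it (`coef`, `rpcc`,
#' `mrpcc`), the pipeline stage (`raw`, `shrunk`, `amplified`), and a matrix
#' of pairwise support counts |U(i,j)| (number of co-observed responses) used
#' by the shrinkage step. The diagonal is ignored by all consumers; after
#' amplification it is set to zero so a row or column can never be selected
#' as its own neighbour.
#'
#' @slot values numeric symmetric matrix with identical row/column names.
#' @slot support numeric symmetric matrix of non-negative pairwise counts.
#' @slot axis `"cell_line"` or `"drug"`.
#' @slot definition `"coef"`, `"rpcc"` or `"mrpcc"`.
#' @slot stage `"raw"`, `"shrunk"` or `"amplified"`.
#' @name SimilarityMatrix-class
#' @aliases SimilarityMatrix-class
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  slots = c(values = "matrix", support = "matrix", axis = "character",
            definition = "character", stage = "character"))

setValidity("SimilarityMatrix", function(object) {
  msgs <- .checkLabelled(object@values, "values")
  v <- object@values
  if (nrow(v) != ncol(v))
    msgs <- c(msgs, "similarity matrix must be square")
  else if (!identical(rownames(v), colnames(v)))
    msgs <- c(msgs, "row and column labels must be identical")
  else if (max(abs(v - t(v))) > 1e-10)
    msgs <- c(msgs, "similarity matrix must be symmetric (tolerance 1e-10)")
  if (!identical(dim(object@support), dim(v)))
    msgs <- c(msgs, "support must have the same shape as values")
  else if (any(object@support < 0) ||
           max(abs(object@support - round(object@support))) > 1e-9)
    msgs <- c(msgs, "support must be non-negative integer counts")
  else if (max(abs(object@support - t(object@support))) > 0)
    msgs <- c(msgs, "support must be symmetric")
  if (!(object@axis %in% .SIM_AXES))
    msgs <- c(msgs, "axis must be 'cell_line' or 'drug'")
  if (!(object@definition %in% .SIM_DEFINITIONS))
    msgs <- c(msgs, "definition must be 'coef', 'rpcc' or 'mrpcc'")
  if (!(object@stage %in% .SIM_STAGES))
    msgs <- c(msgs, "stage must be 'raw', 'shrunk' or 'amplified'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimilarityMatrix
#'
#' Low-level constructor; most users obtain similarity matrices from
#' [coefCell()], [coefDrug()], [rpccSimilarity()] or [buildSimilarities()].
#'
#' @param values square symmetric numeric matrix with identical row/column
#'   labels.
#' @param support matrix of pairwise co-observation counts, same shape;
#'   defaults to zero (shrinkage then nullifies every pair, so supply real
#'   counts before shrinking).
#' @param axis `"cell_line"` or `"drug"`.
#' @param definition `"coef"`, `"rpcc"` or `"mrpcc"`.
#' @param stage `"raw"`, `"shrunk"` or `"amplified"`.
#' @return A [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(values, support = NULL, axis = "cell_line",
                             definition = "coef", stage = "raw") {
  if (is.null(support))
    support <- matrix(0, nrow(values), ncol(values), dimnames = dimnames(values))
  new("SimilarityMatrix", values = values, support = support, axis = axis,
      definition = definition, stage = stage)
}

#' BaselineModel: global mean plus cell-line and drug bias terms
#'
#' The baseline estimate for entry (u, i) is `b_ui = mu + b_u + b_i`, where
#' `mu` is the mean of all observed responses and `b_u`, `b_i` are regularised
#' deviations of cell line u and drug i from that mean. See [fitBaseline()].
#'
#' @slot mu numeric(1), global mean of observed responses.
#' @slot bCell named numeric vector of per-cell-line biases (length m).
#' @slot bDrug named numeric vector of per-drug biases (length n).
#' @slot lambdaDrug non-negative regulariser on the drug biases.
#' @slot lambdaCell non-negative regulariser on the cell-line biases.
#' @name BaselineModel-class
#' @aliases BaselineModel-class
#' @exportClass BaselineModel
setClass("BaselineModel",
  slots = c(mu = "numeric", bCell = "numeric", bDrug = "numeric",
            lambdaDrug = "numeric", lambdaCell = "numeric"))

setValidity("BaselineModel", function(object) {
  msgs <- character()
  if (length(object@mu) != 1L || !is.finite(object@mu))
    msgs <- c(msgs, "mu must be a single finite number")
  if (any(!is.finite(object@bCell)) || any(!is.finite(object@bDrug)))
    msgs <- c(msgs, "biases must be finite")
  if (is.null(names(object@bCell)) || is.null(names(object@bDrug)))
    msgs <- c(msgs, "biases must be named by cell line / drug")
  if (object@lambdaDrug < 0 || object@lambdaCell < 0)
    msgs <- c(msgs, "regularisers must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' PredictionResult: predicted responses for a set of matrix entries
#'
#' @slot entries data.frame with columns `cell_line`, `drug`, `predicted`,
#'   `fallback` (`TRUE` when neither orientation had usable neighbours and the
#'   prediction is the bare baseline).
#' @slot baseline the [BaselineModel-class] used.
#' @slot config list snapshot of the prediction parameters.
#' @name PredictionResult-class
#' @aliases PredictionResult-class
#' @exportClass PredictionResult
setClass("PredictionResult",
  slots = c(entries = "data.frame", baseline = "BaselineModel", config = "list"))

setValidity("PredictionResult", function(object) {
  req <- c("cell_line", "drug", "predicted", "fallback")
  if (!all(req %in% names(object@entries)))
    return(sprintf("entries must have columns: %s", paste(req, collapse = ", ")))
  if (any(!is.finite(object@entries$predicted)))
    return("predicted values must be finite")
  TRUE
})

#' FoldAssignment: an entry-wise cross-validation partition
#'
#' Partitions the observed entries of a [ResponseMatrix-class] into folds of
#' near-equal size (sizes differ by at most one).
#'
#' @slot cell integer row indices of the observed entries.
#' @slot drug integer column indices of the observed entries.
#' @slot fold integer fold id in `0..folds-1` per entry.
#' @slot folds number of folds.
#' @slot seed the RNG seed the assignment was drawn with.
#' @name FoldAssignment-class
#' @aliases FoldAssignment-class
#' @exportClass FoldAssignment
setClass("FoldAssignment",
  slots = c(cell = "integer", drug = "integer", fold = "integer",
            folds = "integer", seed = "integer"))

setValidity("FoldAssignment", function(object) {
  msgs <- character()
  n <- length(object@cell)
  if (length(object@drug) != n || length(object@fold) != n)
    msgs <- c(msgs, "cell, drug and fold must have equal length")
  if (any(object@fold < 0L) || any(object@fold >= object@folds))
    msgs <- c(msgs, "fold ids must lie in 0..folds-1")
  sz <- tabulate(object@fold + 1L, nbins = object@folds)
  if (n >= object@folds && diff(range(sz)) > 1L)
    msgs <- c(msgs, "fold sizes must differ by at most 1")
  if (length(msgs)) msgs else TRUE
})

#' CVReport: cross-validation performance summary
#'
#' Per-drug Pearson correlation (PCC) and RMSE between held-out observed and
#' predicted responses, pooled over the folds of each repetition, both over
#' all test entries and restricted to each drug's sensitive/resistant cell
#' lines; plus drug-averaged means and standard deviations.
#'
#' @slot drugMetrics data.frame with one row per (drug, repetition):
#'   `drug`, `repetition`, `n_test`, `pcc`, `rmse`, `n_sr`, `pcc_sr`,
#'   `rmse_sr` (`NA` where undefined).
#' @slot summary data.frame with one row per metric/subset: `metric`,
#'   `subset`, `mean`, `sd`, `n_defined`, `n_undefined`.
#' @slot config list snapshot of the evaluation parameters.
#' @slot seeds integer seeds used, one per repetition.
#' @name CVReport-class
#' @aliases CVReport-class
#' @exportClass CVReport
setClass("CVReport",
  slots = c(drugMetrics = "data.frame", summary = "data.frame",
            config = "list", seeds = "integer"))

#' SyntheticTruth: ground truth behind a generated dataset
#'
#' @slot mu0 true global mean.
#' @slot bCell true cell-line biases.
#' @slot bDrug true drug biases.
#' @slot cellFactors m x d latent cell-line factor matrix.
#' @slot drugFactors n x d latent drug factor matrix.
#' @slot noiseless the full noiseless response matrix
#'   `mu0 + b_u + b_i + <c_u, d_i>`.
#' @name SyntheticTruth-class
#' @aliases SyntheticTruth-class
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  slots = c(mu0 = "numeric", bCell = "numeric", bDrug = "numeric",
            cellFactors = "matrix", drugFactors = "matrix",
            noiseless = "matrix"))

setValidity("SyntheticTruth", function(object) {
  recon <- object@mu0 + outer(object@bCell, object@bDrug, "+") +
    object@cellFactors %*% t(object@drugFactors)
  if (max(abs(recon - object@noiseless)) > 1e-10)
    return("noiseless matrix must equal mu0 + b_u + b_i + factor inner products")
  TRUE
})
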