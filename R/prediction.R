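## Dual-orientation neighbourhood prediction.
##
## For a target entry (u, i) two neighbour sets are formed from the amplified
## similarities: the k most similar drugs with an observed response in cell
## line u (drug-oriented), and the k most similar cell lines with an observed
## response to drug i (cell-line-oriented). Each set contributes a weighted
## mean of baseline residuals; the prediction is the baseline plus the
## average of the two corrections:
##   r_hat_ui = b_ui + 1/2 * ( sum_j w_ij (r_uj - b_uj) / sum_j w_ij
##                           + sum_v w_uv (r_vi - b_vi) / sum_v w_uv ).
## If one orientation has no usable neighbours its term is dropped (no 1/2);
## if both are empty the baseline alone is returned with a fallback flag.

.DEGENERATE_WEIGHT <- 1e-12

#' Select the k nearest neighbours for one target entry
#'
#' Candidates are restricted to those with an observed response at the
#' required position (drug-oriented: drugs j with `r_uj` observed;
#' cell-line-oriented: cell lines v with `r_vi` observed) and strictly
#' positive amplified weight; the k largest weights win, ties broken by label
#' order. Fewer than k are returned when candidates are scarce.
#'
#' @param cellIndex,drugIndex integer position of the target entry (u, i).
#' @param sim an amplified-stage [SimilarityMatrix-class] whose axis matches
#'   `orientation` (drug axis for drug-oriented, cell-line axis otherwise).
#' @param response the training [ResponseMatrix-class].
#' @param k maximum number of neighbours, `k >= 1`.
#' @param orientation `"drug_oriented"` or `"cell_line_oriented"`.
#' @return List with `neighbors` (integer indices, weight-sorted) and
#'   `weights` (matching amplified similarities, non-increasing).
#' @export
selectNeighbors <- function(cellIndex, drugIndex, sim, response, k,
                            orientation = c("drug_oriented", "cell_line_oriented")) {
  orientation <- match.arg(orientation)
  stopifnot(is(sim, "SimilarityMatrix"), is(response, "ResponseMatrix"))
  if (k < 1)
    stop("k must be at least 1", call. = FALSE)
  if (simStage(sim) != "amplified")
    stop("neighbour selection requires an amplified-stage similarity",
         call. = FALSE)
  M <- isObserved(response)
  if (orientation == "drug_oriented") {
    if (simAxis(sim) != "drug")
      stop("drug-oriented selection needs a drug-axis similarity", call. = FALSE)
    w <- simValues(sim)[drugIndex, ]
    cand <- which(M[cellIndex, ] & w > 0)
    cand <- cand[cand != drugIndex]
  } else {
    if (simAxis(sim) != "cell_line")
      stop("cell-line-oriented selection needs a cell-line-axis similarity",
           call. = FALSE)
    w <- simValues(sim)[cellIndex, ]
    cand <- which(M[, drugIndex] & w > 0)
    cand <- cand[cand != cellIndex]
  }
  if (length(cand) == 0L)
    return(list(neighbors = integer(0), weights = numeric(0)))
  ord <- order(w[cand], decreasing = TRUE)  # stable: ties keep label order
  top <- unname(cand[ord][seq_len(min(k, length(cand)))])
  list(neighbors = top, weights = unname(w[top]))
}

# Weighted-mean residual correction for one orientation; NULL if degenerate.
.orientationTerm <- function(weights, residuals) {
  if (length(weights) == 0L) return(NULL)
  sw <- sum(weights)
  if (sw < .DEGENERATE_WEIGHT) return(NULL)
  sum(weights * residuals) / sw
}

#' Predict a single entry from its two neighbour sets
#'
#' @param cellIndex,drugIndex integer position of the target entry.
#' @param drugNeighbors,cellNeighbors neighbour sets from [selectNeighbors()]
#'   for the drug-oriented and cell-line-oriented views.
#' @param response the training [ResponseMatrix-class].
#' @param baseline a [BaselineModel-class] fitted on the same training mask.
#' @return List with `value` and `fallback` (`TRUE` when both orientations
#'   were empty or degenerate and the bare baseline was returned).
#' @export
predictEntry <- function(cellIndex, drugIndex, drugNeighbors, cellNeighbors,
                         response, baseline) {
  stopifnot(is(baseline, "BaselineModel"))
  V <- responseValues(response)
  mu <- globalMean(baseline)
  bC <- cellBias(baseline)
  bD <- drugBias(baseline)
  bui <- mu + bC[[cellIndex]] + bD[[drugIndex]]
  termDrug <- .orientationTerm(
    drugNeighbors$weights,
    V[cellIndex, drugNeighbors$neighbors] -
      (mu + bC[[cellIndex]] + bD[drugNeighbors$neighbors]))
  termCell <- .orientationTerm(
    cellNeighbors$weights,
    V[cellNeighbors$neighbors, drugIndex] -
      (mu + bC[cellNeighbors$neighbors] + bD[[drugIndex]]))
  terms <- c(termDrug, termCell)
  if (length(terms) == 0L)
    list(value = bui, fallback = TRUE)
  else
    list(value = bui + mean(terms), fallback = FALSE)
}

.resolveTargets <- function(response, targets) {
  M <- isObserved(response)
  if (is.character(targets) && length(targets) == 1L) {
    idx <- switch(targets,
      missing = which(!M, arr.ind = TRUE),
      observed = which(M, arr.ind = TRUE),
      all = which(M | TRUE, arr.ind = TRUE),
      stop("targets must be 'missing', 'observed', 'all' or an index matrix",
           call. = FALSE))
    return(idx)
  }
  idx <- as.matrix(targets)[, 1:2, drop = FALSE]
  if (is.character(idx)) {
    rows <- match(idx[, 1L], cellLines(response))
    cols <- match(idx[, 2L], drugs(response))
    if (anyNA(rows) || anyNA(cols))
      stop("target labels not present in the response matrix", call. = FALSE)
    idx <- cbind(rows, cols)
  }
  storage.mode(idx) <- "integer"
  if (any(idx[, 1L] < 1L | idx[, 1L] > nrow(M)) ||
      any(idx[, 2L] < 1L | idx[, 2L] > ncol(M)))
    stop("target indices outside the response matrix", call. = FALSE)
  idx
}

#' Predict a set of response-matrix entries (the full HIWCF step)
#'
#' Fits the baseline on the observed entries of `response`, then predicts
#' every requested target entry with the dual-orientation neighbourhood
#' interpolation. Deterministic given inputs and configuration.
#'
#' @param response the training [ResponseMatrix-class].
#' @param cellSim amplified-stage cell-line [SimilarityMatrix-class].
#' @param drugSim amplified-stage drug [SimilarityMatrix-class].
#' @param kCell neighbourhood size for the cell-line orientation (default 20).
#' @param kDrug neighbourhood size for the drug orientation (default 5;
#'   drug panels are small).
#' @param targets `"missing"` (default: all unobserved entries),
#'   `"observed"`, `"all"`, a 2-column integer index matrix, or a 2-column
#'   character matrix / data.frame of (cell line, drug) labels.
#' @param lambdaDrug,lambdaCell baseline regularisers (defaults 5 and 2).
#' @return A [PredictionResult-class].
#' @export
predictResponse <- function(response, cellSim, drugSim, kCell = 20, kDrug = 5,
                            targets = "missing", lambdaDrug = 5, lambdaCell = 2) {
  stopifnot(is(response, "ResponseMatrix"),
            is(cellSim, "SimilarityMatrix"), is(drugSim, "SimilarityMatrix"))
  if (simStage(cellSim) != "amplified" || simStage(drugSim) != "amplified")
    stop("prediction requires amplified-stage similarities", call. = FALSE)
  if (simAxis(cellSim) != "cell_line" || simAxis(drugSim) != "drug")
    stop("cellSim must be on the cell-line axis and drugSim on the drug axis",
         call. = FALSE)
  if (!identical(rownames(simValues(cellSim)), cellLines(response)) ||
      !identical(rownames(simValues(drugSim)), drugs(response)))
    stop("similarity labels do not match the response matrix", call. = FALSE)
  if (kCell < 1 || kDrug < 1)
    stop("neighbourhood sizes must be at least 1", call. = FALSE)
  baseline <- fitBaseline(response, lambdaDrug = lambdaDrug,
                          lambdaCell = lambdaCell)
  idx <- .resolveTargets(response, targets)
  V <- responseValues(response)
  M <- isObserved(response)
  Wc <- simValues(cellSim)
  Wd <- simValues(drugSim)
  bMat <- baselineMatrix(baseline)
  resid <- V - bMat
  nT <- nrow(idx)
  pred <- numeric(nT)
  fell <- logical(nT)
  for (t in seq_len(nT)) {
    u <- idx[t, 1L]
    i <- idx[t, 2L]
    # drug-oriented term
    wd <- Wd[i, ]
    cand <- which(M[u, ] & wd > 0)
    cand <- cand[cand != i]
    termDrug <- NULL
    if (length(cand)) {
      ord <- order(wd[cand], decreasing = TRUE)
      top <- cand[ord][seq_len(min(kDrug, length(cand)))]
      termDrug <- .orientationTerm(wd[top], resid[u, top])
    }
    # cell-line-oriented term
    wc <- Wc[u, ]
    cand <- which(M[, i] & wc > 0)
    cand <- cand[cand != u]
    termCell <- NULL
    if (length(cand)) {
      ord <- order(wc[cand], decreasing = TRUE)
      top <- cand[ord][seq_len(min(kCell, length(cand)))]
      termCell <- .orientationTerm(wc[top], resid[top, i])
    }
    terms <- c(termDrug, termCell)
    if (length(terms) == 0L) {
      pred[t] <- bMat[u, i]
      fell[t] <- TRUE
    } else {
      pred[t] <- bMat[u, i] + mean(terms)
    }
  }
  entries <- data.frame(
    cell_line = cellLines(response)[idx[, 1L]],
    drug = drugs(response)[idx[, 2L]],
    predicted = pred,
    fallback = fell,
    stringsAsFactors = FALSE)
  new("PredictionResult", entries = entries, baseline = baseline,
      config = list(k_cell = kCell, k_drug = kDrug,
                    lambda_drug = lambdaDrug, lambda_cell = lambdaCell,
                    definition_cell = simDefinition(cellSim),
                    definition_drug = simDefinition(drugSim)))
}

#' One-call HIWCF pipeline
#'
#' Aligns the inputs, builds the amplified similarities under the chosen
#' definition, and predicts the requested targets. This is the top-level
#' entry point mirroring the method end to end.
#'
#' @inheritParams predictResponse
#' @inheritParams buildSimilarities
#' @param expression an [ExpressionMatrix-class] (needed for `"coef"` and
#'   `"mrpcc"`).
#' @param fingerprints a [FingerprintMatrix-class] (needed for `"coef"` and
#'   `"mrpcc"`).
#' @return A [PredictionResult-class].
#' @examples
#' sim <- generateSynthetic(syntheticConfig(m = 40, n = 10, seed = 7))
#' res <- hiwcf(sim$response, sim$expression, sim$fingerprints)
#' head(predictedEntries(res))
#' @export
hiwcf <- function(response, expression = NULL, fingerprints = NULL,
                  definition = c("mrpcc", "rpcc", "coef"),
                  targets = "missing", kCell = 20, kDrug = 5,
                  lambdaDrug = 5, lambdaCell = 2, lambda4 = 50, rho = 2.5,
                  minOverlap = 3, cellSim = NULL, drugSim = NULL) {
  definition <- match.arg(definition)
  aligned <- alignInputs(response, expression, fingerprints)
  sims <- buildSimilarities(aligned$response, aligned$expression,
                            aligned$fingerprints, definition,
                            cellSim = cellSim, drugSim = drugSim,
                            lambda4 = lambda4, rho = rho,
                            minOverlap = minOverlap)
  res <- predictResponse(aligned$response, sims$cell, sims$drug,
                         kCell = kCell, kDrug = kDrug, targets = targets,
                         lambdaDrug = lambdaDrug, lambdaCell = lambdaCell)
  res@config <- c(res@config,
                  list(definition = definition, lambda4 = lambda4, rho = rho,
                       min_overlap = minOverlap))
  res
}
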