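## Similarity definitions over cell lines and drugs.
##
## Three definitions feed the neighbourhood model:
##   COEF  -- side information only: Pearson correlation of gene-expression
##            profiles (cell lines) or Jaccard coefficient of binary chemical
##            fingerprints (drugs).
##   RPCC  -- response only: Pearson correlation of two rows (cell lines) or
##            two columns (drugs) of the observed response matrix, computed
##            over pairwise-complete positions.
##   MRPCC -- elementwise product COEF * RPCC, rewarding pairs consistent in
##            both views.
## Raw similarities then pass through support-based shrinkage
## w <- |U|/(|U| + lambda4) * w and case amplification w <- w * |w|^(rho - 1),
## in that order, before neighbour selection.

#' Expression-based cell-line similarity (COEF)
#'
#' Pearson correlation between the gene-expression profiles of every pair of
#' cell lines. Cell lines with a constant profile yield undefined
#' correlations; those entries are set to 0 with a warning (0 = "no usable
#' evidence"). Support is initialised to the gene count; replace it with
#' response-overlap counts via [responseSupport()] before shrinking.
#'
#' @param expression an [ExpressionMatrix-class] with at least 2 genes.
#' @return A raw-stage [SimilarityMatrix-class] on the cell-line axis.
#' @export
coefCell <- function(expression) {
  stopifnot(is(expression, "ExpressionMatrix"))
  E <- exprValues(expression)
  if (nrow(E) < 2L)
    stop("need at least 2 genes to correlate expression profiles", call. = FALSE)
  r <- suppressWarnings(stats::cor(E))
  if (anyNA(r)) {
    warning("constant expression profile(s): undefined correlations set to 0")
    r[is.na(r)] <- 0
  }
  k <- ncol(E)
  support <- matrix(nrow(E), k, k, dimnames = dimnames(r))
  SimilarityMatrix(r, support = support, axis = "cell_line",
                   definition = "coef", stage = "raw")
}

#' Fingerprint-based drug similarity (COEF)
#'
#' Jaccard coefficient between the binary chemical fingerprints of every pair
#' of drugs: |bits on in both| / |bits on in either|, in `[0, 1]`. All-zero
#' fingerprints are rejected at construction of the
#' [FingerprintMatrix-class], so the coefficient is always defined.
#'
#' @param fingerprints a [FingerprintMatrix-class].
#' @return A raw-stage [SimilarityMatrix-class] on the drug axis.
#' @export
coefDrug <- function(fingerprints) {
  stopifnot(is(fingerprints, "FingerprintMatrix"))
  fp <- fingerprintValues(fingerprints)
  inter <- fp %*% t(fp)
  on <- rowSums(fp)
  union <- outer(on, on, "+") - inter
  r <- inter / union
  k <- nrow(fp)
  support <- matrix(ncol(fp), k, k, dimnames = dimnames(r))
  SimilarityMatrix(r, support = support, axis = "drug",
                   definition = "coef", stage = "raw")
}

# Pairwise-complete Pearson over the rows of X under mask M, with overlap
# counts. Vectorised through masked cross-products so the m x m (or n x n)
# matrix never needs an explicit pair loop.
.pairwisePearson <- function(X, M, minOverlap) {
  Xz <- X
  Xz[!M] <- 0
  Mn <- M * 1
  n <- Mn %*% t(Mn)
  Sx <- Xz %*% t(Mn)       # Sx[u,v] = sum of u's values over the (u,v) overlap
  Sxy <- Xz %*% t(Xz)
  Sxx <- (Xz * Xz) %*% t(Mn)
  num <- n * Sxy - Sx * t(Sx)
  den2 <- pmax(n * Sxx - Sx^2, 0) * t(pmax(n * Sxx - Sx^2, 0))
  ok <- n >= minOverlap & den2 > 0
  r <- matrix(0, nrow(X), nrow(X), dimnames = list(rownames(X), rownames(X)))
  r[ok] <- num[ok] / sqrt(den2[ok])
  r <- pmin(pmax(r, -1), 1)
  r <- (r + t(r)) / 2  # remove float asymmetry from the two den factors
  list(r = r, support = n)
}

#' Response-profile similarity (RPCC)
#'
#' Pearson correlation between two rows (cell lines) or two columns (drugs)
#' of the observed response matrix, computed over the positions observed in
#' both vectors. Pairs whose overlap is below `minOverlap` or whose overlap
#' has zero variance get similarity 0; the overlap count is stored as the
#' pair's support for later shrinkage.
#'
#' @param response a [ResponseMatrix-class].
#' @param axis `"cell_line"` (correlate rows) or `"drug"` (correlate columns).
#' @param minOverlap minimum number of co-observed positions for a defined
#'   correlation (default 3).
#' @return A raw-stage [SimilarityMatrix-class].
#' @export
rpccSimilarity <- function(response, axis = c("cell_line", "drug"),
                           minOverlap = 3) {
  stopifnot(is(response, "ResponseMatrix"))
  axis <- match.arg(axis)
  V <- responseValues(response)
  M <- isObserved(response)
  if (axis == "drug") {
    V <- t(V)
    M <- t(M)
  }
  pw <- .pairwisePearson(V, M, minOverlap)
  SimilarityMatrix(pw$r, support = pw$support, axis = axis,
                   definition = "rpcc", stage = "raw")
}

#' Hybrid similarity (MRPCC): elementwise product of COEF and RPCC
#'
#' Multiplying the side-information similarity by the response-profile
#' similarity promotes pairs that agree in both views. Support is taken from
#' the RPCC operand (the response overlap). Note that two negative factors
#' produce a positive product; such pairs rank as similar even though each
#' view alone calls them dissimilar -- a documented property of the product
#' definition.
#'
#' @param coef a raw COEF [SimilarityMatrix-class].
#' @param rpcc a raw RPCC [SimilarityMatrix-class] on the same axis with the
#'   same label order.
#' @return A raw-stage MRPCC [SimilarityMatrix-class].
#' @export
mrpccSimilarity <- function(coef, rpcc) {
  stopifnot(is(coef, "SimilarityMatrix"), is(rpcc, "SimilarityMatrix"))
  if (simAxis(coef) != simAxis(rpcc))
    stop("COEF and RPCC operands are on different axes", call. = FALSE)
  if (!identical(rownames(simValues(coef)), rownames(simValues(rpcc))))
    stop("COEF and RPCC operands have mismatched labels", call. = FALSE)
  if (simStage(coef) != "raw" || simStage(rpcc) != "raw")
    stop("MRPCC must be formed from raw-stage operands", call. = FALSE)
  if (simDefinition(coef) != "coef" || simDefinition(rpcc) != "rpcc")
    stop("operands must be a COEF and an RPCC similarity", call. = FALSE)
  SimilarityMatrix(simValues(coef) * simValues(rpcc),
                   support = simSupport(rpcc), axis = simAxis(coef),
                   definition = "mrpcc", stage = "raw")
}

#' Replace a similarity's support with response-overlap counts
#'
#' Shrinkage discounts each pair by its number of co-observed responses.
#' COEF similarities are built from side information and carry a constant
#' support (gene or bit count); this helper substitutes the pairwise response
#' overlap so that shrinkage treats every definition consistently.
#'
#' @param sim a raw-stage [SimilarityMatrix-class].
#' @param response the [ResponseMatrix-class] supplying the overlap counts.
#' @return The same similarity with support replaced.
#' @export
responseSupport <- function(sim, response) {
  stopifnot(is(sim, "SimilarityMatrix"), is(response, "ResponseMatrix"))
  M <- isObserved(response) * 1
  ids <- rownames(simValues(sim))
  if (simAxis(sim) == "cell_line") {
    if (!identical(ids, cellLines(response)))
      stop("similarity labels do not match the response cell lines", call. = FALSE)
    support <- M %*% t(M)
  } else {
    if (!identical(ids, drugs(response)))
      stop("similarity labels do not match the response drugs", call. = FALSE)
    support <- t(M) %*% M
  }
  SimilarityMatrix(simValues(sim), support = support, axis = simAxis(sim),
                   definition = simDefinition(sim), stage = simStage(sim))
}

#' Shrink similarities by their pairwise support
#'
#' `w <- |U| / (|U| + lambda4) * w` elementwise, where |U| is each pair's
#' co-observation count. Pairs supported by few shared responses are pulled
#' toward 0; when support equals `lambda4` the factor is exactly 1/2, and
#' zero-support pairs are nullified. Default `lambda4 = 50`.
#'
#' @param sim a raw-stage [SimilarityMatrix-class] with meaningful support.
#' @param lambda4 non-negative shrinkage constant.
#' @return A shrunk-stage [SimilarityMatrix-class].
#' @export
shrinkSimilarity <- function(sim, lambda4 = 50) {
  stopifnot(is(sim, "SimilarityMatrix"))
  if (lambda4 < 0)
    stop("lambda4 must be non-negative", call. = FALSE)
  if (simStage(sim) != "raw")
    stop("shrinkage applies to raw-stage similarities", call. = FALSE)
  S <- simSupport(sim)
  factor <- ifelse(S + lambda4 > 0, S / (S + lambda4), 0)
  SimilarityMatrix(simValues(sim) * factor, support = S, axis = simAxis(sim),
                   definition = simDefinition(sim), stage = "shrunk")
}

#' Case amplification of similarity weights
#'
#' `w <- w * |w|^(rho - 1)` elementwise, preserving sign. For `rho > 1` this
#' exaggerates strong similarities and suppresses weak ones (|w| <= 1 shrinks
#' toward 0; 0 and +/-1 are fixed points). Default `rho = 2.5`. The diagonal
#' is zeroed so an item can never be its own neighbour.
#'
#' @param sim a shrunk-stage [SimilarityMatrix-class].
#' @param rho amplification power, `rho >= 1`.
#' @return An amplified-stage [SimilarityMatrix-class].
#' @export
amplifySimilarity <- function(sim, rho = 2.5) {
  stopifnot(is(sim, "SimilarityMatrix"))
  if (rho < 1)
    stop("rho must be >= 1", call. = FALSE)
  if (simStage(sim) != "shrunk")
    stop("amplification follows shrinkage (raw -> shrunk -> amplified)",
         call. = FALSE)
  w <- simValues(sim)
  w <- w * abs(w)^(rho - 1)
  diag(w) <- 0
  SimilarityMatrix(w, support = simSupport(sim), axis = simAxis(sim),
                   definition = simDefinition(sim), stage = "amplified")
}

#' Build the amplified cell-line and drug similarity pair
#'
#' Convenience wrapper running the full similarity pipeline for one
#' definition: raw similarity, response-overlap support, shrinkage,
#' amplification.
#'
#' `definition = "coef"` needs `expression` and `fingerprints` (or
#' precomputed raw similarities); `"rpcc"` needs only the response;
#' `"mrpcc"` needs both.
#'
#' @param response a [ResponseMatrix-class] (training entries only).
#' @param expression an [ExpressionMatrix-class] aligned to the response, or
#'   `NULL`.
#' @param fingerprints a [FingerprintMatrix-class] aligned to the response,
#'   or `NULL`.
#' @param definition `"mrpcc"`, `"rpcc"` or `"coef"`.
#' @param cellSim,drugSim optional precomputed raw side-information
#'   similarities used in place of `expression` / `fingerprints`.
#' @param lambda4 shrinkage constant (default 50).
#' @param rho case-amplification power (default 2.5).
#' @param minOverlap minimum pairwise overlap for RPCC (default 3).
#' @return List with amplified `cell` and `drug` [SimilarityMatrix-class]es.
#' @export
buildSimilarities <- function(response, expression = NULL, fingerprints = NULL,
                              definition = c("mrpcc", "rpcc", "coef"),
                              cellSim = NULL, drugSim = NULL,
                              lambda4 = 50, rho = 2.5, minOverlap = 3) {
  definition <- match.arg(definition)
  needSide <- definition %in% c("coef", "mrpcc")
  if (needSide) {
    if (is.null(cellSim)) {
      if (is.null(expression))
        stop(sprintf("definition '%s' needs expression data or a precomputed cell similarity",
                     definition), call. = FALSE)
      cellSim <- coefCell(expression)
    }
    if (is.null(drugSim)) {
      if (is.null(fingerprints))
        stop(sprintf("definition '%s' needs fingerprints or a precomputed drug similarity",
                     definition), call. = FALSE)
      drugSim <- coefDrug(fingerprints)
    }
  }
  raw <- switch(definition,
    coef = list(cell = cellSim, drug = drugSim),
    rpcc = list(cell = rpccSimilarity(response, "cell_line", minOverlap),
                drug = rpccSimilarity(response, "drug", minOverlap)),
    mrpcc = list(
      cell = mrpccSimilarity(cellSim, rpccSimilarity(response, "cell_line", minOverlap)),
      drug = mrpccSimilarity(drugSim, rpccSimilarity(response, "drug", minOverlap))))
  lapply(raw, function(s)
    amplifySimilarity(shrinkSimilarity(responseSupport(s, response), lambda4), rho))
}

#' Write / read a similarity matrix as labelled CSV
#'
#' The axis, definition and stage tags are recorded as `#`-prefixed metadata
#' lines above the header; `readSimilarity` restores them (support is not
#' serialised and comes back as zero -- recompute with [responseSupport()]).
#'
#' @param x a [SimilarityMatrix-class].
#' @param path CSV path.
#' @return For `writeSimilarity`, `path` invisibly; for `readSimilarity`, the
#'   restored [SimilarityMatrix-class].
#' @export
writeSimilarity <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# axis: %s", simAxis(x)), con)
  writeLines(sprintf("# definition: %s", simDefinition(x)), con)
  writeLines(sprintf("# stage: %s", simStage(x)), con)
  v <- simValues(x)
  writeLines(paste(c("id", colnames(v)), collapse = ","), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i], format(v[i, ], digits = 15, trim = TRUE)),
                     collapse = ","), con)
  invisible(path)
}

#' @rdname writeSimilarity
#' @export
readSimilarity <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  tag <- function(key, default) {
    hit <- grep(sprintf("^# %s: ", key), meta, value = TRUE)
    if (length(hit)) sub(sprintf("^# %s: ", key), "", hit[1L]) else default
  }
  body <- lines[!startsWith(lines, "# ")]
  tf <- tempfile(fileext = ".csv")
  writeLines(body, tf)
  on.exit(unlink(tf))
  v <- .readLabelledCSV(tf, "similarity matrix")
  v <- (v + t(v)) / 2
  SimilarityMatrix(v, axis = tag("axis", "cell_line"),
                   definition = tag("definition", "coef"),
                   stage = tag("stage", "raw"))
}
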