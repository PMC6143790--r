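## CSV I/O for the matrix formats.
## Convention: RFC-4180 CSV, UTF-8, header row of column labels, first column
## holds row labels. Missing responses are empty cells, "NA" or "NaN"
## (case-insensitive).

.MISSING_TOKENS <- c("", "na", "nan")

.readLabelledCSV <- function(path, what) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character(0))
  if (ncol(df) < 2L)
    stop(sprintf("%s: need a label column plus at least one data column", what),
         call. = FALSE)
  rowLabels <- df[[1L]]
  colLabels <- colnames(df)[-1L]
  if (anyDuplicated(rowLabels))
    stop(sprintf("%s: duplicated row label(s): %s", what,
                 paste(unique(rowLabels[duplicated(rowLabels)]), collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(colLabels))
    stop(sprintf("%s: duplicated column label(s): %s", what,
                 paste(unique(colLabels[duplicated(colLabels)]), collapse = ", ")),
         call. = FALSE)
  raw <- as.matrix(df[, -1L, drop = FALSE])
  txt <- trimws(raw)
  miss <- is.na(txt) | tolower(txt) %in% .MISSING_TOKENS
  num <- suppressWarnings(as.numeric(txt))
  bad <- !miss & is.na(num)
  if (any(bad)) {
    pos <- which(bad)[1L]
    ri <- (pos - 1L) %% nrow(raw) + 1L
    ci <- (pos - 1L) %/% nrow(raw) + 1L
    stop(sprintf("%s: non-numeric value '%s' at row '%s', column '%s'",
                 what, txt[pos], rowLabels[ri], colLabels[ci]),
         call. = FALSE)
  }
  num[miss] <- NA_real_
  matrix(num, nrow(raw), ncol(raw), dimnames = list(rowLabels, colLabels))
}

#' Read a partially observed drug-response matrix from CSV
#'
#' The file must have drug labels in the header row and cell-line labels in the
#' first column. Empty cells, `NA` and `NaN` (case-insensitive) are missing.
#' Rows or columns with zero observed entries are dropped with a warning.
#'
#' @param path path to the CSV file.
#' @param measure `"ic50_log"` or `"activity_area"`.
#' @param transpose set `TRUE` when the file has cell lines in columns.
#' @return A [ResponseMatrix-class].
#' @export
readResponseMatrix <- function(path, measure = c("ic50_log", "activity_area"),
                               transpose = FALSE) {
  measure <- match.arg(measure)
  v <- .readLabelledCSV(path, "response matrix")
  if (transpose) v <- t(v)
  mask <- !is.na(v)
  keepRow <- rowSums(mask) > 0L
  keepCol <- colSums(mask) > 0L
  if (!all(keepRow))
    warning(sprintf("dropping %d cell line(s) with no observed responses: %s",
                    sum(!keepRow), paste(rownames(v)[!keepRow], collapse = ", ")))
  if (!all(keepCol))
    warning(sprintf("dropping %d drug(s) with no observed responses: %s",
                    sum(!keepCol), paste(colnames(v)[!keepCol], collapse = ", ")))
  v <- v[keepRow, keepCol, drop = FALSE]
  if (nrow(v) == 0L || ncol(v) == 0L)
    stop("response matrix has no observed entries", call. = FALSE)
  ResponseMatrix(v, measure = measure)
}

#' Write a ResponseMatrix to CSV
#'
#' Unobserved entries are written as `NA`, so [readResponseMatrix()] on the
#' output round-trips values, mask and labels.
#'
#' @param x a [ResponseMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeResponseMatrix <- function(x, path) {
  v <- responseValues(x)
  v[!isObserved(x)] <- NA_real_
  df <- data.frame(cell_line = rownames(v), v, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a side-information matrix from CSV
#'
#' Reads one of the three auxiliary matrix kinds:
#' \describe{
#'   \item{expression}{genes x cell lines; by default each gene row is z-scored
#'     across cell lines (genes with zero spread are dropped with a warning),
#'     the conventional normalisation before correlating expression profiles.}
#'   \item{fingerprint}{drugs x bits; all entries must be 0/1; all-zero drug
#'     rows are dropped with a warning (Jaccard similarity is undefined for
#'     them).}
#'   \item{similarity}{square with identical row/column labels; small
#'     asymmetries are removed by averaging with the transpose.}
#' }
#'
#' @param path path to the CSV file.
#' @param kind `"expression"`, `"fingerprint"` or `"similarity"`.
#' @param normalize z-score expression rows (expression only).
#' @param axis for `kind = "similarity"`: `"cell_line"` or `"drug"`.
#' @param fingerprintName recorded fingerprint type (fingerprint only).
#' @return An [ExpressionMatrix-class], [FingerprintMatrix-class] or raw-stage
#'   [SimilarityMatrix-class] according to `kind`.
#' @export
readSideMatrix <- function(path, kind = c("expression", "fingerprint", "similarity"),
                           normalize = TRUE, axis = "cell_line",
                           fingerprintName = "unspecified") {
  kind <- match.arg(kind)
  v <- .readLabelledCSV(path, sprintf("%s matrix", kind))
  switch(kind,
    expression = {
      if (anyNA(v))
        stop("expression matrix must not contain missing values", call. = FALSE)
      if (normalize) v <- .zscoreRows(v)
      ExpressionMatrix(v)
    },
    fingerprint = {
      if (anyNA(v) || !all(v %in% c(0, 1))) {
        offending <- v[!(v %in% c(0, 1)) | is.na(v)][1L]
        stop(sprintf("fingerprint matrix: value outside {0,1}: %s", offending),
             call. = FALSE)
      }
      zero <- rowSums(v) == 0
      if (any(zero)) {
        warning(sprintf("dropping %d all-zero fingerprint row(s): %s",
                        sum(zero), paste(rownames(v)[zero], collapse = ", ")))
        v <- v[!zero, , drop = FALSE]
      }
      FingerprintMatrix(v, fingerprintName = fingerprintName)
    },
    similarity = {
      if (nrow(v) != ncol(v))
        stop(sprintf("similarity matrix must be square, got %d x %d",
                     nrow(v), ncol(v)), call. = FALSE)
      if (!identical(rownames(v), colnames(v)))
        stop("similarity matrix must have identical row and column labels",
             call. = FALSE)
      v <- (v + t(v)) / 2  # enforce symmetry (tolerates asymmetries ~1e-8)
      SimilarityMatrix(v, axis = axis, definition = "coef", stage = "raw")
    })
}

.zscoreRows <- function(v) {
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  keep <- sdv > 0
  if (!all(keep))
    warning(sprintf("dropping %d constant gene row(s) during z-scoring",
                    sum(!keep)))
  (v[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
}

#' Align response, expression and fingerprint matrices by shared labels
#'
#' Restricts and reorders all three matrices to the cell lines present in both
#' the response and expression data and the drugs present in both the response
#' and fingerprint data (order taken from the response matrix). Counts of
#' dropped labels are reported; rows/columns of the response matrix left with
#' zero observed entries are then dropped as on load.
#'
#' @param response a [ResponseMatrix-class].
#' @param expression an [ExpressionMatrix-class], or `NULL` to skip cell-line
#'   alignment.
#' @param fingerprints a [FingerprintMatrix-class], or `NULL` to skip drug
#'   alignment.
#' @return A list with elements `response`, `expression`, `fingerprints`.
#' @export
alignInputs <- function(response, expression = NULL, fingerprints = NULL) {
  cl <- cellLines(response)
  dg <- drugs(response)
  if (!is.null(expression)) {
    common <- cl[cl %in% cellLines(expression)]
    if (length(common) == 0L)
      stop("no cell lines shared between response and expression matrices",
           call. = FALSE)
    dropped <- (length(cl) - length(common)) +
      (length(cellLines(expression)) - length(common))
    if (dropped > 0L)
      message(sprintf("alignment dropped %d cell-line label(s)", dropped))
    cl <- common
  }
  if (!is.null(fingerprints)) {
    common <- dg[dg %in% drugs(fingerprints)]
    if (length(common) == 0L)
      stop("no drugs shared between response and fingerprint matrices",
           call. = FALSE)
    dropped <- (length(dg) - length(common)) +
      (length(drugs(fingerprints)) - length(common))
    if (dropped > 0L)
      message(sprintf("alignment dropped %d drug label(s)", dropped))
    dg <- common
  }
  v <- responseValues(response)[cl, dg, drop = FALSE]
  m <- isObserved(response)[cl, dg, drop = FALSE]
  keepRow <- rowSums(m) > 0L
  keepCol <- colSums(m) > 0L
  if (!all(keepRow) || !all(keepCol))
    warning(sprintf("alignment left %d cell line(s)/%d drug(s) without observed entries; dropped",
                    sum(!keepRow), sum(!keepCol)))
  cl <- cl[keepRow]; dg <- dg[keepCol]
  v[!m] <- NA_real_
  resp <- ResponseMatrix(v[cl, dg, drop = FALSE], measure = measureType(response))
  list(
    response = resp,
    expression = if (is.null(expression)) NULL else
      ExpressionMatrix(exprValues(expression)[, cl, drop = FALSE]),
    fingerprints = if (is.null(fingerprints)) NULL else
      FingerprintMatrix(fingerprintValues(fingerprints)[dg, , drop = FALSE],
                        fingerprintName = fingerprintName(fingerprints))
  )
}

#' Write predictions as a three-column CSV
#'
#' Columns `cell_line`, `drug`, `predicted_value`; the prediction parameters
#' are recorded in `#`-prefixed header comment lines.
#'
#' @param x a [PredictionResult-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- x@config
  for (nm in names(cfg))
    writeLines(sprintf("# %s: %s", nm, paste(format(cfg[[nm]]), collapse = ",")), con)
  df <- predictedEntries(x)
  writeLines("cell_line,drug,predicted_value", con)
  writeLines(sprintf("%s,%s,%.10g", df$cell_line, df$drug, df$predicted), con)
  invisible(path)
}

#' Serialise / restore a BaselineModel as CSV
#'
#' Written as `(kind, label, value)` rows: one `mu` row, the regularisers, and
#' one row per cell-line and drug bias.
#'
#' @param x a [BaselineModel-class].
#' @param path CSV path.
#' @return For `writeBaseline`, `path` invisibly; for `readBaseline`, the
#'   restored [BaselineModel-class].
#' @export
writeBaseline <- function(x, path) {
  df <- rbind(
    data.frame(kind = "mu", label = "", value = globalMean(x)),
    data.frame(kind = "lambda_drug", label = "", value = x@lambdaDrug),
    data.frame(kind = "lambda_cell", label = "", value = x@lambdaCell),
    data.frame(kind = "cell_line", label = names(cellBias(x)), value = unname(cellBias(x))),
    data.frame(kind = "drug", label = names(drugBias(x)), value = unname(drugBias(x))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBaseline
#' @export
readBaseline <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "numeric"))
  pick <- function(kind) {
    sub <- df[df$kind == kind, , drop = FALSE]
    stats::setNames(sub$value, sub$label)
  }
  new("BaselineModel",
      mu = unname(pick("mu")),
      bCell = pick("cell_line"),
      bDrug = pick("drug"),
      lambdaDrug = unname(pick("lambda_drug")),
      lambdaCell = unname(pick("lambda_cell")))
}
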