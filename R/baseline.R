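## Baseline estimate: b_ui = mu + b_u + b_i.
##
## Observed responses carry strong systematic row (cell line) and column
## (drug) effects -- some drugs are potent across the whole panel, some cell
## lines are broadly resistant. The baseline removes these before any
## neighbourhood interpolation. The biases are regularised means of
## residuals, computed in closed form in two passes: drug biases first,
##   b_i = sum_{u in U(i)} (r_ui - mu) / (lambda_drug + |U(i)|)
## then cell-line biases against the drug-adjusted residuals,
##   b_u = sum_{i in U(u)} (r_ui - mu - b_i) / (lambda_cell + |U(u)|).

#' Fit the global-mean-plus-biases baseline model
#'
#' `mu` is the mean of all observed entries. Drug biases are regularised
#' column means of the residuals `(r_ui - mu)`; cell-line biases are
#' regularised row means of `(r_ui - mu - b_i)`. Larger regularisers shrink
#' the biases toward zero; the
#' defaults (`lambdaDrug = 5`, `lambdaCell = 2`) follow common practice for
#' this estimator. A row or column with zero observed entries gets bias 0.
#'
#' @param response a [ResponseMatrix-class] with at least one observed entry.
#' @param lambdaDrug non-negative regulariser on drug biases (default 5).
#' @param lambdaCell non-negative regulariser on cell-line biases (default 2).
#' @return A [BaselineModel-class].
#' @examples
#' v <- matrix(c(1, 3, 2, NA), 2, 2,
#'             dimnames = list(c("CL1", "CL2"), c("d1", "d2")))
#' fitBaseline(ResponseMatrix(v))
#' @export
fitBaseline <- function(response, lambdaDrug = 5, lambdaCell = 2) {
  stopifnot(is(response, "ResponseMatrix"))
  if (lambdaDrug < 0 || lambdaCell < 0)
    stop("regularisers must be non-negative", call. = FALSE)
  M <- isObserved(response)
  if (!any(M))
    stop("cannot fit a baseline on a matrix with no observed entries",
         call. = FALSE)
  V <- responseValues(response)
  V[!M] <- 0
  nObsDrug <- colSums(M)
  nObsCell <- rowSums(M)
  mu <- sum(V) / sum(M)
  bDrug <- ifelse(nObsDrug > 0, colSums((V - mu) * M) / (lambdaDrug + nObsDrug), 0)
  resid <- (V - mu - matrix(bDrug, nrow(V), ncol(V), byrow = TRUE)) * M
  bCell <- ifelse(nObsCell > 0, rowSums(resid) / (lambdaCell + nObsCell), 0)
  new("BaselineModel",
      mu = mu,
      bCell = stats::setNames(bCell, cellLines(response)),
      bDrug = stats::setNames(bDrug, drugs(response)),
      lambdaDrug = lambdaDrug, lambdaCell = lambdaCell)
}

#' Baseline prediction for specific entries
#'
#' Returns `b_ui = mu + b_u + b_i` for each requested (cell line, drug) pair;
#' defined for observed and unobserved entries alike.
#'
#' @param model a fitted [BaselineModel-class].
#' @param cellIndex integer or character cell-line indices (recycled against
#'   `drugIndex`).
#' @param drugIndex integer or character drug indices.
#' @return Numeric vector of baseline estimates.
#' @export
predictBaseline <- function(model, cellIndex, drugIndex) {
  stopifnot(is(model, "BaselineModel"))
  bu <- cellBias(model)[cellIndex]
  bi <- drugBias(model)[drugIndex]
  if (anyNA(bu) || anyNA(bi))
    stop("cell or drug index out of range for the fitted model", call. = FALSE)
  unname(globalMean(model) + bu + bi)
}

#' Full baseline matrix
#'
#' The m x n matrix of `mu + b_u + b_i` over every (cell line, drug) pair.
#'
#' @param model a fitted [BaselineModel-class].
#' @return Numeric matrix with cell-line rows and drug columns.
#' @export
baselineMatrix <- function(model) {
  stopifnot(is(model, "BaselineModel"))
  globalMean(model) + outer(cellBias(model), drugBias(model), "+")
}
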