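## Cross-validation harness.
##
## Observed entries are partitioned entry-wise into folds of near-equal size.
## For each fold the test entries are masked out of the training matrix
## BEFORE the baseline and every response-derived similarity are computed, so
## no held-out value can leak into its own prediction. Test predictions are
## pooled per drug across the folds of a repetition and scored with Pearson
## correlation (PCC) and RMSE, both on all test entries of the drug and on
## the drug's sensitive/resistant cell lines (observed response more than t
## standard deviations from the drug's observed mean).

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
.withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Partition the observed entries into cross-validation folds
#'
#' Uniformly random entry-wise partition; fold sizes differ by at most one
#' (with N = qF + r entries, r folds get q + 1 and the rest q). Reproducible
#' from the seed; the caller's RNG state is untouched.
#'
#' @param response a [ResponseMatrix-class].
#' @param folds number of folds, at least 2 (default 10).
#' @param seed integer RNG seed.
#' @return A [FoldAssignment-class].
#' @export
makeFolds <- function(response, folds = 10, seed = 1) {
  stopifnot(is(response, "ResponseMatrix"))
  if (folds < 2)
    stop("need at least 2 folds", call. = FALSE)
  obs <- which(isObserved(response), arr.ind = TRUE)
  n <- nrow(obs)
  if (n < folds)
    stop(sprintf("only %d observed entries for %d folds", n, folds),
         call. = FALSE)
  fold <- integer(n)
  .withSeed(seed, {
    perm <- sample.int(n)
    fold[perm] <- rep(seq_len(folds) - 1L, length.out = n)
  })
  new("FoldAssignment", cell = as.integer(obs[, 1L]),
      drug = as.integer(obs[, 2L]), fold = fold,
      folds = as.integer(folds), seed = as.integer(seed))
}

#' Indices of a drug's sensitive and resistant cell lines
#'
#' The extremes of one drug's observed response vector: indices whose value
#' deviates from the vector's mean by more than `t` standard deviations
#' (both tails, so both the most sensitive and the most resistant lines).
#'
#' @param x numeric vector of one drug's observed responses.
#' @param t threshold in standard deviations (default 1).
#' @return Integer indices into `x`; empty (with a warning) when `x` has
#'   zero spread.
#' @export
sensitiveResistant <- function(x, t = 1.0) {
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (is.na(s) || s == 0) {
    warning("zero spread: no sensitive/resistant cell lines identified")
    return(integer(0))
  }
  which(abs(x - mean(x)) > t * s)
}

#' Pearson correlation and RMSE between observed and predicted vectors
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return Named numeric vector `c(pcc, rmse)`; `pcc` is `NA` when either
#'   vector is constant or shorter than 2 (undefined correlation).
#' @export
predictionMetrics <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  if (length(observed) < 1L)
    stop("need at least one value", call. = FALSE)
  rmse <- sqrt(mean((observed - predicted)^2))
  pcc <- NA_real_
  if (length(observed) >= 2L &&
      stats::sd(observed) > 0 && stats::sd(predicted) > 0)
    pcc <- stats::cor(observed, predicted)
  c(pcc = pcc, rmse = rmse)
}

# Mask the entries of one fold out of a ResponseMatrix (training view).
.maskFold <- function(response, assignment, fold) {
  hide <- assignment@fold == fold
  M <- isObserved(response)
  M[cbind(assignment@cell[hide], assignment@drug[hide])] <- FALSE
  v <- responseValues(response)
  v[!M] <- NA_real_
  ResponseMatrix(v, mask = M, measure = measureType(response))
}

#' Cross-validated evaluation of the prediction pipeline
#'
#' Runs `repetitions` rounds of `folds`-fold cross-validation over the
#' observed entries. Within each repetition every fold in turn is held out,
#' the baseline and all response-derived similarities are recomputed from the
#' remaining training entries only, and the held-out entries are predicted.
#' Per-drug metrics pool each drug's test predictions across the folds of the
#' repetition; the summary reports unweighted drug-averaged means and
#' standard deviations pooled over repetitions, with counts of drugs whose
#' metric was undefined (fewer than 2 test values, or a constant vector).
#'
#' @inheritParams hiwcf
#' @param folds number of folds (default 10).
#' @param repetitions number of repeated cross-validation rounds (default 1).
#' @param seed master seed; repetition r uses `seed + r - 1`.
#' @param srThreshold sensitive/resistant threshold in SD units (default 1).
#' @return A [CVReport-class].
#' @export
crossValidate <- function(response, expression = NULL, fingerprints = NULL,
                          definition = c("mrpcc", "rpcc", "coef"),
                          folds = 10, repetitions = 1, seed = 1,
                          kCell = 20, kDrug = 5, lambdaDrug = 5,
                          lambdaCell = 2, lambda4 = 50, rho = 2.5,
                          minOverlap = 3, srThreshold = 1.0,
                          cellSim = NULL, drugSim = NULL) {
  definition <- match.arg(definition)
  aligned <- alignInputs(response, expression, fingerprints)
  response <- aligned$response
  expression <- aligned$expression
  fingerprints <- aligned$fingerprints
  V <- responseValues(response)
  M <- isObserved(response)
  drugIds <- drugs(response)
  seeds <- as.integer(seed + seq_len(repetitions) - 1L)
  rows <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    assignment <- makeFolds(response, folds = folds, seed = seeds[r])
    predMat <- matrix(NA_real_, nrow(V), ncol(V))
    for (f in seq_len(folds) - 1L) {
      train <- .maskFold(response, assignment, f)
      sims <- buildSimilarities(train, expression, fingerprints, definition,
                                cellSim = cellSim, drugSim = drugSim,
                                lambda4 = lambda4, rho = rho,
                                minOverlap = minOverlap)
      hide <- assignment@fold == f
      tgt <- cbind(assignment@cell[hide], assignment@drug[hide])
      res <- predictResponse(train, sims$cell, sims$drug, kCell = kCell,
                             kDrug = kDrug, targets = tgt,
                             lambdaDrug = lambdaDrug, lambdaCell = lambdaCell)
      predMat[tgt] <- predictedEntries(res)$predicted
    }
    perDrug <- lapply(seq_along(drugIds), function(i) {
      cells <- which(M[, i])
      obs <- V[cells, i]
      pred <- predMat[cells, i]
      main <- if (length(obs) >= 2L) predictionMetrics(obs, pred)
              else c(pcc = NA_real_, rmse = NA_real_)
      srIdx <- if (length(obs) >= 3L && stats::sd(obs) > 0)
        sensitiveResistant(obs, t = srThreshold) else integer(0)
      sr <- if (length(srIdx) >= 2L) predictionMetrics(obs[srIdx], pred[srIdx])
            else c(pcc = NA_real_, rmse = NA_real_)
      data.frame(drug = drugIds[i], repetition = r, n_test = length(obs),
                 pcc = unname(main["pcc"]), rmse = unname(main["rmse"]),
                 n_sr = length(srIdx), pcc_sr = unname(sr["pcc"]),
                 rmse_sr = unname(sr["rmse"]), stringsAsFactors = FALSE)
    })
    rows[[r]] <- do.call(rbind, perDrug)
  }
  dm <- do.call(rbind, rows)
  summarise <- function(col, metric, subset) {
    x <- dm[[col]]
    data.frame(metric = metric, subset = subset,
               mean = mean(x, na.rm = TRUE),
               sd = stats::sd(x, na.rm = TRUE),
               n_defined = sum(!is.na(x)), n_undefined = sum(is.na(x)),
               stringsAsFactors = FALSE)
  }
  summary <- rbind(summarise("pcc", "pcc", "all"),
                   summarise("rmse", "rmse", "all"),
                   summarise("pcc_sr", "pcc", "sensitive_resistant"),
                   summarise("rmse_sr", "rmse", "sensitive_resistant"))
  new("CVReport", drugMetrics = dm, summary = summary,
      config = list(definition = definition, folds = folds,
                    repetitions = repetitions, k_cell = kCell, k_drug = kDrug,
                    lambda_drug = lambdaDrug, lambda_cell = lambdaCell,
                    lambda4 = lambda4, rho = rho, min_overlap = minOverlap,
                    sr_threshold = srThreshold),
      seeds = seeds)
}

#' Write a CVReport as tidy CSV files
#'
#' `path` receives the per-drug long table (drug, repetition, metric, subset,
#' value); `summaryPath`, when given, receives the drug-averaged summary.
#'
#' @param x a [CVReport-class].
#' @param path output CSV for the per-drug metrics.
#' @param summaryPath optional output CSV for the summary table.
#' @return `path`, invisibly.
#' @export
writeCVReport <- function(x, path, summaryPath = NULL) {
  dm <- drugMetrics(x)
  long <- rbind(
    data.frame(drug = dm$drug, repetition = dm$repetition, metric = "pcc",
               subset = "all", value = dm$pcc),
    data.frame(drug = dm$drug, repetition = dm$repetition, metric = "rmse",
               subset = "all", value = dm$rmse),
    data.frame(drug = dm$drug, repetition = dm$repetition, metric = "pcc",
               subset = "sensitive_resistant", value = dm$pcc_sr),
    data.frame(drug = dm$drug, repetition = dm$repetition, metric = "rmse",
               subset = "sensitive_resistant", value = dm$rmse_sr))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  if (!is.null(summaryPath))
    utils::write.csv(cvSummary(x), summaryPath, row.names = FALSE, quote = FALSE)
  invisible(path)
}
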