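## Synthetic response / expression / fingerprint triples with known truth.
##
## The generator emulates the structure the method assumes in real cell-line
## panels: additive row (cell line) and column (drug) bias effects, a shared
## low-rank signal linking the response matrix to both side-information
## matrices, additive Gaussian noise, and uniform missing-at-random masking.
##   response    r_ui = mu0 + b_u + b_i + <c_u, d_i> + eps
##   expression  E    = A c^T + noise   (genes x cell lines)
##   fingerprint F    = 1[B d^T + noise > 0]^T (drugs x bits, ~50% density)
## so that expression-profile correlation tracks cell-factor similarity and
## fingerprint Jaccard similarity tracks drug-factor similarity.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a mid-sized panel: 200 cell lines x 30 drugs, latent
#' rank 3, drug biases wider than cell-line biases (drugs differ in potency
#' far more than lines differ in general resistance), response noise at 20%
#' of the latent-signal scale, and 20% of entries missing at random. Presets
#' for the two canonical public panel shapes are available via
#' [syntheticPreset()].
#'
#' @param m,n,g,p numbers of cell lines, drugs, genes and fingerprint bits.
#' @param d latent rank of the shared signal.
#' @param mu0 global mean response.
#' @param sdBu,sdBi standard deviations of the cell-line and drug biases.
#' @param noiseSD response noise SD; `NULL` (default) means `0.2 * sqrt(d)`,
#'   i.e. 20% of the latent interaction's standard deviation.
#' @param exprNoiseSD,fpNoiseSD noise SDs of the expression map and the
#'   pre-threshold fingerprint map.
#' @param q missing fraction in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return A validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(m = 200, n = 30, g = 300, p = 128, d = 3,
                            mu0 = 3, sdBu = 1, sdBi = 1.5, noiseSD = NULL,
                            exprNoiseSD = 1, fpNoiseSD = 1, q = 0.2,
                            seed = 1) {
  if (is.null(noiseSD)) noiseSD <- 0.2 * sqrt(d)
  cfg <- list(m = m, n = n, g = g, p = p, d = d, mu0 = mu0, sdBu = sdBu,
              sdBi = sdBi, noiseSD = noiseSD, exprNoiseSD = exprNoiseSD,
              fpNoiseSD = fpNoiseSD, q = q, seed = as.integer(seed))
  if (any(c(m, n, g, p, d) < 2))
    stop("all dimensions (m, n, g, p, d) must be at least 2", call. = FALSE)
  if (q < 0 || q >= 1)
    stop("missing fraction q must lie in [0, 1)", call. = FALSE)
  if (any(c(sdBu, sdBi, noiseSD, exprNoiseSD, fpNoiseSD) < 0))
    stop("standard deviations must be non-negative", call. = FALSE)
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Preset synthetic configurations shaped like the public panels
#'
#' `"gdsc"`: 652 cell lines x 135 drugs with 19.7% of entries missing;
#' `"ccle"`: 491 cell lines x 23 drugs with 3.75% missing. `scale` shrinks
#' both panel dimensions (e.g. `scale = 0.25` for a quarter-size panel)
#' while keeping the missingness and signal structure.
#'
#' @param name `"gdsc"` or `"ccle"`.
#' @param scale multiplier on the panel dimensions, in `(0, 1]`.
#' @param ... further arguments passed to [syntheticConfig()].
#' @return A `SyntheticConfig`.
#' @export
syntheticPreset <- function(name = c("gdsc", "ccle"), scale = 1, ...) {
  name <- match.arg(name)
  if (scale <= 0 || scale > 1)
    stop("scale must lie in (0, 1]", call. = FALSE)
  dims <- switch(name,
    gdsc = list(m = 652, n = 135, q = 0.197),
    ccle = list(m = 491, n = 23, q = 0.0375))
  syntheticConfig(m = max(4L, round(dims$m * scale)),
                  n = max(4L, round(dims$n * scale)),
                  q = dims$q, ...)
}

.labels <- function(prefix, k) sprintf("%s%03d", prefix, seq_len(k))

#' Generate a synthetic response / expression / fingerprint triple
#'
#' Draws biases, latent factors and noise as configured, builds the three
#' matrices, and masks a `q` fraction of response entries uniformly at
#' random. The mask is redrawn (up to 100 attempts) if it would leave a cell
#' line or drug with no observed entry; drug rows whose thresholded
#' fingerprint comes out all-zero are resampled the same way. Fully
#' reproducible from `config$seed`; the caller's RNG state is untouched.
#'
#' @param config a `SyntheticConfig` from [syntheticConfig()].
#' @return List with `response` ([ResponseMatrix-class]), `expression`
#'   ([ExpressionMatrix-class]), `fingerprints` ([FingerprintMatrix-class])
#'   and `truth` ([SyntheticTruth-class]).
#' @examples
#' sim <- generateSynthetic(syntheticConfig(m = 30, n = 8, seed = 42))
#' sim$response
#' @export
generateSynthetic <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  .withSeed(config$seed, {
    m <- config$m; n <- config$n; d <- config$d
    cl <- .labels("CL", m); dg <- .labels("D", n)
    bCell <- stats::setNames(stats::rnorm(m, 0, config$sdBu), cl)
    bDrug <- stats::setNames(stats::rnorm(n, 0, config$sdBi), dg)
    C <- matrix(stats::rnorm(m * d), m, d, dimnames = list(cl, NULL))
    D <- matrix(stats::rnorm(n * d), n, d, dimnames = list(dg, NULL))
    noiseless <- config$mu0 + outer(bCell, bDrug, "+") + C %*% t(D)
    values <- noiseless + matrix(stats::rnorm(m * n, 0, config$noiseSD), m, n)
    # expression: linear readout of the cell factors
    A <- matrix(stats::rnorm(config$g * d), config$g, d)
    E <- A %*% t(C) +
      matrix(stats::rnorm(config$g * m, 0, config$exprNoiseSD), config$g, m)
    dimnames(E) <- list(.labels("G", config$g), cl)
    # fingerprints: thresholded linear readout of the drug factors
    B <- matrix(stats::rnorm(config$p * d), config$p, d)
    fp <- (D %*% t(B) +
             matrix(stats::rnorm(n * config$p, 0, config$fpNoiseSD),
                    n, config$p) > 0) * 1
    for (attempt in seq_len(100L)) {
      zero <- rowSums(fp) == 0
      if (!any(zero)) break
      fp[zero, ] <- (D[zero, , drop = FALSE] %*% t(B) +
                       matrix(stats::rnorm(sum(zero) * config$p, 0,
                                           config$fpNoiseSD),
                              sum(zero), config$p) > 0) * 1
    }
    if (any(rowSums(fp) == 0))
      stop("could not draw fingerprints without all-zero rows", call. = FALSE)
    dimnames(fp) <- list(dg, .labels("fp", config$p))
    # missing-at-random mask
    nMiss <- round(config$q * m * n)
    mask <- matrix(TRUE, m, n)
    if (nMiss > 0) {
      for (attempt in seq_len(100L)) {
        cand <- matrix(TRUE, m, n)
        cand[sample.int(m * n, nMiss)] <- FALSE
        if (all(rowSums(cand) > 0) && all(colSums(cand) > 0)) {
          mask <- cand
          break
        }
        if (attempt == 100L)
          stop("missing fraction too high: a cell line or drug lost all entries",
               call. = FALSE)
      }
    }
    dimnames(values) <- list(cl, dg)
    dimnames(mask) <- list(cl, dg)
    list(
      response = ResponseMatrix(values, mask = mask, measure = "ic50_log"),
      expression = ExpressionMatrix(E),
      fingerprints = FingerprintMatrix(fp, fingerprintName = "synthetic"),
      truth = new("SyntheticTruth", mu0 = config$mu0, bCell = bCell,
                  bDrug = bDrug, cellFactors = C, drugFactors = D,
                  noiseless = noiseless))
  })
}

#' Mask additional observed entries at random
#'
#' Hides `round(fraction * n_observed)` of the currently observed entries,
#' chosen uniformly at random; previously missing entries are untouched.
#' Used to carve held-out test sets. The mask is redrawn (up to 100 attempts)
#' if a cell line or drug would lose all its observed entries.
#'
#' @param response a [ResponseMatrix-class].
#' @param fraction fraction of observed entries to hide, in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return A new [ResponseMatrix-class] with the reduced mask.
#' @export
maskEntries <- function(response, fraction, seed = 1) {
  stopifnot(is(response, "ResponseMatrix"))
  if (fraction < 0 || fraction >= 1)
    stop("fraction must lie in [0, 1)", call. = FALSE)
  M <- isObserved(response)
  obs <- which(M)
  nHide <- round(fraction * length(obs))
  if (nHide == 0L) return(response)
  v <- responseValues(response)
  .withSeed(seed, {
    for (attempt in seq_len(100L)) {
      newM <- M
      newM[sample(obs, nHide)] <- FALSE
      if (all(rowSums(newM) > 0) && all(colSums(newM) > 0)) {
        v[!newM] <- NA_real_
        return(ResponseMatrix(v, mask = newM, measure = measureType(response)))
      }
    }
    stop("masking fraction too high: a cell line or drug lost all entries",
         call. = FALSE)
  })
}
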