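# Build an amplified similarity directly from a weight matrix (weights are
# taken as already-shrunk values; amplification with rho = 1 is the identity
# apart from diagonal zeroing).
asAmplified <- function(w, axis) {
  s <- SimilarityMatrix(w, support = matrix(10, nrow(w), ncol(w),
                                            dimnames = dimnames(w)),
                        axis = axis, definition = "rpcc", stage = "shrunk")
  amplifySimilarity(s, rho = 1)
}

test_that("neighbour selection filters, ranks and truncates candidates", {
  v <- matrix(1:20, 4, 5, dimnames = list(lbl("CL", 4), lbl("d", 5)))
  v[1, 4] <- NA
  r <- ResponseMatrix(v)
  ids <- lbl("d", 5)
  w <- matrix(0, 5, 5, dimnames = list(ids, ids))
  w[1, 2] <- w[2, 1] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.5
  w[1, 5] <- w[5, 1] <- 0.1
  w[1, 4] <- w[4, 1] <- 0.7
  sim <- asAmplified(w, "drug")
  # target (CL1, d1): d4 unobserved for CL1, so top-2 among {d2,d3,d5}
  ns <- selectNeighbors(1, 1, sim, r, k = 2, orientation = "drug_oriented")
  expect_equal(ns$neighbors, c(2L, 3L))
  expect_equal(ns$weights, c(0.9, 0.5))
  # k larger than the candidate pool returns all of it, sorted
  ns3 <- selectNeighbors(1, 1, sim, r, k = 10, orientation = "drug_oriented")
  expect_equal(ns3$neighbors, c(2L, 3L, 5L))
  # all-zero weights: empty set
  wz <- matrix(0, 5, 5, dimnames = list(ids, ids))
  nsz <- selectNeighbors(1, 1, asAmplified(wz, "drug"), r, k = 3,
                         orientation = "drug_oriented")
  expect_length(nsz$neighbors, 0)
  expect_error(selectNeighbors(1, 1, sim, r, k = 0, "drug_oriented"), "at least 1")
})

test_that("neighbour selection matches an exhaustive sort oracle", {
  set.seed(77)
  for (rep in 1:10) {
    r <- randomResponse(10, 8, pMissing = 0.2, seed = 400 + rep)
    ids <- lbl("CL", 10)
    w <- matrix(runif(100, -0.5, 1), 10, 10, dimnames = list(ids, ids))
    w <- (w + t(w)) / 2
    sim <- asAmplified(w, "cell_line")
    wAmp <- simValues(sim)
    u <- sample(10, 1); i <- sample(8, 1)
    ns <- selectNeighbors(u, i, sim, r, k = 4, orientation = "cell_line_oriented")
    cand <- setdiff(which(isObserved(r)[, i] & wAmp[u, ] > 0), u)
    expected <- cand[order(-wAmp[u, cand], cand)][seq_len(min(4, length(cand)))]
    expect_equal(ns$neighbors, expected)
  }
})

test_that("single-entry prediction follows the interpolation formula", {
  v <- matrix(5, 4, 4, dimnames = list(lbl("CL", 4), lbl("d", 4)))
  r <- ResponseMatrix(v)
  bl <- new("BaselineModel", mu = 2,
            bCell = setNames(c(0.5, 0, 0, 0), lbl("CL", 4)),
            bDrug = setNames(c(-0.2, 0, 0, 0), lbl("d", 4)),
            lambdaDrug = 5, lambdaCell = 2)
  # both sets empty: baseline with fallback flag; b_ui = 2 + 0.5 - 0.2
  p <- predictEntry(1, 1, list(neighbors = integer(0), weights = numeric(0)),
                    list(neighbors = integer(0), weights = numeric(0)), r, bl)
  expect_true(p$fallback)
  expect_equal(p$value, 2.3)
  # neighbours whose residuals vanish leave the baseline untouched
  vv <- matrix(0, 3, 3, dimnames = list(lbl("CL", 3), lbl("d", 3)))
  vv[1, 2] <- 2; vv[2, 1] <- 2   # equal to their baselines below
  r2 <- ResponseMatrix(vv)
  bl2 <- new("BaselineModel", mu = 2,
             bCell = setNames(rep(0, 3), lbl("CL", 3)),
             bDrug = setNames(rep(0, 3), lbl("d", 3)),
             lambdaDrug = 5, lambdaCell = 2)
  p2 <- predictEntry(1, 1, list(neighbors = 2L, weights = 0.8),
                     list(neighbors = 2L, weights = 0.3), r2, bl2)
  expect_false(p2$fallback)
  expect_equal(p2$value, 2)
  # worked example: drug residuals +1/-1 at weights 0.4/0.1, cell residual
  # +0.5 at weight 0.2 -> correction 1/2 * ((0.4-0.1)/0.5 + 0.5) = 0.55
  vv3 <- matrix(0, 3, 4, dimnames = list(lbl("CL", 3), lbl("d", 4)))
  vv3[1, 2] <- 3; vv3[1, 3] <- 1    # residuals +1, -1 around baseline 2
  vv3[2, 1] <- 2.5                  # residual +0.5
  r3 <- ResponseMatrix(vv3)
  bl3 <- new("BaselineModel", mu = 2,
             bCell = setNames(rep(0, 3), lbl("CL", 3)),
             bDrug = setNames(rep(0, 4), lbl("d", 4)),
             lambdaDrug = 5, lambdaCell = 2)
  p3 <- predictEntry(1, 1, list(neighbors = c(2L, 3L), weights = c(0.4, 0.1)),
                     list(neighbors = 2L, weights = 0.2), r3, bl3)
  expect_equal(p3$value, 2 + 0.55, tolerance = 1e-12)
  # one empty orientation: the other term is used alone (no halving)
  p4 <- predictEntry(1, 1, list(neighbors = c(2L, 3L), weights = c(0.4, 0.1)),
                     list(neighbors = integer(0), weights = numeric(0)), r3, bl3)
  expect_equal(p4$value, 2 + (0.4 - 0.1) / 0.5, tolerance = 1e-12)
  expect_false(p4$fallback)
})

test_that("matrix prediction: constant fixed point and determinism", {
  v <- matrix(4.2, 6, 5, dimnames = list(lbl("CL", 6), lbl("d", 5)))
  v[2, 3] <- NA; v[5, 1] <- NA
  r <- ResponseMatrix(v)
  e <- randomExpression(12, 6, seed = 31)
  fp <- randomFingerprints(5, 16, seed = 31)
  res <- hiwcf(r, e, fp, definition = "mrpcc", targets = "observed")
  expect_equal(predictedEntries(res)$predicted,
               rep(4.2, sum(isObserved(r))), tolerance = 1e-10)
  res2 <- hiwcf(r, e, fp, definition = "mrpcc", targets = "observed")
  expect_identical(predictedEntries(res), predictedEntries(res2))
})

test_that("full pipeline equals the scalar oracle on random small instances", {
  for (s in 1:20) {
    m <- sample(5:10, 1); n <- sample(4:8, 1)
    r <- randomResponse(m, n, pMissing = runif(1, 0.1, 0.35), seed = 500 + s)
    e <- randomExpression(6, m, seed = 600 + s)
    fp <- randomFingerprints(n, 8, seed = 700 + s)
    def <- sample(c("mrpcc", "rpcc", "coef"), 1)
    res <- suppressWarnings(
      hiwcf(r, e, fp, definition = def, targets = "missing",
            kCell = 4, kDrug = 3))
    tgt <- which(!isObserved(r), arr.ind = TRUE)
    o <- oracle_predict(responseValues(r), isObserved(r), exprValues(e),
                        fingerprintValues(fp), tgt, definition = def,
                        kCell = 4, kDrug = 3)
    expect_equal(predictedEntries(res)$predicted, o$predicted,
                 tolerance = 1e-10)
    expect_equal(predictedEntries(res)$fallback, o$fallback)
  }
})

test_that("predictions reduce to the baseline when no weights are positive", {
  r <- randomResponse(6, 5, pMissing = 0.2, seed = 41)
  ids <- cellLines(r); dg <- drugs(r)
  wc <- matrix(0, 6, 6, dimnames = list(ids, ids))
  wd <- matrix(0, 5, 5, dimnames = list(dg, dg))
  res <- predictResponse(r, asAmplified(wc, "cell_line"),
                         asAmplified(wd, "drug"), targets = "missing")
  bl <- fitBaseline(r)
  tgt <- which(!isObserved(r), arr.ind = TRUE)
  expect_true(all(predictedEntries(res)$fallback))
  expect_equal(predictedEntries(res)$predicted,
               baselineMatrix(bl)[tgt], tolerance = 1e-12)
})

test_that("interpolation corrections stay within the neighbour residual range", {
  for (s in 1:5) {
    m <- 8; n <- 6
    r <- randomResponse(m, n, pMissing = 0.25, seed = 800 + s)
    sims <- buildSimilarities(r, definition = "rpcc")
    bl <- fitBaseline(r)
    bmat <- baselineMatrix(bl)
    resid <- responseValues(r) - bmat
    tgt <- which(!isObserved(r), arr.ind = TRUE)
    res <- predictResponse(r, sims$cell, sims$drug, kCell = 4, kDrug = 3,
                           targets = tgt)
    pe <- predictedEntries(res)
    for (t in seq_len(nrow(tgt))) {
      u <- tgt[t, 1]; i <- tgt[t, 2]
      dn <- selectNeighbors(u, i, sims$drug, r, 3, "drug_oriented")
      cn <- selectNeighbors(u, i, sims$cell, r, 4, "cell_line_oriented")
      rs <- c(resid[u, dn$neighbors], resid[cn$neighbors, i])
      if (length(rs) > 0 && !pe$fallback[t]) {
        corr <- pe$predicted[t] - bmat[u, i]
        expect_gte(corr, min(rs) - 1e-10)
        expect_lte(corr, max(rs) + 1e-10)
      }
    }
  }
})

test_that("raising k beyond the candidate pool leaves predictions unchanged", {
  r <- randomResponse(7, 5, pMissing = 0.2, seed = 55)
  sims <- buildSimilarities(r, definition = "rpcc")
  resA <- predictResponse(r, sims$cell, sims$drug, kCell = 50, kDrug = 50)
  resB <- predictResponse(r, sims$cell, sims$drug, kCell = 500, kDrug = 500)
  expect_identical(predictedEntries(resA)$predicted,
                   predictedEntries(resB)$predicted)
})

test_that("prediction guards against mismatched or unprepared similarities", {
  r <- randomResponse(5, 4, seed = 61)
  sims <- buildSimilarities(r, definition = "rpcc")
  raw <- rpccSimilarity(r, "cell_line")
  expect_error(predictResponse(r, raw, sims$drug), "amplified")
  expect_error(predictResponse(r, sims$drug, sims$cell), "axis")
  expect_error(predictResponse(r, sims$cell, sims$drug,
                               targets = cbind(9, 1)), "outside")
})
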