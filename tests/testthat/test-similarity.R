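test_that("expression similarity is the Pearson correlation of profiles", {
  E <- matrix(c(1, 2, 3,
                2, 4, 6,
                3, 2, 1,
                1, 2, 4), 3, 4,
              dimnames = list(lbl("G", 3), lbl("CL", 4)))
  s <- coefCell(ExpressionMatrix(E))
  v <- simValues(s)
  expect_equal(v["CL01", "CL02"], 1)             # scaled copy
  expect_equal(v["CL01", "CL03"], -1)            # reversed profile
  expect_equal(v["CL01", "CL04"],
               oracle_pearson(c(1, 2, 3), c(1, 2, 4)), tolerance = 1e-12)
  expect_equal(unname(simSupport(s)[1, 2]), 3)   # gene count
  # constant profile: undefined correlations set to 0 with a warning
  E2 <- cbind(E, CL05 = c(2, 2, 2))
  expect_warning(s2 <- coefCell(ExpressionMatrix(E2)), "constant")
  expect_equal(unname(simValues(s2)["CL05", "CL01"]), 0)
})

test_that("fingerprint similarity is the Jaccard coefficient", {
  v <- rbind(d1 = c(1, 1, 0, 0), d2 = c(1, 1, 0, 0),
             d3 = c(0, 0, 1, 1), d4 = c(1, 0, 1, 0))
  colnames(v) <- lbl("fp", 4)
  s <- coefDrug(FingerprintMatrix(v))
  expect_equal(simValues(s)["d1", "d2"], 1)
  expect_equal(simValues(s)["d1", "d3"], 0)
  expect_equal(simValues(s)["d1", "d4"], 1 / 3)
  expect_equal(simValues(s), oracle_jaccard(v), ignore_attr = TRUE)
})

test_that("response similarity uses pairwise-complete overlap with support", {
  v <- rbind(CL1 = c(1, 2, NA, 4),
             CL2 = c(2, 4, 6, 8),
             CL3 = c(5, 1, 3, NA))
  colnames(v) <- lbl("d", 4)
  r <- ResponseMatrix(v)
  s <- rpccSimilarity(r, "cell_line", minOverlap = 3)
  expect_equal(simValues(s)["CL1", "CL2"], 1)              # (1,2,4) vs (2,4,8)
  expect_equal(unname(simSupport(s)["CL1", "CL2"]), 3)
  expect_equal(unname(simValues(s)["CL1", "CL3"]), 0)      # overlap 2 < 3
  expect_equal(unname(simSupport(s)["CL1", "CL3"]), 2)
  expect_equal(unname(simValues(s)["CL1", "CL1"]), 1)      # self-correlation
  # overlap 2 allowed when minOverlap lowered: positions {1,2} co-observed
  s2 <- rpccSimilarity(r, "cell_line", minOverlap = 2)
  expect_equal(simValues(s2)["CL1", "CL3"],
               oracle_pearson(c(1, 2), c(5, 1)), tolerance = 1e-12)
})

test_that("response similarity matches the scalar oracle and full-vector cor", {
  for (s in 1:10) {
    r <- randomResponse(7, 6, pMissing = 0.25, seed = 100 + s)
    for (axis in c("cell_line", "drug")) {
      sim <- rpccSimilarity(r, axis)
      V <- responseValues(r); M <- isObserved(r)
      if (axis == "drug") { V <- t(V); M <- t(M) }
      o <- oracle_rpcc_rows(V, M)
      expect_equal(simValues(sim), o$r, tolerance = 1e-10, ignore_attr = TRUE)
      expect_equal(simSupport(sim), o$support, ignore_attr = TRUE)
    }
    # fully observed: equals the standard Pearson matrix
    rf <- randomResponse(7, 6, pMissing = 0, seed = 200 + s)
    simf <- rpccSimilarity(rf, "drug")
    expect_equal(simValues(simf), cor(responseValues(rf)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("MRPCC is the elementwise product with RPCC support", {
  r <- randomResponse(6, 5, pMissing = 0.2, seed = 9)
  e <- randomExpression(10, 6, seed = 9)
  cf <- coefCell(e)
  rp <- rpccSimilarity(r, "cell_line")
  mr <- mrpccSimilarity(cf, rp)
  expect_equal(simValues(mr), simValues(cf) * simValues(rp))
  expect_identical(simSupport(mr), simSupport(rp))
  expect_equal(simDefinition(mr), "mrpcc")
  # product sign: two negatives make a positive
  expect_true(all(sign(simValues(mr)) ==
                  sign(simValues(cf)) * sign(simValues(rp))))
  # coef identically 1 leaves rpcc unchanged
  ones <- SimilarityMatrix(matrix(1, 6, 6, dimnames = dimnames(simValues(cf))),
                           axis = "cell_line", definition = "coef")
  expect_equal(simValues(mrpccSimilarity(ones, rp)), simValues(rp))
  # axis mismatch rejected
  rpD <- rpccSimilarity(r, "drug")
  expect_error(mrpccSimilarity(cf, rpD), "different axes")
})

test_that("shrinkage scales each pair by support/(support+lambda4)", {
  ids <- lbl("d", 3)
  w <- matrix(c(1, 0.8, 0.6, 0.8, 1, 0, 0.6, 0, 1), 3, 3,
              dimnames = list(ids, ids))
  sup <- matrix(c(100, 50, 150, 50, 100, 0, 150, 0, 100), 3, 3,
                dimnames = list(ids, ids))
  s <- SimilarityMatrix(w, support = sup, axis = "drug", definition = "rpcc")
  sh <- shrinkSimilarity(s, lambda4 = 50)
  expect_equal(simValues(sh)[1, 2], 0.4)        # support == lambda4: exactly half
  expect_equal(simValues(sh)[1, 3], 0.45)       # 150/200 * 0.6
  expect_equal(simValues(sh)[2, 3], 0)          # zero support: nullified
  expect_equal(simStage(sh), "shrunk")
  expect_error(shrinkSimilarity(s, lambda4 = -1), "non-negative")
  expect_error(shrinkSimilarity(sh), "raw-stage")
})

test_that("case amplification is w*|w|^(rho-1) with sign kept and 0/±1 fixed", {
  ids <- lbl("x", 4)
  w <- matrix(0, 4, 4, dimnames = list(ids, ids))
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- -0.5
  w[2, 3] <- w[3, 2] <- 1
  w[2, 4] <- w[4, 2] <- -1
  diag(w) <- 1
  s <- SimilarityMatrix(w, support = matrix(10, 4, 4, dimnames = list(ids, ids)),
                        axis = "cell_line", definition = "mrpcc", stage = "shrunk")
  a <- amplifySimilarity(s, rho = 2.5)
  expect_equal(simValues(a)[1, 2], 0.5^2.5)
  expect_equal(simValues(a)[1, 3], -(0.5^2.5))
  expect_equal(simValues(a)[2, 3], 1)
  expect_equal(simValues(a)[2, 4], -1)
  expect_equal(simValues(a)[1, 4], 0)
  expect_equal(unname(diag(simValues(a))), rep(0, 4))  # self never a neighbour
  expect_error(amplifySimilarity(s, rho = 0.5), ">= 1")
})

test_that("shrink and amplify never increase |w|, keep sign, order and symmetry", {
  for (s in 1:5) {
    r <- randomResponse(8, 6, pMissing = 0.3, seed = 300 + s)
    raw <- rpccSimilarity(r, "cell_line")
    sh <- shrinkSimilarity(raw, 50)
    am <- amplifySimilarity(sh, 2.5)
    for (x in list(raw, sh, am))
      expect_lt(max(abs(simValues(x) - t(simValues(x)))), 1e-10)
    expect_true(all(abs(simValues(sh)) <= abs(simValues(raw)) + 1e-12))
    expect_true(all(abs(simValues(am)) <= abs(simValues(sh)) + 1e-12))
    off <- row(simValues(raw)) != col(simValues(raw))
    expect_true(all(sign(simValues(sh)[off]) == sign(simValues(raw)[off]) |
                    simValues(sh)[off] == 0))
    # amplification preserves the ranking of |w| (strictly monotone transform)
    expect_equal(order(abs(simValues(am)[off])), order(abs(simValues(sh)[off])))
  }
})

test_that("similarity matrices round-trip through CSV with metadata", {
  r <- randomResponse(5, 4, seed = 21)
  s <- rpccSimilarity(r, "drug")
  tf <- tempfile(fileext = ".csv")
  writeSimilarity(s, tf)
  s2 <- readSimilarity(tf)
  expect_equal(simValues(s2), simValues(s), tolerance = 1e-12)
  expect_equal(simAxis(s2), "drug")
  expect_equal(simDefinition(s2), "rpcc")
  expect_equal(simStage(s2), "raw")
  unlink(tf)
})
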