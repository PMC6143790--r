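# Small random fixtures built in code.

lbl <- function(prefix, k) sprintf("%s%02d", prefix, seq_len(k))

# Random partially observed response matrix with every row and column keeping
# at least one observation and a minimum pairwise overlap for row pairs.
randomResponse <- function(m, n, pMissing = 0.2, seed = 1) {
  set.seed(seed)
  repeat {
    v <- matrix(rnorm(m * n, mean = 2, sd = 1.5), m, n,
                dimnames = list(lbl("CL", m), lbl("d", n)))
    mask <- matrix(runif(m * n) > pMissing, m, n)
    if (all(rowSums(mask) > 0) && all(colSums(mask) > 0)) {
      v[!mask] <- NA_real_
      return(ResponseMatrix(v))
    }
  }
}

randomExpression <- function(g, m, seed = 1) {
  set.seed(seed)
  ExpressionMatrix(matrix(rnorm(g * m), g, m,
                          dimnames = list(lbl("G", g), lbl("CL", m))))
}

randomFingerprints <- function(n, p, seed = 1) {
  set.seed(seed)
  repeat {
    v <- matrix(rbinom(n * p, 1, 0.5), n, p,
                dimnames = list(lbl("d", n), lbl("fp", p)))
    if (all(rowSums(v) > 0)) return(FingerprintMatrix(v))
  }
}

# Pure-noise dataset: response unrelated to the (random) side information.
noiseDataset <- function(m, n, g = 50, p = 32, pMissing = 0.1, seed = 1) {
  list(response = randomResponse(m, n, pMissing, seed),
       expression = randomExpression(g, m, seed + 1000),
       fingerprints = randomFingerprints(n, p, seed + 2000))
}
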