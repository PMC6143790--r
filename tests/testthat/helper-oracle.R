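# Scalar reference implementations of every pipeline stage, written with
# explicit loops and sharing no code with the package. These act as
# independent oracles for the vectorised implementation.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (k in seq_len(n)) {
    num <- num + (x[k] - mx) * (y[k] - my)
    dx <- dx + (x[k] - mx)^2
    dy <- dy + (y[k] - my)^2
  }
  if (dx == 0 || dy == 0) return(NA_real_)
  num / sqrt(dx * dy)
}

oracle_baseline <- function(V, M, lambda2 = 5, lambda3 = 2) {
  m <- nrow(V); n <- ncol(V)
  tot <- 0; cnt <- 0
  for (u in seq_len(m)) for (i in seq_len(n)) if (M[u, i]) {
    tot <- tot + V[u, i]; cnt <- cnt + 1
  }
  mu <- tot / cnt
  bD <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0; c <- 0
    for (u in seq_len(m)) if (M[u, i]) { s <- s + V[u, i] - mu; c <- c + 1 }
    bD[i] <- if (c > 0) s / (lambda2 + c) else 0
  }
  bC <- numeric(m)
  for (u in seq_len(m)) {
    s <- 0; c <- 0
    for (i in seq_len(n)) if (M[u, i]) { s <- s + V[u, i] - mu - bD[i]; c <- c + 1 }
    bC[u] <- if (c > 0) s / (lambda3 + c) else 0
  }
  list(mu = mu, bCell = bC, bDrug = bD)
}

# Pairwise-complete Pearson over rows of V; zero when overlap < minOverlap or
# degenerate. Returns similarity and overlap-count matrices.
oracle_rpcc_rows <- function(V, M, minOverlap = 3) {
  m <- nrow(V)
  r <- matrix(0, m, m)
  sup <- matrix(0, m, m)
  for (u in seq_len(m)) for (v in seq_len(m)) {
    both <- which(M[u, ] & M[v, ])
    sup[u, v] <- length(both)
    if (length(both) >= minOverlap) {
      val <- oracle_pearson(V[u, both], V[v, both])
      r[u, v] <- if (is.na(val)) 0 else val
    }
  }
  list(r = r, support = sup)
}

oracle_jaccard <- function(Fp) {
  n <- nrow(Fp)
  r <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    inter <- 0; uni <- 0
    for (b in seq_len(ncol(Fp))) {
      if (Fp[i, b] == 1 && Fp[j, b] == 1) inter <- inter + 1
      if (Fp[i, b] == 1 || Fp[j, b] == 1) uni <- uni + 1
    }
    r[i, j] <- inter / uni
  }
  r
}

oracle_coef_expression <- function(E) {
  m <- ncol(E)
  r <- matrix(0, m, m)
  for (u in seq_len(m)) for (v in seq_len(m)) {
    val <- oracle_pearson(E[, u], E[, v])
    r[u, v] <- if (is.na(val)) 0 else val
  }
  r
}

oracle_shrink <- function(w, sup, lambda4 = 50) {
  out <- w
  for (i in seq_len(nrow(w))) for (j in seq_len(ncol(w)))
    out[i, j] <- if (sup[i, j] + lambda4 > 0)
      sup[i, j] / (sup[i, j] + lambda4) * w[i, j] else 0
  out
}

oracle_amplify <- function(w, rho = 2.5) {
  out <- w
  for (i in seq_len(nrow(w))) for (j in seq_len(ncol(w)))
    out[i, j] <- w[i, j] * abs(w[i, j])^(rho - 1)
  diag(out) <- 0
  out
}

# Full scalar pipeline: baseline + similarities + dual-orientation kNN
# prediction for the given target entries. definition in coef/rpcc/mrpcc.
oracle_predict <- function(V, M, E, Fp, targets, definition = "mrpcc",
                           kCell = 20, kDrug = 5, lambda2 = 5, lambda3 = 2,
                           lambda4 = 50, rho = 2.5, minOverlap = 3) {
  bl <- oracle_baseline(V, M, lambda2, lambda3)
  m <- nrow(V); n <- ncol(V)
  rpC <- oracle_rpcc_rows(V, M, minOverlap)
  rpD <- oracle_rpcc_rows(t(V), t(M), minOverlap)
  wC <- switch(definition,
    coef = oracle_coef_expression(E),
    rpcc = rpC$r,
    mrpcc = oracle_coef_expression(E) * rpC$r)
  wD <- switch(definition,
    coef = oracle_jaccard(Fp),
    rpcc = rpD$r,
    mrpcc = oracle_jaccard(Fp) * rpD$r)
  wC <- oracle_amplify(oracle_shrink(wC, rpC$support, lambda4), rho)
  wD <- oracle_amplify(oracle_shrink(wD, rpD$support, lambda4), rho)
  bmat <- matrix(0, m, n)
  for (u in seq_len(m)) for (i in seq_len(n))
    bmat[u, i] <- bl$mu + bl$bCell[u] + bl$bDrug[i]
  out <- numeric(nrow(targets))
  fell <- logical(nrow(targets))
  for (t in seq_len(nrow(targets))) {
    u <- targets[t, 1]; i <- targets[t, 2]
    # drug-oriented
    cand <- setdiff(which(M[u, ] & wD[i, ] > 0), i)
    termD <- NULL
    if (length(cand) > 0) {
      cand <- cand[order(-wD[i, cand], cand)][seq_len(min(kDrug, length(cand)))]
      sw <- sum(wD[i, cand])
      if (sw >= 1e-12)
        termD <- sum(wD[i, cand] * (V[u, cand] - bmat[u, cand])) / sw
    }
    # cell-line-oriented
    cand <- setdiff(which(M[, i] & wC[u, ] > 0), u)
    termC <- NULL
    if (length(cand) > 0) {
      cand <- cand[order(-wC[u, cand], cand)][seq_len(min(kCell, length(cand)))]
      sw <- sum(wC[u, cand])
      if (sw >= 1e-12)
        termC <- sum(wC[u, cand] * (V[cand, i] - bmat[cand, i])) / sw
    }
    terms <- c(termD, termC)
    if (length(terms) == 0) {
      out[t] <- bmat[u, i]
      fell[t] <- TRUE
    } else {
      out[t] <- bmat[u, i] + sum(terms) / length(terms)
    }
  }
  list(predicted = out, fallback = fell)
}
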