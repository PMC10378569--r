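# Brute-force oracle estimators, independent of the package implementation:
# contingency tables are enumerated cell by cell with base::table(), and the
# conditional quantities stratify explicitly instead of using entropy
# identities.

oracle_entropy <- function(x, base = 2) {
  n <- length(x)
  h <- 0
  for (cnt in as.vector(table(x))) {
    if (cnt > 0) {
      p <- cnt / n
      h <- h - p * log(p, base)
    }
  }
  h
}

oracle_mi <- function(x, y, base = 2) {
  n <- length(x)
  tab <- table(x, y)
  px <- unname(rowSums(tab)) / n
  py <- unname(colSums(tab)) / n
  s <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pxy <- tab[i, j] / n
      if (pxy > 0) s <- s + pxy * log(pxy / (px[i] * py[j]), base)
    }
  }
  s
}

oracle_cmi <- function(x, y, z, base = 2) {
  s <- 0
  for (zz in unique(z)) {
    idx <- z == zz
    s <- s + mean(idx) * oracle_mi(x[idx], y[idx], base)
  }
  s
}

oracle_interaction <- function(x, y, z, base = 2) {
  oracle_mi(paste(x, y), z, base) -
    oracle_mi(x, z, base) - oracle_mi(y, z, base)
}

oracle_omega <- function(fj, fk, cl, base = 2) {
  den <- oracle_entropy(fj, base) + oracle_entropy(cl, base)
  if (den == 0) return(1)
  1 + 2 * (oracle_cmi(fj, cl, fk, base) - oracle_mi(fj, cl, base)) / den
}

# Criterion score of candidate column k given selected columns `sel`,
# recomputed from raw contingency enumeration.
oracle_candidate_score <- function(name, codes, cl, sel, k,
                                   beta = 1, base = 2) {
  xk <- codes[, k]
  if (length(sel) == 0L) return(oracle_mi(xk, cl, base))
  rel <- oracle_mi(xk, cl, base)
  red <- function() sum(vapply(sel, function(j)
    oracle_mi(xk, codes[, j], base), numeric(1)))
  cond <- function() sum(vapply(sel, function(j)
    oracle_cmi(xk, codes[, j], cl, base), numeric(1)))
  switch(name,
    wbfs = sum(vapply(sel, function(j)
      oracle_omega(codes[, j], xk, cl, base) *
        oracle_cmi(xk, cl, codes[, j], base), numeric(1))),
    mim = rel,
    mifs = rel - beta * red(),
    mrmr = rel - red() / length(sel),
    cife = rel - red() + cond(),
    condred = rel + cond(),
    disr = sum(vapply(sel, function(j) {
      pair <- paste(xk, codes[, j])
      hj <- oracle_entropy(paste(pair, cl), base)
      if (hj == 0) 0 else oracle_mi(pair, cl, base) / hj
    }, numeric(1))))
}
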