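# Independent brute-force oracles and small data builders used across the
# suite. Oracles deliberately use naive loops, not the package's vectorized
# code paths.

# random balanced RCBD trial as a plain data.frame of plot records
random_trial <- function(G, E, r, seed, mu = 10, sd = 1) {
  set.seed(seed)
  rec <- expand.grid(genotype = sprintf("g%02d", seq_len(G)),
                     environment = sprintf("e%d", seq_len(E)),
                     block = paste0("b", seq_len(r)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec$yield <- abs(mu + rnorm(nrow(rec), 0, sd))
  rec
}

# per-cell averaging by explicit loop
oracle_cell_means <- function(rec, genotypes, environments) {
  out <- matrix(NA_real_, length(genotypes), length(environments),
                dimnames = list(genotypes, environments))
  for (g in genotypes) {
    for (e in environments) {
      out[g, e] <- mean(rec$yield[rec$genotype == g & rec$environment == e])
    }
  }
  out
}

# RCBD strata by explicit group-by-group summation of squared deviations
oracle_rcbd_ss <- function(rec) {
  genotypes <- unique(rec$genotype)
  environments <- unique(rec$environment)
  G <- length(genotypes); E <- length(environments)
  r <- nrow(rec) / (G * E)
  grand <- mean(rec$yield)
  ssE <- 0
  for (e in environments) {
    ssE <- ssE + G * r * (mean(rec$yield[rec$environment == e]) - grand)^2
  }
  ssB <- 0
  for (e in environments) {
    sub <- rec[rec$environment == e, ]
    em <- mean(sub$yield)
    for (b in unique(sub$block)) {
      ssB <- ssB + G * (mean(sub$yield[sub$block == b]) - em)^2
    }
  }
  ssG <- 0
  for (g in genotypes) {
    ssG <- ssG + E * r * (mean(rec$yield[rec$genotype == g]) - grand)^2
  }
  ssGE <- 0
  for (g in genotypes) {
    for (e in environments) {
      cellm <- mean(rec$yield[rec$genotype == g & rec$environment == e])
      gm <- mean(rec$yield[rec$genotype == g])
      em <- mean(rec$yield[rec$environment == e])
      ssGE <- ssGE + r * (cellm - gm - em + grand)^2
    }
  }
  ssTot <- sum((rec$yield - grand)^2)
  list(ssE = ssE, ssB = ssB, ssG = ssG, ssGE = ssGE,
       ssErr = ssTot - ssE - ssB - ssG - ssGE, ssTotal = ssTot)
}

# competition rank by counting strictly better values
oracle_rank <- function(values, descending = FALSE) {
  vapply(seq_along(values), function(i) {
    if (descending) sum(values > values[i]) + 1L
    else sum(values < values[i]) + 1L
  }, integer(1))
}

# a small CellMeans with known low-rank interaction planted by hand
planted_means <- function(G = 8, E = 4, d = c(3, 1), r = 2, seed = 7,
                          mu = 12) {
  set.seed(seed)
  alpha <- rnorm(G); alpha <- alpha - mean(alpha)
  beta <- rnorm(E); beta <- beta - mean(beta)
  ctr <- function(n, k) {
    X <- matrix(rnorm(n * k), n, k)
    X <- sweep(X, 2, colMeans(X))
    qr.Q(qr(X))
  }
  U <- ctr(G, length(d)); V <- ctr(E, length(d))
  Y <- mu + outer(alpha, beta, "+") + U %*% (d * t(V))
  dimnames(Y) <- list(sprintf("g%02d", seq_len(G)),
                      sprintf("e%d", seq_len(E)))
  CellMeans(Y, replicateCount = r)
}

# flip the sign of one interaction axis of a fit (tests sign invariance)
flip_axis <- function(fit, n) {
  fit@genotypeScores[, n] <- -fit@genotypeScores[, n]
  fit@environmentScores[, n] <- -fit@environmentScores[, n]
  fit
}
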