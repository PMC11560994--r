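#' @include biplot.R
NULL

# run code under a given RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# orthonormal columns, each orthogonal to the constant vector (zero-sum)
# and, optionally, with zero entries at `zeroRows`
random_zero_sum_axes <- function(n, k, zeroRows = integer()) {
  if (k == 0L) return(matrix(numeric(), n, 0L))
  base <- cbind(rep(1, n))
  for (i in zeroRows) {
    e <- numeric(n); e[i] <- 1
    base <- cbind(base, e)
  }
  if (k > n - ncol(base)) {
    stop("cannot build ", k, " orthonormal zero-sum axes of length ", n,
         " with ", length(zeroRows), " zeroed rows", call. = FALSE)
  }
  X <- matrix(stats::rnorm(n * k), n, k)
  # project draws off the constant/indicator space, then orthonormalize
  Qb <- qr.Q(qr(base))
  X <- X - Qb %*% crossprod(Qb, X)
  Q <- qr.Q(qr(X))
  # fix QR's arbitrary column signs deterministically
  for (j in seq_len(k)) {
    i <- which.max(abs(Q[, j]))
    if (Q[i, j] < 0) Q[, j] <- -Q[, j]
  }
  Q
}

#' Generate a synthetic RCBD multi-environment trial with planted AMMI
#' structure
#'
#' Draws a trial from the generative model the AMMI decomposition assumes:
#' plot yield = mu + alpha_g + beta_e + sum_k d_k u_gk v_ek + block effect
#' + plot error, with centered main effects, a planted low-rank interaction
#' built from random orthonormal zero-sum axes, block effects nested in
#' environments, and i.i.d. Gaussian plot error. The same seed reproduces
#' the trial bit for bit; the caller's RNG state is left untouched.
#'
#' Defaults emulate the packaged maize reference trial: 69 genotypes, five
#' locations, three blocks, grand mean 13.18 t/ha, main-effect spreads and
#' interaction singular values matching its ANOVA partition, plot error SD
#' 0.8 t/ha (error MS 0.64) and a small block SD.
#'
#' @param G,E,r Genotypes (>= 3), environments (>= 3), replicates (>= 1).
#' @param mu Grand mean (t/ha).
#' @param alphaSd,betaSd SDs of the genotype/environment main-effect draws
#'   (centered after drawing).
#' @param singularValues Planted mean-basis interaction singular values
#'   (decreasing; length at most `min(G-1, E-1) - length(zeroLoadingGenotypes)`).
#' @param blockSd,errorSd Block-effect and plot-error SDs (>= 0).
#' @param seed Integer seed.
#' @param zeroLoadingGenotypes Optional indices of genotypes forced to zero
#'   loading on every interaction axis (perfectly stable by construction).
#' @return List with `trial` ([TrialData-class]) and `truth`
#'   ([SyntheticTruth-class]).
#' @examples
#' sim <- generateMet(G = 10, E = 4, r = 3, singularValues = c(2, 1),
#'                    seed = 42)
#' sim$truth
#' @export
generateMet <- function(G = 69L, E = 5L, r = 3L, mu = 13.18,
                        alphaSd = 0.92, betaSd = 0.86,
                        singularValues = c(7.59, 7.11, 6.01, 5.18),
                        blockSd = 0.12, errorSd = 0.8, seed = 1L,
                        zeroLoadingGenotypes = integer()) {
  G <- as.integer(G); E <- as.integer(E); r <- as.integer(r)
  if (G < 3L || E < 3L) stop("need G >= 3 and E >= 3")
  if (r < 1L) stop("need r >= 1")
  K <- length(singularValues)
  if (K > min(G - 1L, E - 1L)) {
    stop("planted rank ", K, " infeasible for a ", G, " x ", E, " table",
         call. = FALSE)
  }
  if (any(singularValues < 0)) stop("singular values must be nonnegative")
  if (K > 1L && is.unsorted(rev(singularValues))) {
    stop("singularValues must be non-increasing (axis order is the SVD's)")
  }
  if (alphaSd < 0 || betaSd < 0 || blockSd < 0 || errorSd < 0) {
    stop("standard deviations must be nonnegative")
  }

  out <- with_seed(seed, {
    alpha <- stats::rnorm(G, 0, alphaSd); alpha <- alpha - mean(alpha)
    beta <- stats::rnorm(E, 0, betaSd); beta <- beta - mean(beta)
    U <- random_zero_sum_axes(G, K, zeroRows = zeroLoadingGenotypes)
    V <- random_zero_sum_axes(E, K)
    omega <- if (K > 0L) U %*% (singularValues * t(V)) else matrix(0, G, E)
    blocks <- matrix(stats::rnorm(E * r, 0, blockSd), E, r)
    eps <- array(stats::rnorm(G * E * r, 0, errorSd), dim = c(G, E, r))
    list(alpha = alpha, beta = beta, U = U, V = V, omega = omega,
         blocks = blocks, eps = eps)
  })

  gid <- sprintf("g%02d", seq_len(G))
  eid <- sprintf("e%d", seq_len(E))
  cell <- mu + outer(out$alpha, out$beta, "+") + out$omega
  rec <- expand.grid(genotype = gid, environment = eid,
                     block = paste0("b", seq_len(r)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(rec$genotype, gid); ei <- match(rec$environment, eid)
  ki <- match(rec$block, paste0("b", seq_len(r)))
  rec$yield <- cell[cbind(gi, ei)] + out$blocks[cbind(ei, ki)] +
    out$eps[cbind(gi, ei, ki)]
  if (any(rec$yield <= 0)) {
    stop("generated nonpositive yields; raise mu or lower the SDs",
         call. = FALSE)
  }

  names(out$alpha) <- gid; names(out$beta) <- eid
  truth <- methods::new("SyntheticTruth",
    mu = mu, alpha = out$alpha, beta = out$beta,
    singularValues = as.numeric(singularValues),
    genotypeAxes = out$U, environmentAxes = out$V,
    blockSd = blockSd, errorSd = errorSd, seed = as.integer(seed)
  )
  list(trial = TrialData(rec, genotypes = gid, environments = eid),
       truth = truth)
}

#' Simulation study of AMMI parameter recovery
#'
#' Repeatedly generates trials under one configuration, fits the AMMI model
#' to each trial's cell means, and summarizes how well the planted
#' interaction is recovered: bias and RMSE of each singular value, the
#' distribution of the axis-1 explained %, and the Spearman agreement
#' between the planted and estimated ASV rankings.
#'
#' @param G,E,r,mu,alphaSd,betaSd,singularValues,blockSd,errorSd Passed to
#'   [generateMet()]; `singularValues` must have length >= 2 for the ASV
#'   agreement to be defined.
#' @param nReps Number of replicate trials (>= 1).
#' @param seed Base seed; replicate i uses `seed + i`.
#' @return List with `perAxis` (data.frame: axis, trueD, meanEst, bias,
#'   rmse, relRmse), `explainedPct1` (summary stats of the axis-1 share),
#'   `asvRankCor` (mean Spearman correlation, `NA` when planted rank < 2),
#'   `nReps` and `seed`.
#' @export
recoveryStudy <- function(G = 50L, E = 5L, r = 3L, mu = 13.18,
                          alphaSd = 0.92, betaSd = 0.86,
                          singularValues = c(6, 3), blockSd = 0.12,
                          errorSd = 0.3, nReps = 200L, seed = 1L) {
  nReps <- as.integer(nReps)
  if (nReps < 1L) stop("nReps must be >= 1")
  K <- length(singularValues)
  dEst <- matrix(NA_real_, nReps, max(K, 1L))
  expl1 <- numeric(nReps)
  asvCor <- rep(NA_real_, nReps)

  for (i in seq_len(nReps)) {
    sim <- generateMet(G = G, E = E, r = r, mu = mu, alphaSd = alphaSd,
                       betaSd = betaSd, singularValues = singularValues,
                       blockSd = blockSd, errorSd = errorSd,
                       seed = seed + i)
    fit <- fitAmmi(cellMeans(sim$trial), nAxes = "all")
    d <- fit@singularValues
    dEst[i, seq_len(min(K, length(d)))] <- d[seq_len(min(K, length(d)))]
    expl1[i] <- fit@axisTable$explainedPct[1L]
    if (K >= 2L) {
      tr <- sim$truth
      wTrue <- tr@singularValues[1L]^2 / tr@singularValues[2L]^2
      asvTrue <- asvFromScores(
        tr@genotypeAxes[, 1L] * sqrt(tr@singularValues[1L]),
        tr@genotypeAxes[, 2L] * sqrt(tr@singularValues[2L]), wTrue)
      asvHat <- asv(fit)
      asvCor[i] <- stats::cor(rank(asvTrue), rank(as.numeric(asvHat)))
    }
  }

  perAxis <- data.frame(
    axis = seq_len(K),
    trueD = as.numeric(singularValues),
    meanEst = colMeans(dEst[, seq_len(K), drop = FALSE]),
    stringsAsFactors = FALSE
  )
  if (K > 0L) {
    perAxis$bias <- perAxis$meanEst - perAxis$trueD
    err2 <- sweep(dEst[, seq_len(K), drop = FALSE], 2L, perAxis$trueD)^2
    perAxis$rmse <- sqrt(colMeans(err2))
    perAxis$relRmse <- perAxis$rmse / perAxis$trueD
  }
  list(
    perAxis = perAxis,
    explainedPct1 = c(mean = mean(expl1), sd = stats::sd(expl1),
                      min = min(expl1), max = max(expl1)),
    asvRankCor = if (K >= 2L) mean(asvCor) else NA_real_,
    nReps = nReps,
    seed = as.integer(seed)
  )
}
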