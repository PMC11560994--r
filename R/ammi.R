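#' @include anova.R
NULL

#' Double-center a cell-mean matrix
#'
#' Removes the additive structure: subtracts row (genotype) and column
#' (environment) means and adds back the grand mean, leaving the
#' interaction matrix whose rows and columns all sum to zero.
#'
#' @param means A [CellMeans-class] object or a plain numeric matrix.
#' @return List with `mu` (grand mean), `alpha` (genotype deviations),
#'   `beta` (environment deviations) and `centered` (the G x E interaction
#'   matrix).
#' @examples
#' doubleCenter(matrix(c(1, 0, 0, 1), 2,
#'                     dimnames = list(c("g1", "g2"), c("e1", "e2"))))
#' @export
doubleCenter <- function(means) {
  Y <- if (methods::is(means, "CellMeans")) yieldMatrix(means) else as.matrix(means)
  mu <- mean(Y)
  alpha <- rowMeans(Y) - mu
  beta <- colMeans(Y) - mu
  centered <- Y - outer(alpha, beta, function(a, b) a + b) - mu
  list(mu = mu, alpha = alpha, beta = beta, centered = centered)
}

#' Gollob degrees of freedom for a multiplicative interaction term
#'
#' The n-th interaction axis of a G x E table is assigned
#' `G + E - 1 - 2n` degrees of freedom for its approximate F test.
#'
#' @param n Axis index (1-based), at most `min(G - 1, E - 1)`.
#' @param G,E Numbers of genotypes and environments.
#' @return Integer degrees of freedom.
#' @examples
#' gollobDf(1, G = 69, E = 5) # 71
#' @export
gollobDf <- function(n, G, E) {
  nmax <- min(G - 1L, E - 1L)
  if (any(n < 1L | n > nmax)) {
    stop("axis index must lie in 1..min(G-1, E-1) = ", nmax, call. = FALSE)
  }
  as.integer(G + E - 1L - 2L * n)
}

# count axes numerically distinguishable from zero: relative to the leading
# singular value and to the data scale (an exactly additive table must
# report zero usable axes, not min(G-1, E-1) machine-noise ones)
n_usable_axes <- function(d, scale) {
  if (!length(d)) return(0L)
  thr <- max(1e-10 * d[1L], 1e-12 * max(1, abs(scale)))
  sum(d > thr)
}

# orient axis signs: flip each axis so the environment carrying the largest
# absolute score on that axis gets a positive score
orient_env_max <- function(gs, es) {
  for (n in seq_len(ncol(es))) {
    j <- which.max(abs(es[, n]))
    if (length(j) && es[j, n] < 0) {
      es[, n] <- -es[, n]
      gs[, n] <- -gs[, n]
    }
  }
  list(gs = gs, es = es)
}

#' Fit the AMMI model to a cell-mean matrix
#'
#' Additive main effects by double-centering, multiplicative interaction by
#' singular value decomposition of the centered matrix. Scores are scaled
#' symmetrically -- genotype and environment sides each carry the square
#' root of the singular value -- so that for every axis n the sum of squared
#' scores on either side equals d_n, and the outer product of the two score
#' columns reconstructs that axis's interaction term. Per-axis plot-basis
#' sums of squares are `r * d_n^2`; the per-axis share of the interaction
#' SS is `d_n^2 / sum(d^2) * 100`.
#'
#' Axis signs from an SVD are arbitrary; with `orient = "env-max"` each
#' axis is flipped so the environment with the largest absolute score is
#' positive. All substantive outputs (SS, explained %, ASV, fitted values,
#' selections) are invariant to these flips.
#'
#' @param means A [CellMeans-class] object.
#' @param nAxes Number of axes to retain for the fitted/residual split:
#'   an integer, `"all"`, or `"auto"` (the Gollob-significant count at
#'   `alphaLevel` when `errorMs`/`errorDf` are supplied, else 2 -- the
#'   biplot convention -- capped at the available axes).
#' @param errorMs,errorDf Optional pooled plot-error mean square and d.f.;
#'   when present, per-axis F and p values against that error are filled in.
#' @param alphaLevel Significance level used by `nAxes = "auto"`.
#' @param orient `"env-max"` (default) or `"none"`.
#' @return An [AmmiFit-class] object carrying scores for *all* available
#'   axes regardless of `nAxes`; `nAxes` only sets the retained count used
#'   by [fittedMatrix()] defaults and the stored residual.
#' @examples
#' fit <- fitAmmi(smoliceMaize()$means, errorMs = 432.9 / 680, errorDf = 680)
#' axisSummary(fit)
#' @export
fitAmmi <- function(means, nAxes = "auto", errorMs = NULL, errorDf = NULL,
                    alphaLevel = 0.05, orient = c("env-max", "none")) {
  stopifnot(methods::is(means, "CellMeans"))
  orient <- match.arg(orient)
  if (xor(is.null(errorMs), is.null(errorDf))) {
    stop("supply errorMs and errorDf together")
  }
  Y <- yieldMatrix(means)
  G <- nrow(Y); E <- ncol(Y)
  nAvail <- min(G - 1L, E - 1L)
  if (nAvail < 1L) stop("need at least 2 genotypes and 2 environments")
  r <- replicateCount(means)

  dc <- doubleCenter(Y)
  sv <- svd(dc$centered)
  d <- sv$d[seq_len(nAvail)]
  d[d < 0] <- 0
  gs <- sv$u[, seq_len(nAvail), drop = FALSE] %*% diag(sqrt(d), nAvail)
  es <- sv$v[, seq_len(nAvail), drop = FALSE] %*% diag(sqrt(d), nAvail)
  if (orient == "env-max") {
    o <- orient_env_max(gs, es)
    gs <- o$gs; es <- o$es
  }
  dimnames(gs) <- list(rownames(Y), paste0("IPCA", seq_len(nAvail)))
  dimnames(es) <- list(colnames(Y), paste0("IPCA", seq_len(nAvail)))

  ssAxis <- r * d^2
  dfAxis <- gollobDf(seq_len(nAvail), G, E)
  totalD2 <- sum(d^2)
  expl <- if (totalD2 > 0) 100 * d^2 / totalD2 else rep(NA_real_, nAvail)
  axisTable <- data.frame(
    axis = seq_len(nAvail),
    singularValue = d,
    ss = ssAxis,
    df = dfAxis,
    ms = ssAxis / dfAxis,
    f = NA_real_,
    p = NA_real_,
    explainedPct = expl,
    stringsAsFactors = FALSE
  )
  if (!is.null(errorMs) && errorMs > 0) {
    axisTable$f <- axisTable$ms / errorMs
    axisTable$p <- stats::pf(axisTable$f, axisTable$df, errorDf,
                             lower.tail = FALSE)
  }

  nPos <- n_usable_axes(d, dc$mu)
  retained <- if (identical(nAxes, "all")) {
    nAvail
  } else if (identical(nAxes, "auto")) {
    if (!is.null(errorMs) && errorMs > 0) {
      sig <- !is.na(axisTable$p) & axisTable$p < alphaLevel
      leading_run(sig)
    } else {
      min(2L, nPos)
    }
  } else {
    nAxes <- as.integer(nAxes)
    if (is.na(nAxes) || nAxes < 0L || nAxes > nAvail) {
      stop("nAxes must lie in 0..", nAvail, call. = FALSE)
    }
    nAxes
  }

  recon <- if (retained > 0L) {
    gs[, seq_len(retained), drop = FALSE] %*%
      t(es[, seq_len(retained), drop = FALSE])
  } else {
    matrix(0, G, E)
  }

  methods::new("AmmiFit",
    grandMean = dc$mu,
    genotypeEffects = dc$alpha,
    environmentEffects = dc$beta,
    singularValues = d,
    genotypeScores = gs,
    environmentScores = es,
    residual = dc$centered - recon,
    replicateCount = r,
    nRetained = as.integer(retained),
    axisTable = axisTable,
    orientation = orient
  )
}

leading_run <- function(flags) {
  n <- 0L
  for (f in flags) {
    if (!isTRUE(f)) break
    n <- n + 1L
  }
  n
}

#' Approximate F tests for the interaction axes (Gollob)
#'
#' Tests each multiplicative axis against an externally supplied pooled
#' error mean square: axis MS is the plot-basis axis SS divided by the
#' Gollob degrees of freedom `G + E - 1 - 2n`, F is axis MS over error MS,
#' and the p value is the upper tail of F(df_axis, df_error). The
#' recommended number of axes to retain is the count of *leading*
#' consecutive significant axes.
#'
#' @param fit An [AmmiFit-class] object.
#' @param errorMs Pooled plot-error mean square (> 0).
#' @param errorDf Its degrees of freedom (>= 1).
#' @param alphaLevel Significance level for the retention recommendation.
#' @return List with `table` (axis, ss, df, ms, f, p, significant) and
#'   `recommendedN`.
#' @export
gollobTest <- function(fit, errorMs, errorDf, alphaLevel = 0.05) {
  stopifnot(methods::is(fit, "AmmiFit"))
  if (!is.numeric(errorMs) || errorMs <= 0) stop("errorMs must be positive")
  if (errorDf < 1) stop("errorDf must be >= 1")
  tab <- fit@axisTable[c("axis", "ss", "df", "ms")]
  tab$f <- tab$ms / errorMs
  tab$p <- stats::pf(tab$f, tab$df, errorDf, lower.tail = FALSE)
  tab$significant <- tab$p < alphaLevel
  list(table = tab, recommendedN = leading_run(tab$significant))
}

#' Combined AMMI analysis-of-variance table
#'
#' Assembles the publication-style table: genotype, environment and
#' interaction strata, the interaction split into its multiplicative axes
#' (with Gollob d.f.), a residual interaction row for the axes beyond the
#' retained ones, and the error stratum when supplied. The explained %
#' column follows the convention of published AMMI tables: main strata as a
#' share of the summed SS (including error when available), interaction
#' axes as a share of the interaction SS.
#'
#' @param fit An [AmmiFit-class] object.
#' @param errorMs,errorDf Optional pooled error mean square and d.f.
#' @param nAxesShown How many leading axes to list individually; default is
#'   the fit's retained count, with a pooled `GxE residual` row for the rest.
#' @return data.frame in the layout of [partitionRcbd()].
#' @export
ammiAnovaTable <- function(fit, errorMs = NULL, errorDf = NULL,
                           nAxesShown = NULL) {
  stopifnot(methods::is(fit, "AmmiFit"))
  if (xor(is.null(errorMs), is.null(errorDf))) {
    stop("supply errorMs and errorDf together")
  }
  G <- length(fit@genotypeEffects)
  E <- length(fit@environmentEffects)
  r <- fit@replicateCount
  if (is.null(nAxesShown)) nAxesShown <- fit@nRetained
  nAxesShown <- min(as.integer(nAxesShown), length(fit@singularValues))

  ssG <- r * E * sum(fit@genotypeEffects^2)
  ssE <- r * G * sum(fit@environmentEffects^2)
  ssGE <- r * sum(fit@singularValues^2)
  haveErr <- !is.null(errorMs) && errorMs > 0
  ssErr <- if (haveErr) errorMs * errorDf else 0
  total <- ssG + ssE + ssGE + ssErr

  ftest <- function(ss, df) {
    if (!haveErr) return(c(NA_real_, NA_real_))
    f <- (ss / df) / errorMs
    c(f, stats::pf(f, df, errorDf, lower.tail = FALSE))
  }
  fG <- ftest(ssG, G - 1L); fE <- ftest(ssE, E - 1L)
  fGE <- ftest(ssGE, (G - 1L) * (E - 1L))

  out <- rbind(
    anova_row("genotypes", G - 1L, ssG, fG[1L], fG[2L], 100 * ssG / total),
    anova_row("environments", E - 1L, ssE, fE[1L], fE[2L], 100 * ssE / total),
    anova_row("GxE", (G - 1L) * (E - 1L), ssGE, fGE[1L], fGE[2L],
              100 * ssGE / total)
  )
  at <- fit@axisTable
  for (n in seq_len(nAxesShown)) {
    fp <- ftest(at$ss[n], at$df[n])
    out <- rbind(out, anova_row(paste0("IPCA ", n), at$df[n], at$ss[n],
                                fp[1L], fp[2L],
                                if (ssGE > 0) 100 * at$ss[n] / ssGE else NA_real_))
  }
  if (nAxesShown < nrow(at)) {
    rest <- seq(nAxesShown + 1L, nrow(at))
    ssRes <- sum(at$ss[rest])
    dfRes <- (G - 1L) * (E - 1L) - sum(at$df[seq_len(nAxesShown)])
    fp <- ftest(ssRes, dfRes)
    out <- rbind(out, anova_row("GxE residual", dfRes, ssRes, fp[1L], fp[2L],
                                if (ssGE > 0) 100 * ssRes / ssGE else NA_real_))
  }
  if (haveErr) {
    out <- rbind(out, anova_row("error", errorDf, ssErr,
                                explainedPct = 100 * ssErr / total))
  }
  out
}
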