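#' @include AllClasses.R
NULL

anova_row <- function(stratum, df, ss, f = NA_real_, p = NA_real_,
                      explainedPct = NA_real_) {
  data.frame(
    stratum = stratum,
    df = as.integer(df),
    ss = ss,
    ms = ifelse(df > 0, ss / df, NA_real_),
    f = f,
    p = p,
    explainedPct = explainedPct,
    stringsAsFactors = FALSE
  )
}

#' Stratified ANOVA of a balanced RCBD multi-environment trial
#'
#' Partitions the total (plot-basis) sum of squares of a complete, balanced
#' randomized-complete-block multi-environment trial into environments,
#' blocks within environments, genotypes, genotype-by-environment
#' interaction and pooled error. Blocks are nested in environments (one
#' RCBD per location); there is no genotype-by-block stratum. Genotype,
#' environment and interaction F statistics are tested against the pooled
#' error mean square; explained % is each stratum's share of the total SS.
#'
#' @param data A complete, balanced [TrialData-class] with at least two
#'   replicates (otherwise no error stratum exists).
#' @return data.frame with columns `stratum`, `df`, `ss`, `ms`, `f`, `p`,
#'   `explainedPct`. Strata: `environments`, `blocks(environments)`,
#'   `genotypes`, `GxE`, `error`, `total`.
#' @seealso [partitionMeans()] for the cell-mean-only partition.
#' @export
partitionRcbd <- function(data) {
  stopifnot(methods::is(data, "TrialData"))
  means <- cellMeans(data) # also validates completeness/balance
  r <- replicateCount(means)
  if (r < 2L) {
    stop("single-replicate trial has no error stratum; ",
         "use partitionMeans() on cellMeans(data) instead", call. = FALSE)
  }
  rec <- data@records
  G <- length(data@genotypes)
  E <- length(data@environments)
  # every genotype must sit once in every block of its environment, or the
  # block stratum is not estimable by plain mean contrasts
  for (e in data@environments) {
    sub <- rec[rec$environment == e, ]
    if (any(table(sub$genotype, sub$block) != 1L)) {
      stop("environment ", e, " is not a complete block design: every ",
           "genotype must appear exactly once per block", call. = FALSE)
    }
  }
  y <- rec$yield
  grand <- mean(y)

  envMean <- tapply(y, factor(rec$environment, data@environments), mean)
  genMean <- tapply(y, factor(rec$genotype, data@genotypes), mean)
  blockMean <- tapply(y, list(factor(rec$environment, data@environments),
                              rec$block), mean)

  ssTotal <- sum((y - grand)^2)
  ssE <- G * r * sum((envMean - grand)^2)
  ssG <- E * r * sum((genMean - grand)^2)
  cellDev <- sweep(sweep(yieldMatrix(means), 1L, genMean), 2L, envMean) + grand
  ssGE <- r * sum(cellDev^2)
  ssB <- G * sum(sweep(blockMean, 1L, envMean)^2, na.rm = TRUE)
  ssErr <- ssTotal - ssE - ssG - ssGE - ssB

  dfE <- E - 1L
  dfB <- E * (r - 1L)
  dfG <- G - 1L
  dfGE <- (G - 1L) * (E - 1L)
  dfErr <- E * (r - 1L) * (G - 1L)
  msErr <- ssErr / dfErr

  ftest <- function(ss, df) {
    f <- (ss / df) / msErr
    c(f = f, p = stats::pf(f, df, dfErr, lower.tail = FALSE))
  }
  fE <- ftest(ssE, dfE); fG <- ftest(ssG, dfG); fGE <- ftest(ssGE, dfGE)
  pct <- function(ss) 100 * ss / ssTotal

  rbind(
    anova_row("environments", dfE, ssE, fE["f"], fE["p"], pct(ssE)),
    anova_row("blocks(environments)", dfB, ssB, explainedPct = pct(ssB)),
    anova_row("genotypes", dfG, ssG, fG["f"], fG["p"], pct(ssG)),
    anova_row("GxE", dfGE, ssGE, fGE["f"], fGE["p"], pct(ssGE)),
    anova_row("error", dfErr, ssErr, explainedPct = pct(ssErr)),
    anova_row("total", dfE + dfB + dfG + dfGE + dfErr, ssTotal,
              explainedPct = 100)
  )
}

#' Main-effect and interaction ANOVA from cell means alone
#'
#' Recovers the genotype, environment and interaction strata from a
#' genotype-by-environment mean table, on the plot basis (mean-basis sums
#' of squares times the replicate count r). Blocks and pooled error cannot
#' be recovered from means; when an externally known error mean square and
#' its degrees of freedom are supplied, F statistics against that error are
#' emitted and the error stratum is appended, so published F tests can be
#' reproduced from a published mean table.
#'
#' @param means A [CellMeans-class] object.
#' @param errorMs,errorDf Optional pooled error mean square (plot basis)
#'   and its degrees of freedom.
#' @return data.frame as in [partitionRcbd()], with strata `environments`,
#'   `genotypes`, `GxE` and, if error information is given, `error`.
#'   `explainedPct` is each stratum's share of the summed SS of the listed
#'   strata (published tables may use a total that additionally includes an
#'   unprinted block stratum).
#' @export
partitionMeans <- function(means, errorMs = NULL, errorDf = NULL) {
  stopifnot(methods::is(means, "CellMeans"))
  if (!is.null(errorMs) && errorMs < 0) stop("errorMs must be nonnegative")
  if (xor(is.null(errorMs), is.null(errorDf))) {
    stop("supply errorMs and errorDf together")
  }
  Y <- yieldMatrix(means)
  r <- replicateCount(means)
  G <- nrow(Y); E <- ncol(Y)
  grand <- mean(Y)
  gMean <- rowMeans(Y); eMean <- colMeans(Y)
  ssG <- r * E * sum((gMean - grand)^2)
  ssE <- r * G * sum((eMean - grand)^2)
  centered <- sweep(sweep(Y, 1L, gMean), 2L, eMean) + grand
  ssGE <- r * sum(centered^2)
  dfG <- G - 1L; dfE <- E - 1L; dfGE <- (G - 1L) * (E - 1L)

  haveErr <- !is.null(errorMs)
  ftest <- function(ss, df) {
    if (!haveErr || errorMs == 0) return(c(f = NA_real_, p = NA_real_))
    f <- (ss / df) / errorMs
    c(f = f, p = stats::pf(f, df, errorDf, lower.tail = FALSE))
  }
  fE <- ftest(ssE, dfE); fG <- ftest(ssG, dfG); fGE <- ftest(ssGE, dfGE)

  ssErr <- if (haveErr) errorMs * errorDf else 0
  total <- ssG + ssE + ssGE + ssErr
  pct <- function(ss) 100 * ss / total

  out <- rbind(
    anova_row("environments", dfE, ssE, fE["f"], fE["p"], pct(ssE)),
    anova_row("genotypes", dfG, ssG, fG["f"], fG["p"], pct(ssG)),
    anova_row("GxE", dfGE, ssGE, fGE["f"], fGE["p"], pct(ssGE))
  )
  if (haveErr) {
    out <- rbind(out, anova_row("error", errorDf, ssErr,
                                explainedPct = pct(ssErr)))
  }
  out
}

#' Format an ANOVA table in the style of published trial reports
#'
#' Pretty text rendering with a significance star column (`***` marks
#' p < 0.001, mirroring the usual annotation of trial ANOVA tables).
#'
#' @param tab data.frame from [partitionRcbd()], [partitionMeans()] or
#'   [ammiAnovaTable()].
#' @return Character vector of formatted lines, invisibly printed with
#'   `cat()` when `print = TRUE`.
#' @param print Print the lines to the console?
#' @export
formatAnovaTable <- function(tab, print = TRUE) {
  stars <- ifelse(is.na(tab$p), "", ifelse(tab$p < 0.001, "***",
            ifelse(tab$p < 0.01, "**", ifelse(tab$p < 0.05, "*", ""))))
  lines <- sprintf("%-22s %5d %10.1f %8.2f %8s %3s %8s",
                   tab$stratum, tab$df, tab$ss,
                   ifelse(is.na(tab$ms), NA, tab$ms),
                   ifelse(is.na(tab$f), "", sprintf("%.2f", tab$f)), stars,
                   ifelse(is.na(tab$explainedPct), "",
                          sprintf("%.2f", tab$explainedPct)))
  header <- sprintf("%-22s %5s %10s %8s %8s %3s %8s",
                    "source", "d.f.", "SS", "MS", "F", "", "expl.%")
  lines <- c(header, lines)
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
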