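#' @include ammi.R
NULL

#' ASV from raw axis scores
#'
#' The bare stability formula: `sqrt((w * ipca1)^2 + ipca2^2)` with weight
#' `w` equal to the ratio of the first two interaction axis sums of squares
#' (plot or mean basis -- the replicate count cancels, so the ratio equals
#' `d1^2 / d2^2`). Scores are expected in the symmetric sqrt(d) scaling,
#' the scaling in which published score tables are consistent with their
#' companion ANOVA tables.
#'
#' @param ipca1,ipca2 Numeric vectors of first/second-axis genotype scores.
#' @param weight SS_IPCA1 / SS_IPCA2.
#' @return Numeric vector of ASV values.
#' @examples
#' asvFromScores(0.076, -0.089, weight = 172.8 / 151.7) # ~0.124
#' @export
asvFromScores <- function(ipca1, ipca2, weight) {
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight < 0) {
    stop("weight must be a single nonnegative number")
  }
  sqrt((weight * ipca1)^2 + ipca2^2)
}

#' @describeIn asv ASV for every genotype of a fit, with
#'   `weight = SS_IPCA1 / SS_IPCA2` taken from the fit itself.
#' @export
setMethod("asv", "AmmiFit", function(fit, ...) {
  if (nAxesAvailable(fit) < 2L) {
    stop("degenerate fit: fewer than two non-zero interaction axes, ",
         "the ASV weight SS_IPCA1/SS_IPCA2 is undefined", call. = FALSE)
  }
  d <- fit@singularValues
  w <- d[1L]^2 / d[2L]^2
  out <- asvFromScores(fit@genotypeScores[, 1L], fit@genotypeScores[, 2L], w)
  names(out) <- genotypeNames(fit)
  attr(out, "weight") <- w
  out
})

#' Competition (minimum) ranks
#'
#' Rank 1 is best; tied values share the smallest applicable rank (the
#' "1224" convention), so each rank equals one plus the count of strictly
#' better values. Yields are ranked descending (highest yield = 1), ASV
#' ascending (most stable = 1).
#'
#' @param values Numeric vector.
#' @param direction `"ascending"` (small is best) or `"descending"`.
#' @return Integer ranks.
#' @examples
#' rankValues(c(3, 1, 2), "descending") # 1 3 2
#' rankValues(c(5, 5, 4), "ascending")  # 2 2 1
#' @export
rankValues <- function(values, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  if (!length(values)) stop("values must be nonempty")
  x <- if (direction == "descending") -as.numeric(values) else as.numeric(values)
  as.integer(rank(x, ties.method = "min"))
}

#' Stability table: mean yield, ASV, ranks and the genotype selection index
#'
#' Builds the per-genotype selection summary: mean yield, first two axis
#' scores, ASV, the competition rank of yield (descending) and of ASV
#' (ascending), and their sum -- the genotype selection index (GSI). Low
#' GSI flags genotypes that are jointly high-yielding and stable.
#'
#' @param fit An [AmmiFit-class] with at least two non-degenerate axes.
#' @param sort Sort the table by GSI ascending (best first)? Default keeps
#'   input genotype order.
#' @return data.frame with columns `genotype`, `mean`, `ipca1`, `ipca2`,
#'   `asv`, `rankYield`, `rankAsv`, `gsi`; the ASV weight is attached as
#'   `attr(, "weight")`.
#' @examples
#' fit <- fitAmmi(smoliceMaize()$means)
#' head(stabilityTable(fit, sort = TRUE))
#' @export
stabilityTable <- function(fit, sort = FALSE) {
  stopifnot(methods::is(fit, "AmmiFit"))
  a <- asv(fit)
  meanYield <- fit@grandMean + fit@genotypeEffects
  rankYield <- rankValues(meanYield, "descending")
  rankAsv <- rankValues(as.numeric(a), "ascending")
  out <- data.frame(
    genotype = genotypeNames(fit),
    mean = as.numeric(meanYield),
    ipca1 = fit@genotypeScores[, 1L],
    ipca2 = fit@genotypeScores[, 2L],
    asv = as.numeric(a),
    rankYield = rankYield,
    rankAsv = rankAsv,
    gsi = rankYield + rankAsv,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  if (sort) out <- out[order(out$gsi, out$genotype), , drop = FALSE]
  attr(out, "weight") <- attr(a, "weight")
  out
}
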