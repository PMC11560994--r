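#' @include stability.R
NULL

quadrant_of <- function(x, y) {
  # a coordinate of exactly zero counts as positive (deterministic tie rule)
  ifelse(x >= 0 & y >= 0, "Q1",
    ifelse(x < 0 & y >= 0, "Q2",
      ifelse(x < 0 & y < 0, "Q3", "Q4")))
}

#' AMMI1 biplot coordinates (mean yield vs IPCA1)
#'
#' Genotype points at (mean yield, IPCA1 score) and environment points at
#' (environment mean yield, environment IPCA1 score), with the grand mean
#' as the vertical reference line. Points near the reference with small
#' |IPCA1| are high/low yielding and stable; large |IPCA1| signals strong
#' specific interaction.
#'
#' @param fit An [AmmiFit-class] with at least one axis.
#' @return data.frame (`label`, `role`, `x`, `y`) with attributes `kind =
#'   "AMMI1"` and `referenceX` (the grand mean).
#' @export
ammi1Coords <- function(fit) {
  stopifnot(methods::is(fit, "AmmiFit"))
  out <- data.frame(
    label = c(genotypeNames(fit), environmentNames(fit)),
    role = rep(c("genotype", "environment"),
               c(length(fit@genotypeEffects), length(fit@environmentEffects))),
    x = c(fit@grandMean + fit@genotypeEffects,
          fit@grandMean + fit@environmentEffects),
    y = c(fit@genotypeScores[, 1L], fit@environmentScores[, 1L]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "kind") <- "AMMI1"
  attr(out, "referenceX") <- fit@grandMean
  out
}

#' AMMI2 biplot coordinates (IPCA1 vs IPCA2)
#'
#' Genotypes and environments in one interaction-score frame, each point
#' labelled with the quadrant it falls in; the four quadrants group
#' genotypes (with the environments they lean towards) by the sign pattern
#' of their specific adaptation.
#'
#' @param fit An [AmmiFit-class] with at least two axes.
#' @return data.frame (`label`, `role`, `x`, `y`, `quadrant`) with
#'   attribute `kind = "AMMI2"`.
#' @export
ammi2Coords <- function(fit) {
  stopifnot(methods::is(fit, "AmmiFit"))
  if (ncol(fit@genotypeScores) < 2L) {
    stop("AMMI2 coordinates need at least two interaction axes", call. = FALSE)
  }
  out <- data.frame(
    label = c(genotypeNames(fit), environmentNames(fit)),
    role = rep(c("genotype", "environment"),
               c(nrow(fit@genotypeScores), nrow(fit@environmentScores))),
    x = c(fit@genotypeScores[, 1L], fit@environmentScores[, 1L]),
    y = c(fit@genotypeScores[, 2L], fit@environmentScores[, 2L]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$quadrant <- quadrant_of(out$x, out$y)
  attr(out, "kind") <- "AMMI2"
  out
}

#' AMMI-estimated cell values from a truncated fit
#'
#' Reconstructs the G x E table from the grand mean, the main effects and
#' the first `nAxes` multiplicative terms:
#' `mu + alpha_g + beta_e + sum_n gScore[g, n] * eScore[e, n]`. With all
#' axes the original cell means are recovered exactly; with zero axes the
#' fit is purely additive.
#'
#' @param fit An [AmmiFit-class] object.
#' @param nAxes Number of leading axes to include (default: the fit's
#'   retained count).
#' @return Numeric G x E matrix of estimated yields.
#' @export
fittedMatrix <- function(fit, nAxes = nAxesRetained(fit)) {
  stopifnot(methods::is(fit, "AmmiFit"))
  nAxes <- as.integer(nAxes)
  if (is.na(nAxes) || nAxes < 0L || nAxes > ncol(fit@genotypeScores)) {
    stop("nAxes must lie in 0..", ncol(fit@genotypeScores), call. = FALSE)
  }
  G <- length(fit@genotypeEffects); E <- length(fit@environmentEffects)
  add <- fit@grandMean + outer(fit@genotypeEffects, fit@environmentEffects, "+")
  inter <- if (nAxes > 0L) {
    fit@genotypeScores[, seq_len(nAxes), drop = FALSE] %*%
      t(fit@environmentScores[, seq_len(nAxes), drop = FALSE])
  } else {
    matrix(0, G, E)
  }
  add + inter
}

#' Best AMMI-predicted genotypes in each environment
#'
#' Ranks genotypes within each environment by their AMMI-estimated yield
#' (from [fittedMatrix()] with `nAxes` terms) and returns the top `topK`.
#' Because the estimate uses score *products*, the selections are invariant
#' to axis sign flips. Ties keep input genotype order.
#'
#' @param fit An [AmmiFit-class] object.
#' @param nAxes Interaction axes used for the estimate (default: retained).
#' @param topK How many genotypes to list per environment.
#' @return data.frame (`environment`, `rank`, `genotype`, `fitted`),
#'   environments in input order.
#' @export
perEnvironmentSelections <- function(fit, nAxes = nAxesRetained(fit), topK = 4L) {
  stopifnot(methods::is(fit, "AmmiFit"))
  topK <- as.integer(topK)
  if (topK < 1L || topK > length(fit@genotypeEffects)) {
    stop("topK must lie in 1..G", call. = FALSE)
  }
  est <- fittedMatrix(fit, nAxes)
  envs <- environmentNames(fit)
  gens <- genotypeNames(fit)
  rows <- lapply(seq_along(envs), function(e) {
    ord <- order(-est[, e])[seq_len(topK)]
    data.frame(environment = envs[e], rank = seq_len(topK),
               genotype = gens[ord], fitted = est[ord, e],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Draw the AMMI1 biplot
#'
#' Base-graphics rendering of [ammi1Coords()]: genotypes as points,
#' environments as labelled triangles, dashed grand-mean vertical and zero
#' horizontal reference lines.
#'
#' @param fit An [AmmiFit-class] object.
#' @param labelGenotypes Label every genotype point? Off by default (69
#'   labels overplot badly).
#' @param ... Passed to [graphics::plot()].
#' @return The coordinate data.frame, invisibly.
#' @export
plotAmmi1 <- function(fit, labelGenotypes = FALSE, ...) {
  co <- ammi1Coords(fit)
  gg <- co[co$role == "genotype", ]
  ee <- co[co$role == "environment", ]
  graphics::plot(co$x, co$y, type = "n",
                 xlab = "mean yield (t/ha)", ylab = "IPCA1", ...)
  graphics::abline(v = attr(co, "referenceX"), lty = 2, col = "grey50")
  graphics::abline(h = 0, lty = 2, col = "grey50")
  graphics::points(gg$x, gg$y, pch = 1, col = "grey30")
  if (labelGenotypes) {
    graphics::text(gg$x, gg$y, gg$label, cex = 0.5, pos = 3)
  }
  graphics::points(ee$x, ee$y, pch = 17, col = "red3")
  graphics::text(ee$x, ee$y, ee$label, col = "red3", pos = 3, cex = 0.8)
  invisible(co)
}

#' Draw the AMMI2 biplot
#'
#' Base-graphics rendering of [ammi2Coords()]: genotypes as points,
#' environments as vectors from the origin.
#'
#' @inheritParams plotAmmi1
#' @return The coordinate data.frame, invisibly.
#' @export
plotAmmi2 <- function(fit, labelGenotypes = FALSE, ...) {
  co <- ammi2Coords(fit)
  gg <- co[co$role == "genotype", ]
  ee <- co[co$role == "environment", ]
  lim <- range(c(co$x, co$y, 0))
  graphics::plot(co$x, co$y, type = "n", xlim = lim, ylim = lim,
                 xlab = "IPCA1", ylab = "IPCA2", asp = 1, ...)
  graphics::abline(h = 0, v = 0, lty = 2, col = "grey50")
  graphics::points(gg$x, gg$y, pch = 1, col = "grey30")
  if (labelGenotypes) {
    graphics::text(gg$x, gg$y, gg$label, cex = 0.5, pos = 3)
  }
  graphics::arrows(0, 0, ee$x, ee$y, length = 0.08, col = "red3")
  graphics::text(ee$x, ee$y, ee$label, col = "red3", pos = 3, cex = 0.8)
  invisible(co)
}
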