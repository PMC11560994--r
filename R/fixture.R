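#' @include trial-io.R
NULL

#' Packaged maize multi-environment yield reference dataset
#'
#' A published reference dataset: mean grain yields (t/ha) of 69 maize
#' hybrids bred at Smolice (66 experimental flint/dent hybrids plus the
#' check cultivars NK Ravello, Ricardinio and ES Gallery) evaluated in 2017
#' in a randomized complete block design with three replicates at five
#' Polish locations -- Kobierzyce, Mikulice, Placzkowo (Płaczkowo),
#' Radzikow (Radzików) and Smolice. Alongside the 69 x 5 cell-mean matrix,
#' the published per-genotype interaction scores (IPCA1/IPCA2), AMMI
#' stability values (ASV), genotype selection indices (GSI) and
#' per-environment means and scores are included for regression testing.
#'
#' Values are stored exactly as printed (yields to 2 d.p., scores to
#' 3 d.p.); tolerances in any reproduction should allow for that rounding.
#' The reference GSI column is reproduced verbatim; note that it is not
#' arithmetically consistent with the reference ASV column for every
#' genotype (recomputing ranks from the printed ASV changes a few entries),
#' see the methods vignette.
#'
#' @return A list with elements
#'   \describe{
#'     \item{means}{[CellMeans-class], 69 x 5, `replicateCount = 3`.}
#'     \item{genotypeScores}{data.frame: genotype, code, mean, ipca1,
#'       ipca2, asv, gsi (as published).}
#'     \item{environmentScores}{data.frame: environment, mean, ipca1,
#'       ipca2 (as published).}
#'   }
#' @examples
#' ref <- smoliceMaize()
#' ref$means
#' yieldMatrix(ref$means)["SMH_1706", ]
#' @export
smoliceMaize <- function() {
  dir <- system.file("extdata", package = "metammi", mustWork = TRUE)
  wide <- utils::read.csv(file.path(dir, "smolice2017_yield_means.csv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(wide[, -(1:2)])
  rownames(m) <- wide$genotype
  means <- CellMeans(m, replicateCount = 3L)
  gs <- utils::read.csv(file.path(dir, "smolice2017_genotype_scores.csv"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  es <- utils::read.csv(file.path(dir, "smolice2017_environment_scores.csv"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  list(means = means, genotypeScores = gs, environmentScores = es)
}
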