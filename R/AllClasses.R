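#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# TrialData
# ---------------------------------------------------------------------------

#' Replicate-level records of an RCBD multi-environment trial
#'
#' Holds one row per plot: genotype, environment, block (nested within
#' environment) and yield in t/ha. Genotype and environment orderings are
#' explicit and preserved everywhere downstream -- no alphabetical
#' re-sorting. A trial need not be complete to be represented, but
#' [cellMeans()] and [partitionRcbd()] require completeness and balance.
#'
#' @slot records data.frame with columns `genotype`, `environment`,
#'   `block` (character) and `yield` (numeric, strictly positive t/ha).
#' @slot genotypes Ordered character vector of genotype ids.
#' @slot environments Ordered character vector of environment ids.
#'
#' @section Validity:
#' All yields must be positive and finite; no
#' (genotype, environment, block) triple may appear twice; the ordering
#' vectors must contain exactly the ids present in the records.
#'
#' @seealso [TrialData()], [readTrialLong()], [cellMeans()]
#' @export
setClass("TrialData",
  representation(
    records = "data.frame",
    genotypes = "character",
    environments = "character"
  )
)

setValidity("TrialData", function(object) {
  rec <- object@records
  req <- c("genotype", "environment", "block", "yield")
  if (!all(req %in% names(rec))) {
    return(paste0("records must have columns ", paste(req, collapse = ", ")))
  }
  if (!is.numeric(rec$yield)) {
    return("yield must be numeric")
  }
  if (any(!is.finite(rec$yield)) || any(rec$yield <= 0)) {
    return("all yields must be finite and > 0 (t/ha)")
  }
  key <- paste(rec$genotype, rec$environment, rec$block, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    return(paste0("duplicate (genotype, environment, block) record: ",
                  gsub("\r", " / ", dup, fixed = TRUE)))
  }
  if (!setequal(object@genotypes, unique(rec$genotype)) ||
      anyDuplicated(object@genotypes)) {
    return("genotype ordering must list each genotype in the records exactly once")
  }
  if (!setequal(object@environments, unique(rec$environment)) ||
      anyDuplicated(object@environments)) {
    return("environment ordering must list each environment in the records exactly once")
  }
  TRUE
})

#' Construct a TrialData object
#'
#' @param records data.frame with columns `genotype`, `environment`,
#'   `block`, `yield`.
#' @param genotypes,environments Optional explicit orderings; default is
#'   first-appearance order in `records`.
#' @return A [TrialData-class] object.
#' @examples
#' rec <- data.frame(
#'   genotype = "g1", environment = "e1", block = c("b1", "b2", "b3"),
#'   yield = c(1, 2, 3)
#' )
#' TrialData(rec)
#' @export
TrialData <- function(records, genotypes = NULL, environments = NULL) {
  records <- as.data.frame(records)
  for (col in c("genotype", "environment", "block")) {
    if (col %in% names(records)) records[[col]] <- as.character(records[[col]])
  }
  if (is.null(genotypes)) genotypes <- unique(records$genotype)
  if (is.null(environments)) environments <- unique(records$environment)
  methods::new("TrialData",
    records = records,
    genotypes = as.character(genotypes),
    environments = as.character(environments)
  )
}

#' @rdname metammi-generics
#' @export
setMethod("genotypeNames", "TrialData", function(x) x@genotypes)

#' @rdname metammi-generics
#' @export
setMethod("environmentNames", "TrialData", function(x) x@environments)

#' @rdname metammi-generics
#' @export
setMethod("trialRecords", "TrialData", function(x) x@records)

setMethod("show", "TrialData", function(object) {
  cat("TrialData:", nrow(object@records), "plot records |",
      length(object@genotypes), "genotypes x",
      length(object@environments), "environments\n")
  cat("  yield (t/ha): ",
      sprintf("%.2f - %.2f", min(object@records$yield),
              max(object@records$yield)), "\n", sep = "")
})

# ---------------------------------------------------------------------------
# CellMeans
# ---------------------------------------------------------------------------

#' Genotype-by-environment cell-mean matrix
#'
#' A complete matrix of mean yields (t/ha), genotypes in rows and
#' environments in columns, plus the common replicate count `r` behind each
#' cell. `r` converts mean-basis sums of squares to the plot basis
#' (multiplication by `r`) in [partitionMeans()] and [fitAmmi()].
#'
#' @slot yield Numeric G x E matrix with complete dimnames and no missing
#'   cells.
#' @slot replicateCount Positive integer, replicates per cell.
#' @seealso [CellMeans()], [cellMeans()], [fitAmmi()]
#' @export
setClass("CellMeans",
  representation(
    yield = "matrix",
    replicateCount = "integer"
  )
)

setValidity("CellMeans", function(object) {
  y <- object@yield
  if (!is.numeric(y)) return("yield must be a numeric matrix")
  if (any(!is.finite(y))) return("cell-mean matrix must be complete (no missing cells)")
  if (is.null(rownames(y)) || is.null(colnames(y))) {
    return("yield matrix must carry genotype row names and environment column names")
  }
  if (anyDuplicated(rownames(y)) || anyDuplicated(colnames(y))) {
    return("genotype and environment names must be unique")
  }
  if (length(object@replicateCount) != 1L || is.na(object@replicateCount) ||
      object@replicateCount < 1L) {
    return("replicateCount must be a single positive integer")
  }
  TRUE
})

#' Construct a CellMeans object
#'
#' @param yield Numeric matrix of mean yields, genotypes in rows (named),
#'   environments in columns (named).
#' @param replicateCount Number of replicates behind each cell mean.
#' @return A [CellMeans-class] object.
#' @examples
#' m <- matrix(c(5, 6, 7, 6, 7, 8), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("e1", "e2")))
#' CellMeans(m, replicateCount = 3)
#' @export
CellMeans <- function(yield, replicateCount = 1L) {
  methods::new("CellMeans",
    yield = as.matrix(yield),
    replicateCount = as.integer(replicateCount)
  )
}

#' @rdname metammi-generics
#' @export
setMethod("yieldMatrix", "CellMeans", function(x) x@yield)

#' @rdname metammi-generics
#' @export
setMethod("replicateCount", "CellMeans", function(x) x@replicateCount)

#' @rdname metammi-generics
#' @export
setMethod("genotypeNames", "CellMeans", function(x) rownames(x@yield))

#' @rdname metammi-generics
#' @export
setMethod("environmentNames", "CellMeans", function(x) colnames(x@yield))

setMethod("show", "CellMeans", function(object) {
  cat("CellMeans:", nrow(object@yield), "genotypes x",
      ncol(object@yield), "environments | r =", object@replicateCount, "\n")
  cat("  grand mean ", sprintf("%.2f", mean(object@yield)), " t/ha, cells ",
      sprintf("%.2f - %.2f", min(object@yield), max(object@yield)), "\n",
      sep = "")
})

# ---------------------------------------------------------------------------
# AmmiFit
# ---------------------------------------------------------------------------

#' Fitted AMMI decomposition of a cell-mean matrix
#'
#' The additive part (grand mean, genotype and environment deviations) plus
#' the singular value decomposition of the double-centered interaction
#' matrix. Scores are scaled symmetrically: each side carries the square
#' root of the singular value, so the outer product of a genotype and an
#' environment score column reconstructs that axis's interaction term
#' directly, and the sum of squared scores on either side of axis n equals
#' the singular value d_n.
#'
#' @slot grandMean Grand mean yield (t/ha).
#' @slot genotypeEffects,environmentEffects Centered main-effect deviations.
#' @slot singularValues Mean-basis singular values d_n, descending, one per
#'   available axis (min(G-1, E-1)).
#' @slot genotypeScores,environmentScores Score matrices (rows = ids,
#'   columns = axes), sqrt(d)-scaled, oriented per `orientation`.
#' @slot residual G x E interaction left out of the retained axes.
#' @slot replicateCount Replicates behind each cell mean.
#' @slot nRetained Number of axes retained for the residual/fitted split.
#' @slot axisTable Per-axis data.frame: singular value, plot-basis SS,
#'   Gollob d.f., MS, F, p, explained % of the interaction SS.
#' @slot orientation Sign-orientation rule applied ("env-max" or "none").
#' @seealso [fitAmmi()], [asv()], [fittedMatrix()], [ammi2Coords()]
#' @export
setClass("AmmiFit",
  representation(
    grandMean = "numeric",
    genotypeEffects = "numeric",
    environmentEffects = "numeric",
    singularValues = "numeric",
    genotypeScores = "matrix",
    environmentScores = "matrix",
    residual = "matrix",
    replicateCount = "integer",
    nRetained = "integer",
    axisTable = "data.frame",
    orientation = "character"
  )
)

setValidity("AmmiFit", function(object) {
  G <- length(object@genotypeEffects)
  E <- length(object@environmentEffects)
  N <- length(object@singularValues)
  if (abs(sum(object@genotypeEffects)) > 1e-8 * max(1, abs(object@grandMean))) {
    return("genotype deviations must sum to zero")
  }
  if (abs(sum(object@environmentEffects)) > 1e-8 * max(1, abs(object@grandMean))) {
    return("environment deviations must sum to zero")
  }
  if (N != min(G - 1L, E - 1L)) {
    return("one singular value per available axis (min(G-1, E-1)) expected")
  }
  if (is.unsorted(rev(object@singularValues), strictly = FALSE) ||
      any(object@singularValues < -1e-12)) {
    return("singular values must be nonnegative and descending")
  }
  if (!identical(dim(object@genotypeScores), c(G, N)) ||
      !identical(dim(object@environmentScores), c(E, N))) {
    return("score matrices must be G x N and E x N")
  }
  if (object@nRetained < 0L || object@nRetained > N) {
    return("nRetained out of range")
  }
  TRUE
})

#' @rdname metammi-generics
#' @export
setMethod("grandMean", "AmmiFit", function(x) x@grandMean)

#' @rdname metammi-generics
#' @export
setMethod("genotypeEffects", "AmmiFit", function(x) x@genotypeEffects)

#' @rdname metammi-generics
#' @export
setMethod("environmentEffects", "AmmiFit", function(x) x@environmentEffects)

#' @rdname metammi-generics
#' @export
setMethod("genotypeScores", "AmmiFit", function(x) x@genotypeScores)

#' @rdname metammi-generics
#' @export
setMethod("environmentScores", "AmmiFit", function(x) x@environmentScores)

#' @rdname metammi-generics
#' @export
setMethod("interactionResidual", "AmmiFit", function(x) x@residual)

#' @rdname metammi-generics
#' @export
setMethod("axisSummary", "AmmiFit", function(x) x@axisTable)

#' @rdname metammi-generics
#' @export
setMethod("replicateCount", "AmmiFit", function(x) x@replicateCount)

#' @rdname metammi-generics
#' @export
setMethod("genotypeNames", "AmmiFit", function(x) names(x@genotypeEffects))

#' @rdname metammi-generics
#' @export
setMethod("environmentNames", "AmmiFit", function(x) names(x@environmentEffects))

#' @rdname metammi-generics
#' @export
setMethod("nAxesAvailable", "AmmiFit", function(x) {
  n_usable_axes(x@singularValues, x@grandMean)
})

#' @rdname metammi-generics
#' @export
setMethod("nAxesRetained", "AmmiFit", function(x) x@nRetained)

setMethod("show", "AmmiFit", function(object) {
  G <- length(object@genotypeEffects)
  E <- length(object@environmentEffects)
  cat("AmmiFit:", G, "genotypes x", E, "environments, r =",
      object@replicateCount, "\n")
  cat("  grand mean", sprintf("%.3f", object@grandMean), "t/ha;",
      nAxesAvailable(object), "usable axes,", object@nRetained, "retained\n")
  expl <- object@axisTable$explainedPct
  if (length(expl) && all(is.finite(expl))) {
    cat("  interaction explained %:",
        paste(sprintf("%.2f", expl[seq_len(min(3L, length(expl)))]),
              collapse = " / "), "...\n")
  }
})

# ---------------------------------------------------------------------------
# SyntheticTruth
# ---------------------------------------------------------------------------

#' Ground truth behind a synthetic multi-environment trial
#'
#' The generative parameters used by [generateMet()]: additive effects, the
#' planted low-rank interaction (singular values and orthonormal zero-sum
#' axes), and the noise standard deviations. Kept so that recovery studies
#' can compare fitted quantities to what was planted.
#'
#' @slot mu Grand mean.
#' @slot alpha,beta Centered genotype/environment main effects.
#' @slot singularValues Planted interaction singular values (possibly empty).
#' @slot genotypeAxes,environmentAxes Orthonormal zero-sum axis matrices
#'   (G x K and E x K).
#' @slot blockSd,errorSd Block-effect and plot-error standard deviations.
#' @slot seed Integer seed that generated the trial.
#' @export
setClass("SyntheticTruth",
  representation(
    mu = "numeric",
    alpha = "numeric",
    beta = "numeric",
    singularValues = "numeric",
    genotypeAxes = "matrix",
    environmentAxes = "matrix",
    blockSd = "numeric",
    errorSd = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticTruth", function(object) {
  tol <- 1e-8
  if (abs(sum(object@alpha)) > tol) return("alpha must sum to zero")
  if (abs(sum(object@beta)) > tol) return("beta must sum to zero")
  K <- length(object@singularValues)
  for (nm in c("genotypeAxes", "environmentAxes")) {
    A <- methods::slot(object, nm)
    if (ncol(A) != K) return(paste(nm, "must have one column per singular value"))
    if (K > 0L) {
      if (max(abs(crossprod(A) - diag(K))) > 1e-6) {
        return(paste(nm, "columns must be orthonormal"))
      }
      if (max(abs(colSums(A))) > 1e-6) {
        return(paste(nm, "columns must each sum to zero"))
      }
    }
  }
  if (object@blockSd < 0 || object@errorSd < 0) {
    return("standard deviations must be nonnegative")
  }
  TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth: mu =", sprintf("%.3f", object@mu), "| rank",
      length(object@singularValues), "interaction, d = (",
      paste(sprintf("%.3g", object@singularValues), collapse = ", "),
      ") | blockSd", object@blockSd, "errorSd", object@errorSd,
      "| seed", object@seed, "\n")
})
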