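#' @include AllGenerics.R
NULL

#' Generics for trial containers and AMMI fits
#'
#' Accessor generics shared by [TrialData-class], [CellMeans-class] and
#' [AmmiFit-class]. Accessors are the supported way to read the objects;
#' slots are internal.
#'
#' @param x,object An object of one of the package's S4 classes.
#' @param ... Passed to methods.
#' @return See the individual methods.
#' @name metammi-generics
NULL

#' @rdname metammi-generics
#' @export
setGeneric("genotypeNames", function(x) standardGeneric("genotypeNames"))

#' @rdname metammi-generics
#' @export
setGeneric("environmentNames", function(x) standardGeneric("environmentNames"))

#' @rdname metammi-generics
#' @export
setGeneric("replicateCount", function(x) standardGeneric("replicateCount"))

#' @rdname metammi-generics
#' @export
setGeneric("yieldMatrix", function(x) standardGeneric("yieldMatrix"))

#' @rdname metammi-generics
#' @export
setGeneric("trialRecords", function(x) standardGeneric("trialRecords"))

#' Compute genotype-by-environment cell means
#'
#' Averages replicate-level yields into a complete genotype-by-environment
#' mean matrix, the unit of AMMI fitting. The trial must be complete (every
#' genotype-environment pair observed) and balanced (a common replicate
#' count), because downstream plot-basis sums of squares multiply mean-basis
#' quantities by the common replicate count.
#'
#' @param x A [TrialData-class] object.
#' @return A [CellMeans-class] object with `replicateCount` set to the
#'   common number of replicates.
#' @examples
#' trial <- generateMet(G = 4, E = 3, r = 2, seed = 1)$trial
#' cellMeans(trial)
#' @export
setGeneric("cellMeans", function(x) standardGeneric("cellMeans"))

#' @rdname metammi-generics
#' @export
setGeneric("grandMean", function(x) standardGeneric("grandMean"))

#' @rdname metammi-generics
#' @export
setGeneric("genotypeEffects", function(x) standardGeneric("genotypeEffects"))

#' @rdname metammi-generics
#' @export
setGeneric("environmentEffects", function(x) standardGeneric("environmentEffects"))

#' @rdname metammi-generics
#' @export
setGeneric("genotypeScores", function(x) standardGeneric("genotypeScores"))

#' @rdname metammi-generics
#' @export
setGeneric("environmentScores", function(x) standardGeneric("environmentScores"))

#' @rdname metammi-generics
#' @export
setGeneric("interactionResidual", function(x) standardGeneric("interactionResidual"))

#' @rdname metammi-generics
#' @export
setGeneric("axisSummary", function(x) standardGeneric("axisSummary"))

#' @rdname metammi-generics
#' @export
setGeneric("nAxesAvailable", function(x) standardGeneric("nAxesAvailable"))

#' @rdname metammi-generics
#' @export
setGeneric("nAxesRetained", function(x) standardGeneric("nAxesRetained"))

#' AMMI stability value
#'
#' Computes the per-genotype AMMI stability value (ASV) from the first two
#' interaction axes of a fit: the Euclidean distance from the biplot origin
#' with the first-axis score weighted by the ratio of the two axis sums of
#' squares. Lower ASV means more stable across environments.
#'
#' @param fit An [AmmiFit-class] with at least two non-degenerate axes.
#' @param ... Unused.
#' @return Named numeric vector of ASV values (one per genotype), with the
#'   weight used stored in `attr(, "weight")`.
#' @seealso [asvFromScores()] for the bare formula, [stabilityTable()] for
#'   ranks and the genotype selection index.
#' @export
setGeneric("asv", function(fit, ...) standardGeneric("asv"))
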