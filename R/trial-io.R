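#' @include AllClasses.R
NULL

#' Read a long-format replicate-level trial CSV
#'
#' Expects one row per plot with genotype, environment, block and yield
#' columns. Column names are remappable through `columnMap`, so files using
#' e.g. `gen`/`loc`/`rep`/`grain_yield` headers read without editing.
#' Genotype and environment orderings follow first appearance in the file.
#'
#' @param path CSV file with a header row.
#' @param columnMap Named character vector mapping the canonical names
#'   `genotype`, `environment`, `block`, `yield` to the file's column names.
#' @return A [TrialData-class] object.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(genotype = "g1", environment = "e1",
#'                      block = c("b1", "b2", "b3"), yield = c(1, 2, 3)),
#'           f, row.names = FALSE)
#' readTrialLong(f)
#' @export
readTrialLong <- function(path,
                          columnMap = c(genotype = "genotype",
                                        environment = "environment",
                                        block = "block",
                                        yield = "yield")) {
  defaults <- c(genotype = "genotype", environment = "environment",
                block = "block", yield = "yield")
  columnMap <- c(columnMap, defaults[setdiff(names(defaults), names(columnMap))])
  if (!file.exists(path)) stop("trial CSV not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- columnMap[!(columnMap %in% names(raw))]
  if (length(missing)) {
    stop("column '", missing[[1L]], "' (for ", names(missing)[1L],
         ") not found in ", path, call. = FALSE)
  }
  yield_chr <- raw[[columnMap[["yield"]]]]
  yield <- suppressWarnings(as.numeric(yield_chr))
  if (anyNA(yield)) {
    bad <- which(is.na(yield))[1L]
    stop("non-numeric yield '", yield_chr[bad], "' at data row ", bad,
         " of ", path, call. = FALSE)
  }
  rec <- data.frame(
    genotype = raw[[columnMap[["genotype"]]]],
    environment = raw[[columnMap[["environment"]]]],
    block = raw[[columnMap[["block"]]]],
    yield = yield,
    stringsAsFactors = FALSE
  )
  TrialData(rec)
}

#' Write a TrialData object as a long-format CSV
#'
#' Inverse of [readTrialLong()]: writing and re-reading reproduces the
#' object, including genotype/environment order.
#'
#' @param x A [TrialData-class] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrialLong <- function(x, path) {
  stopifnot(methods::is(x, "TrialData"))
  rec <- x@records
  # order rows so genotype/environment first-appearance order round-trips
  rec <- rec[order(match(rec$environment, x@environments),
                   match(rec$genotype, x@genotypes),
                   rec$block), , drop = FALSE]
  rec <- rec[order(match(rec$genotype, x@genotypes)), , drop = FALSE]
  utils::write.csv(rec, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @describeIn cellMeans Average a complete, balanced trial into cell means.
#' @export
setMethod("cellMeans", "TrialData", function(x) {
  rec <- x@records
  gi <- factor(rec$genotype, levels = x@genotypes)
  ei <- factor(rec$environment, levels = x@environments)
  counts <- table(gi, ei)
  if (any(counts == 0L)) {
    miss <- which(counts == 0L, arr.ind = TRUE)
    pairs <- apply(miss, 1L, function(ix) {
      paste0(x@genotypes[ix[1L]], " x ", x@environments[ix[2L]])
    })
    stop("trial is incomplete; missing genotype x environment cells: ",
         paste(utils::head(pairs, 10L), collapse = ", "),
         if (length(pairs) > 10L) " ..." else "", call. = FALSE)
  }
  r <- unique(as.vector(counts))
  if (length(r) != 1L) {
    stop("unbalanced replication: cells carry ", min(counts), " to ",
         max(counts), " replicates; a common replicate count is required",
         call. = FALSE)
  }
  sums <- tapply(rec$yield, list(gi, ei), sum)
  CellMeans(sums / r, replicateCount = r)
})

#' Read a wide genotype-by-environment cell-mean CSV
#'
#' First column is the genotype id; every remaining numeric column is an
#' environment. A trailing column named `mean` (any case) is ignored, so
#' published tables that append a row-mean column read directly.
#'
#' @param path CSV file path.
#' @param replicateCount Replicates behind each printed mean.
#' @param dropColumns Extra non-environment columns to ignore (e.g. a
#'   short-code column).
#' @return A [CellMeans-class] object.
#' @export
readCellMeans <- function(path, replicateCount = 1L, dropColumns = character()) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("wide cell-mean CSV needs a genotype column plus environments")
  ids <- as.character(raw[[1L]])
  body <- raw[-1L]
  keep <- !(tolower(names(body)) == "mean" | names(body) %in% dropColumns)
  body <- body[keep]
  m <- as.matrix(body)
  if (!is.numeric(m)) stop("environment columns must be numeric")
  rownames(m) <- ids
  CellMeans(m, replicateCount = replicateCount)
}

#' Write a CellMeans object as a wide CSV
#'
#' @param x A [CellMeans-class] object.
#' @param path Output CSV path.
#' @param addMean Append a row-mean column (as published tables often do)?
#' @return `path`, invisibly.
#' @export
writeCellMeans <- function(x, path, addMean = FALSE) {
  stopifnot(methods::is(x, "CellMeans"))
  out <- data.frame(genotype = rownames(x@yield), x@yield,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (addMean) out$mean <- rowMeans(x@yield)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Expand a cell-mean matrix into pseudo-replicated trial records
#'
#' Repeats every cell value `r` times with synthetic block labels. Useful
#' for pushing a published mean table through replicate-level code paths;
#' the pseudo-replicates carry no within-cell variation.
#'
#' @param x A [CellMeans-class] object.
#' @param r Number of pseudo-replicates (defaults to the stored count).
#' @return A [TrialData-class] object.
#' @export
pseudoReplicate <- function(x, r = replicateCount(x)) {
  stopifnot(methods::is(x, "CellMeans"), r >= 1L)
  G <- nrow(x@yield); E <- ncol(x@yield)
  rec <- data.frame(
    genotype = rep(rep(rownames(x@yield), times = E), times = r),
    environment = rep(rep(colnames(x@yield), each = G), times = r),
    block = rep(paste0("b", seq_len(r)), each = G * E),
    yield = rep(as.vector(x@yield), times = r),
    stringsAsFactors = FALSE
  )
  TrialData(rec, genotypes = rownames(x@yield),
            environments = colnames(x@yield))
}
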