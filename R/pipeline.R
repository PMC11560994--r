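#' @include synthetic.R
NULL

#' Run the full AMMI analysis pipeline
#'
#' Ties the stages together: read (or take) trial data, average to cell
#' means, partition the ANOVA, fit the AMMI decomposition, compute
#' stability (ASV/GSI), build biplot coordinates and per-environment
#' selections, and optionally write the whole bundle -- CSV tables, a plain
#' text report and a machine-readable JSON summary -- to a directory. The
#' pipeline is a pure function of its inputs and options: rerunning with
#' the same input yields byte-identical files.
#'
#' For replicate-level input the error mean square and degrees of freedom
#' come from the trial's own ANOVA; for cell-mean input they may be
#' supplied (`errorMs`, `errorDf`) to enable the F tests, as when
#' reproducing a published analysis from its printed mean table.
#'
#' When the interaction is degenerate (fewer than two non-zero axes) the
#' stability stage is skipped and flagged in the report rather than
#' failing the run.
#'
#' @param input One of: the string `"fixture"` (the packaged maize
#'   reference dataset), a path to a long-format CSV (see
#'   [readTrialLong()]), a [TrialData-class], or a [CellMeans-class].
#' @param outDir Optional output directory (created if missing).
#' @param nAxes Passed to [fitAmmi()].
#' @param errorMs,errorDf Pooled error MS/d.f. for cell-mean input.
#' @param alphaLevel Significance level for axis retention.
#' @param topK Genotypes listed per environment.
#' @param replicateCount Replicate count assumed for wide/fixture-free
#'   cell-mean input read from `input` when it is a CellMeans built with
#'   r = 1 but the caller knows better; usually leave `NULL`.
#' @param verbose Log each stage to the console?
#' @return Invisibly, a list of class `"ammiReport"`: `means`, `anova`
#'   (data.frame), `fit` ([AmmiFit-class]), `gollob`, `stability`
#'   (data.frame or `NULL` when degenerate), `ammi1`, `ammi2`,
#'   `selections`, `summary` (the JSON-able digest), `files` (paths
#'   written, if any).
#' @examples
#' rep <- runPipeline("fixture", errorMs = 432.9 / 680, errorDf = 680,
#'                    verbose = FALSE)
#' rep$summary$anova$ssGxE
#' @export
runPipeline <- function(input = "fixture", outDir = NULL, nAxes = "auto",
                        errorMs = NULL, errorDf = NULL, alphaLevel = 0.05,
                        topK = 4L, replicateCount = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message("[metammi] ", ...)

  # --- stage: input ---------------------------------------------------------
  anovaTab <- NULL
  if (methods::is(input, "CellMeans")) {
    say("input: CellMeans ", nrow(yieldMatrix(input)), " x ",
        ncol(yieldMatrix(input)))
    means <- input
  } else if (methods::is(input, "TrialData")) {
    say("input: TrialData with ", nrow(trialRecords(input)), " records")
    means <- cellMeans(input)
    anovaTab <- partitionRcbd(input)
  } else if (identical(input, "fixture")) {
    say("input: packaged maize reference dataset (69 x 5, r = 3)")
    means <- smoliceMaize()$means
  } else if (is.character(input) && length(input) == 1L) {
    say("input: reading long CSV ", input)
    trial <- tryCatch(readTrialLong(input), error = function(e) {
      stop("stage 'read' failed for ", input, ": ", conditionMessage(e),
           "\n  hint: expected a long CSV with genotype/environment/block/",
           "yield columns", call. = FALSE)
    })
    means <- cellMeans(trial)
    anovaTab <- partitionRcbd(trial)
  } else {
    stop("input must be 'fixture', a CSV path, a TrialData or a CellMeans")
  }
  if (!is.null(replicateCount)) {
    means <- CellMeans(yieldMatrix(means), replicateCount = replicateCount)
  }

  # --- stage: ANOVA ---------------------------------------------------------
  if (!is.null(anovaTab)) {
    err <- anovaTab[anovaTab$stratum == "error", ]
    if (is.null(errorMs)) {
      errorMs <- err$ms
      errorDf <- err$df
      say("error stratum from trial ANOVA: MS = ", signif(errorMs, 4L),
          ", df = ", errorDf)
    }
  } else {
    anovaTab <- partitionMeans(means, errorMs = errorMs, errorDf = errorDf)
    say("ANOVA from cell means (blocks/error not recoverable from means)")
  }

  # --- stage: AMMI fit ------------------------------------------------------
  fit <- fitAmmi(means, nAxes = nAxes, errorMs = errorMs, errorDf = errorDf,
                 alphaLevel = alphaLevel)
  say("AMMI fit: ", nAxesAvailable(fit), " usable axes, ",
      nAxesRetained(fit), " retained")
  gollob <- if (!is.null(errorMs) && errorMs > 0) {
    gollobTest(fit, errorMs, errorDf, alphaLevel)
  } else NULL

  # --- stage: stability -----------------------------------------------------
  degenerate <- nAxesAvailable(fit) < 2L
  stability <- NULL
  if (degenerate) {
    say("interaction is degenerate (fewer than two non-zero axes); ",
        "ASV/GSI skipped")
  } else {
    stability <- stabilityTable(fit)
  }

  # --- stage: biplots and selections ---------------------------------------
  a1 <- ammi1Coords(fit)
  a2 <- if (!degenerate) ammi2Coords(fit) else NULL
  selections <- perEnvironmentSelections(
    fit, nAxes = nAxesRetained(fit), topK = min(topK, length(genotypeNames(fit))))

  # --- stage: summary -------------------------------------------------------
  Y <- yieldMatrix(means)
  axisTab <- axisSummary(fit)
  summary <- list(
    data = list(
      nGenotypes = nrow(Y), nEnvironments = ncol(Y),
      replicateCount = replicateCount(means),
      grandMean = mean(Y), minCell = min(Y), maxCell = max(Y)
    ),
    anova = list(
      ssG = anovaTab$ss[anovaTab$stratum == "genotypes"],
      ssE = anovaTab$ss[anovaTab$stratum == "environments"],
      ssGxE = anovaTab$ss[anovaTab$stratum == "GxE"]
    ),
    axes = list(
      singularValues = axisTab$singularValue,
      ss = axisTab$ss,
      explainedPct = axisTab$explainedPct,
      retained = nAxesRetained(fit),
      degenerateInteraction = degenerate
    ),
    stability = if (!degenerate) {
      best <- stability[which.min(stability$gsi), ]
      list(asvWeight = attr(stability, "weight"),
           bestGsiGenotype = best$genotype, bestGsi = best$gsi)
    } else {
      list(skipped = "degenerate interaction: ASV weight undefined")
    },
    options = list(nAxes = as.character(nAxes), alphaLevel = alphaLevel,
                   topK = topK,
                   errorMs = if (is.null(errorMs)) NULL else errorMs,
                   errorDf = if (is.null(errorDf)) NULL else errorDf)
  )

  files <- character()
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(obj, name) {
      p <- file.path(outDir, name)
      utils::write.csv(obj, p, row.names = FALSE, quote = TRUE)
      p
    }
    files <- c(
      wr(anovaTab, "anova.csv"),
      wr(cbind(axis = axisTab$axis, axisTab[-1L]), "axes.csv"),
      wr(data.frame(genotype = genotypeNames(fit),
                    mean = grandMean(fit) + genotypeEffects(fit),
                    genotypeScores(fit), check.names = FALSE),
         "genotype_scores.csv"),
      wr(data.frame(environment = environmentNames(fit),
                    mean = grandMean(fit) + environmentEffects(fit),
                    environmentScores(fit), check.names = FALSE),
         "environment_scores.csv"),
      wr(a1, "ammi1_coords.csv"),
      wr(selections, "selections.csv")
    )
    if (!degenerate) {
      files <- c(files, wr(stability, "stability.csv"),
                 wr(a2, "ammi2_coords.csv"))
    }
    jsonPath <- file.path(outDir, "summary.json")
    jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    reportPath <- file.path(outDir, "report.txt")
    writeLines(render_report(anovaTab, fit, gollob, stability, selections,
                             degenerate), reportPath)
    files <- c(files, jsonPath, reportPath)
    say("wrote ", length(files), " files to ", outDir)
  }

  out <- list(means = means, anova = anovaTab, fit = fit, gollob = gollob,
              stability = stability, ammi1 = a1, ammi2 = a2,
              selections = selections, summary = summary, files = files)
  class(out) <- "ammiReport"
  invisible(out)
}

render_report <- function(anovaTab, fit, gollob, stability, selections,
                          degenerate) {
  lines <- c("AMMI multi-environment trial report", "",
             "== Analysis of variance ==")
  lines <- c(lines, formatAnovaTable(anovaTab, print = FALSE), "")
  lines <- c(lines, "== Interaction axes ==")
  at <- axisSummary(fit)
  lines <- c(lines, sprintf(
    "  axis %d: d = %.4f, plot SS = %.2f, df = %d, explained %s of GxE",
    at$axis, at$singularValue, at$ss, at$df,
    ifelse(is.finite(at$explainedPct),
           sprintf("%.2f%%", at$explainedPct), "-")))
  if (!is.null(gollob)) {
    lines <- c(lines, sprintf("  Gollob-recommended axes: %d",
                              gollob$recommendedN))
  }
  lines <- c(lines, "")
  if (degenerate) {
    lines <- c(lines,
      "== Stability ==",
      "  interaction degenerate (zero beyond axis 1): ASV/GSI skipped", "")
  } else {
    lines <- c(lines, "== Stability (best 5 by GSI) ==")
    top <- stability[order(stability$gsi, stability$genotype), ][1:5, ]
    lines <- c(lines, sprintf("  %-12s mean %6.2f  ASV %6.3f  GSI %4d",
                              top$genotype, top$mean, top$asv, top$gsi), "")
  }
  lines <- c(lines, "== Per-environment selections ==")
  for (e in unique(selections$environment)) {
    sub <- selections[selections$environment == e, ]
    lines <- c(lines, sprintf("  %-12s %s", e,
                              paste(sub$genotype, collapse = ", ")))
  }
  lines
}

#' @export
print.ammiReport <- function(x, ...) {
  cat("ammiReport\n")
  formatAnovaTable(x$anova)
  cat("\nretained axes:", nAxesRetained(x$fit), "of",
      nAxesAvailable(x$fit), "usable\n")
  if (!is.null(x$stability)) {
    best <- x$stability[which.min(x$stability$gsi), ]
    cat("best GSI:", best$genotype, "(mean", sprintf("%.2f", best$mean),
        "t/ha, ASV", sprintf("%.3f", best$asv), ", GSI", best$gsi, ")\n")
  } else {
    cat("stability skipped (degenerate interaction)\n")
  }
  invisible(x)
}
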