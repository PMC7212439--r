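#' @include scheme.R
NULL

#' Define an experiment grid
#'
#' The cross of matrix-combination scenarios (e.g. "Q_M" = prediction with
#' the QTL matrix, coancestry control with the marker matrix), trait
#' architectures (number of QTL), and coancestry penalty weights, with R
#' replicates per cell. Replicate seeds derive deterministically from the
#' master seed, so any cell or replicate can be reproduced standalone.
#'
#' @param scenarios character vector from
#'   `c("A_A","M_A","Q_A","A_M","M_M","Q_M")`.
#' @param architectures list/vector of `"all"` or QTL counts.
#' @param penalties numeric penalty weights (w >= 0).
#' @param replicates replicates per cell.
#' @param scale `"reduced"` or `"paper"`; selects the matching
#'   [GenomeSpec-class] and [schemeConfig()] presets.
#' @param masterSeed integer master seed.
#' @return an `ExperimentGrid` list (cells + presets).
#' @export
experimentGrid <- function(scenarios = c("Q_M", "M_M"),
                           architectures = "all",
                           penalties = 25,
                           replicates = 2L,
                           scale = c("reduced", "paper"),
                           masterSeed = 1L) {
  scale <- match.arg(scale)
  ok <- c("A_A", "M_A", "Q_A", "A_M", "M_M", "Q_M")
  stopifnot(all(scenarios %in% ok), length(scenarios) > 0,
            length(penalties) > 0, replicates >= 1L)
  cells <- expand.grid(scenario = scenarios,
                       architecture = as.character(architectures),
                       penalty = penalties,
                       stringsAsFactors = FALSE)
  cells$cell <- seq_len(nrow(cells))
  structure(list(cells = cells, replicates = as.integer(replicates),
                 scale = scale, masterSeed = as.integer(masterSeed)),
            class = "ExperimentGrid")
}

#' @export
print.ExperimentGrid <- function(x, ...) {
  cat("ExperimentGrid:", nrow(x$cells), "cells x", x$replicates,
      "replicates,", x$scale, "scale, master seed", x$masterSeed, "\n")
  invisible(x)
}

## config for one cell at the grid's scale
cellConfig <- function(grid, i) {
  row <- grid$cells[i, ]
  src <- strsplit(row$scenario, "_")[[1L]]
  nQtl <- if (row$architecture == "all") "all" else as.integer(row$architecture)
  maker <- if (grid$scale == "reduced") reducedSchemeConfig else schemeConfig
  ## common marker-driven truncation phase: scenarios share the pre-OCS
  ## history under paired seeds and differ only in the OCS phase
  maker(predSource = src[1L], coanSource = src[2L], truncPredSource = "M",
        nQtl = nQtl, penalty = row$penalty)
}

## founder matching the grid's scale (shared by every cell)
gridFounder <- function(grid) {
  set.seed(deriveSeed(grid$masterSeed, 0L))
  if (grid$scale == "reduced") {
    runFounder(reducedGenome(), nGenerations = 200L, popSize = 50L)
  } else {
    runFounder(genomeSpec(), nGenerations = 1000L, popSize = 50L)
  }
}

#' Run an experiment grid
#'
#' Runs every (cell, replicate) with seeds derived from the master seed;
#' one founder population (from the master seed) is shared by all cells,
#' and each replicate samples a unique base population. If `outDir` is
#' given, per-cell replicate CSVs are written and completed cells are
#' skipped on re-runs; replicate failures are recorded and the run
#' continues.
#'
#' @param grid an [experimentGrid()].
#' @param pools optional pre-built [FounderPools-class] (defaults to one
#'   built from the master seed at the grid's scale).
#' @param outDir optional output directory for per-cell CSVs + manifest.
#' @return list: `replicates` (data.frame of per-replicate summaries),
#'   `aggregate` (per-cell means and SEs), `errors` (per-cell messages).
#' @export
runGrid <- function(grid, pools = NULL, outDir = NULL) {
  if (is.null(pools)) pools <- gridFounder(grid)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  reps <- NULL
  errors <- character()
  for (i in seq_len(nrow(grid$cells))) {
    row <- grid$cells[i, ]
    cellFile <- if (!is.null(outDir))
      file.path(outDir, sprintf("cell_%03d.csv", i)) else NULL
    if (!is.null(cellFile) && file.exists(cellFile)) {
      reps <- rbind(reps, read.table(cellFile, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE))
      next
    }
    cfg <- cellConfig(grid, i)
    cellReps <- NULL
    for (r in seq_len(grid$replicates)) {
      seed <- deriveSeed(grid$masterSeed, i * 1000L + r)
      res <- tryCatch(runScheme(pools, cfg, seed), error = function(e) e)
      if (inherits(res, "error")) {
        errors <- c(errors, sprintf("cell %d rep %d: %s", i, r,
                                    conditionMessage(res)))
        next
      }
      cellReps <- rbind(cellReps, data.frame(
        scenario = row$scenario, architecture = row$architecture,
        penalty = row$penalty, rep = r, seed = seed,
        dG = res@dG, dFtrue = res@dFtrue, dFped = res@dFped,
        accMale = res@accMale, accFemale = res@accFemale,
        stringsAsFactors = FALSE))
    }
    if (!is.null(cellFile) && !is.null(cellReps))
      write.table(cellReps, cellFile, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    reps <- rbind(reps, cellReps)
  }
  agg <- if (!is.null(reps))
    aggregateReplicates(reps[, !(names(reps) %in% c("rep", "seed"))])
  else NULL
  if (!is.null(outDir)) {
    writeLines(c(sprintf("masterSeed\t%d", grid$masterSeed),
                 sprintf("scale\t%s", grid$scale),
                 sprintf("replicates\t%d", grid$replicates),
                 sprintf("cells\t%d", nrow(grid$cells))),
               file.path(outDir, "manifest.tsv"))
    if (!is.null(agg))
      write.table(agg, file.path(outDir, "aggregate.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  list(replicates = reps, aggregate = agg, errors = errors)
}

#' Summary tables from grid results
#'
#' A gain/inbreeding table (per scenario and architecture: mean rates of
#' gain and pedigree inbreeding with SEs, one column block per penalty or
#' realized-inbreeding target), an accuracy table (male/female prediction
#' accuracy), and gain-versus-inbreeding plot data (scenario, penalty,
#' mean realized rate of true inbreeding, mean rate of gain, SEs).
#'
#' @param results the list returned by [runGrid()].
#' @return list of data.frames: `gain`, `accuracy`, `plotData`.
#' @export
makeTables <- function(results) {
  agg <- results$aggregate
  if (is.null(agg) || !nrow(agg))
    return(list(
      gain = data.frame(scenario = character(), architecture = character(),
                        penalty = numeric(), dG = numeric(),
                        dG_se = numeric(), dFped = numeric(),
                        dFped_se = numeric()),
      accuracy = data.frame(scenario = character(),
                            accMale = numeric(), accMale_se = numeric(),
                            accFemale = numeric(), accFemale_se = numeric()),
      plotData = data.frame(scenario = character(), penalty = numeric(),
                            dFtrue = numeric(), dG = numeric())))
  gain <- agg[, c("scenario", "architecture", "penalty",
                  "dG", "dG_se", "dFped", "dFped_se")]
  accTab <- agg[, c("scenario", "architecture", "penalty",
                    "accMale", "accMale_se", "accFemale", "accFemale_se")]
  plotData <- agg[, c("scenario", "architecture", "penalty",
                      "dFtrue", "dFtrue_se", "dG", "dG_se")]
  list(gain = gain, accuracy = accTab, plotData = plotData)
}
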