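#' Default pipeline configuration
#'
#' Every analysis constant is reachable from here, none hard-coded in the
#' stages: QC thresholds (200-gene/3-cell prefilter; 55,000-read,
#' 2,000-gene, 70-of-98-housekeeping, 20%-mito outlier rules with
#' per-line overrides), the 10,000x log-normalization scale factor, 2,000
#' HVGs, 24-bin/100-control module scoring, the cycling and state-mode
#' switches, the 700-cell DE quota with Bonferroni correction, and
#' 1,000-permutation weighted GSEA. The simulation block states the
#' synthetic cohort (10 lines x 2 x 800 cells, planted CSF effects); on
#' synthetic data the gene-count outlier threshold defaults to 500 (a
#' per-line override value from the published rules) because the
#' simulated transcriptome has only 2,000 genes.
#'
#' @return Nested list of stage parameter blocks.
#' @export
defaultPipelineConfig <- function() {
  list(
    simulate = list(nPatients = 10, nCellsPerCondition = 800,
                    nGenes = 2000, outlierFraction = 0.02,
                    csfEffects = list(MES = 1, quiescence = 0.5,
                                      G1S = -0.5, G2M = -0.5),
                    plantedDE = list(gene = "NUPR1", log2fc = 1.5)),
    qc = list(minGenesPerCell = 200, minCellsPerGene = 3,
              maxReads = 55000, minGenesOutlier = 500,
              minHousekeeping = 70, housekeepingListSize = 98,
              maxMitoFraction = 0.20, maxReadsOverride = list(),
              minGenesOverride = list(), keepFlagged = FALSE),
    normalize = list(scaleFactor = 10000),
    hvg = list(n = 2000),
    score = list(nBins = 24, nCtrl = 100, cyclingMode = "average"),
    states = list(mode = "corrected"),
    de = list(quota = 700, topK = 20),
    gsea = list(nPerm = 1000, weight = 1),
    seed = 1L)
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (!nm %in% names(base)) stop(sprintf("unknown config key: '%s'", nm))
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys take their defaults.
#'
#' @param path YAML file path.
#' @return Full configuration list.
#' @export
readPipelineConfig <- function(path) {
  mergeConfig(defaultPipelineConfig(), yaml::read_yaml(path))
}

stageLog <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

#' Run the full single-cell analysis pipeline
#'
#' Simulate (or load) -> QC -> normalize -> score -> states -> DE -> GSEA,
#' with all stage outputs written to `outDir` as plain-text tables and a
#' JSON run manifest (config, seeds, per-file MD5 checksums) written
#' last. Stages communicate through files so each is independently
#' reproducible; re-running with the same config and seed produces
#' identical checksums.
#'
#' @param config a configuration list (see [defaultPipelineConfig()]) or
#'   a YAML file path.
#' @param outDir output directory.
#' @param sce optionally, an existing SingleCellExperiment to analyse
#'   instead of simulating one (its ground truth, if any, is still used
#'   for the gene sets).
#' @param seed overrides `config$seed` when non-NULL.
#' @param verbose log stage progress.
#' @return Invisibly, a list with the manifest and in-memory stage
#'   results (`sce`, `scores`, `states`, `composition`, `de`, `gsea`,
#'   `report`).
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir,
                        sce = NULL, seed = NULL, verbose = TRUE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- mergeConfig(defaultPipelineConfig(), config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  if (is.null(sce)) {
    stageLog(verbose, "simulate: %d lines x 2 x %d cells, %d genes",
             config$simulate$nPatients,
             config$simulate$nCellsPerCondition, config$simulate$nGenes)
    simCfg <- config$simulate
    sce <- simulateCells(ScSimParams(
      nPatients = simCfg$nPatients,
      nCellsPerCondition = simCfg$nCellsPerCondition,
      nGenes = simCfg$nGenes, outlierFraction = simCfg$outlierFraction,
      csfEffects = unlist(simCfg$csfEffects),
      plantedDE = as.data.frame(simCfg$plantedDE),
      seed = childSeed(config$seed, 11)))
  }
  gt <- S4Vectors::metadata(sce)$groundTruth
  writeCellDataset(sce, file.path(outDir, "raw"))
  if (!is.null(gt)) {
    jsonlite::write_json(
      list(csfEffects = as.list(gt$csfEffects), plantedDE = gt$plantedDE,
           outliers = gt$outliers, seed = gt$seed),
      file.path(outDir, "ground_truth.json"), auto_unbox = TRUE,
      digits = NA)
  }

  qcCfg <- config$qc
  th <- qcThresholds(
    minGenesPerCell = qcCfg$minGenesPerCell,
    minCellsPerGene = qcCfg$minCellsPerGene, maxReads = qcCfg$maxReads,
    minGenesOutlier = qcCfg$minGenesOutlier,
    minHousekeeping = qcCfg$minHousekeeping,
    housekeepingListSize = qcCfg$housekeepingListSize,
    maxMitoFraction = qcCfg$maxMitoFraction,
    maxReadsOverride = unlist(qcCfg$maxReadsOverride) %||% numeric(0),
    minGenesOverride = unlist(qcCfg$minGenesOverride) %||% numeric(0))
  stageLog(verbose, "qc: %d cells in", ncol(sce))
  sce <- runQC(sce, th, seed = childSeed(config$seed, 12),
               keepFlagged = isTRUE(qcCfg$keepFlagged))
  report <- S4Vectors::metadata(sce)$qcReport
  stageLog(verbose, "qc: %d cells out (%d outliers)", ncol(sce),
           report$nOutliers)
  utils::write.table(report$perLine, file.path(outDir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sce <- logNormalize(sce, scaleFactor = config$normalize$scaleFactor)
  hvg <- selectHVG(sce, n = min(config$hvg$n, nrow(sce)))
  writeLines(hvg, file.path(outDir, "hvg.txt"))

  gsc <- if (!is.null(gt)) defaultGeneSets(sce) else {
    stop("no gene sets available: supply simulated data or extend runPipeline")
  }
  writeGmt(gsc, file.path(outDir, "gene_sets.gmt"))

  stageLog(verbose, "score: %d sets x %d cells", length(gsc), ncol(sce))
  scores <- scoreCells(sce, gsc, nBins = config$score$nBins,
                       nCtrl = config$score$nCtrl,
                       seed = childSeed(config$seed, 13),
                       cyclingMode = config$score$cyclingMode)
  utils::write.table(cbind(cell = rownames(scores), as.data.frame(scores)),
                     file.path(outDir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  states <- projectStates(scores, mode = config$states$mode)
  comp <- stateComposition(states, sce$line, sce$condition)
  utils::write.table(cbind(cell = rownames(states), as.data.frame(states)),
                     file.path(outDir, "states.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(comp, file.path(outDir, "composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  stageLog(verbose, "de: downsampling to %d cells/line/condition",
           config$de$quota)
  down <- downsampleBalanced(sce, quota = config$de$quota,
                             seed = childSeed(config$seed, 14))
  down <- logNormalize(down, scaleFactor = config$normalize$scaleFactor)
  de <- wilcoxonDE(down)
  top <- topMarkers(de, k = config$de$topK)
  ranks <- rankGenes(de)
  utils::write.table(de, file.path(outDir, "de.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeRnk(ranks, file.path(outDir, "ranks.rnk"))

  stageLog(verbose, "gsea: %d sets, %d permutations", length(gsc),
           config$gsea$nPerm)
  gseaSets <- geneSets(gsc)[intersect(
    c("MES", "MES1", "MES2", "G1S", "G2M", "quiescence"), names(gsc))]
  gsea <- gseaPreranked(ranks, gseaSets, nPerm = config$gsea$nPerm,
                        p = config$gsea$weight,
                        seed = childSeed(config$seed, 15))
  utils::write.table(gsea[setdiff(names(gsea), "leading_edge")],
                     file.path(outDir, "gsea.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  recovery <- if (!is.null(gt)) {
    csf <- sce$condition == "CSF"
    list(
      mesShiftRecovered = mean(scores$MES[csf]) > mean(scores$MES[!csf]),
      quiescenceShiftRecovered =
        mean(scores$quiescent[csf] == "Quiescent") >
          mean(scores$quiescent[!csf] == "Quiescent"),
      plantedDEInTopK = all(gt$plantedDE$gene[gt$plantedDE$log2fc > 0]
                            %in% top$csf),
      gseaHits = gsea$set[gsea$p_perm < 0.05])
  } else NULL

  outputs <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package = as.character(utils::packageVersion("csfShift")),
    seed = config$seed, config = config,
    timestamps = list(start = format(t0), end = format(Sys.time())),
    checksums = as.list(tools::md5sum(sort(outputs))),
    recovery = recovery)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  stageLog(verbose, "done")
  invisible(list(manifest = manifest, sce = sce, scores = scores,
                 states = states, composition = comp, de = de, top = top,
                 gsea = gsea, report = report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
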