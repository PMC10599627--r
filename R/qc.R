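#' Quality-control thresholds
#'
#' Defaults are the published filtering rules for this pipeline's cohort:
#' cells must express at least 200 genes and genes be expressed in at least
#' 3 cells (prefilter); a cell is then tagged as an outlier when it has
#' more than 55,000 reads (80,000 for lines with an override), fewer than
#' 2,000 detected genes (per-line overrides 500/800/1,000 exist for
#' shallow-sequenced lines), fewer than 70 of the 98 housekeeping panel
#' genes, or more than 20% mitochondrial reads.
#'
#' @param minGenesPerCell prefilter: minimum genes detected per cell.
#' @param minCellsPerGene prefilter: minimum cells expressing a gene.
#' @param maxReads outlier: maximum reads per cell.
#' @param minGenesOutlier outlier: minimum detected genes per cell.
#' @param minHousekeeping outlier: minimum housekeeping genes detected.
#' @param housekeepingListSize size of the housekeeping panel.
#' @param maxMitoFraction outlier: maximum mitochondrial read fraction.
#' @param maxReadsOverride,minGenesOverride named numeric vectors of
#'   per-line overrides (names are line ids), e.g.
#'   `maxReadsOverride = c(MN1 = 80000)`.
#' @return A list of class `QCThresholds`.
#' @examples
#' th <- qcThresholds(maxReadsOverride = c(MN1 = 80000))
#' th$maxReads
#' @export
qcThresholds <- function(minGenesPerCell = 200, minCellsPerGene = 3,
    maxReads = 55000, minGenesOutlier = 2000, minHousekeeping = 70,
    housekeepingListSize = 98, maxMitoFraction = 0.20,
    maxReadsOverride = numeric(0), minGenesOverride = numeric(0)) {
  th <- list(minGenesPerCell = minGenesPerCell,
             minCellsPerGene = minCellsPerGene, maxReads = maxReads,
             minGenesOutlier = minGenesOutlier,
             minHousekeeping = minHousekeeping,
             housekeepingListSize = housekeepingListSize,
             maxMitoFraction = maxMitoFraction,
             maxReadsOverride = maxReadsOverride,
             minGenesOverride = minGenesOverride)
  num <- unlist(th[1:7])
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all thresholds must be positive")
  }
  structure(th, class = "QCThresholds")
}

#' Prefilter cells and genes
#'
#' Keeps cells expressing at least `minGenesPerCell` genes (drops empty
#' droplets) and genes expressed in at least `minCellsPerGene` cells. The
#' cell pass runs first, then the gene pass, iterating to a fixed point so
#' the returned matrix satisfies both rules simultaneously.
#'
#' @param sce a SingleCellExperiment with a `counts` assay.
#' @param thresholds a [qcThresholds()] list.
#' @return The filtered SingleCellExperiment with refreshed QC metrics.
#'   An empty result warns but does not error.
#' @export
prefilterCells <- function(sce, thresholds = qcThresholds()) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  keepGene <- rep(TRUE, nrow(counts))
  keepCell <- rep(TRUE, ncol(counts))
  repeat {
    sub <- counts[keepGene, keepCell, drop = FALSE]
    genesPerCell <- Matrix::colSums(sub > 0)
    dropCell <- genesPerCell < thresholds$minGenesPerCell
    if (any(dropCell)) {
      keepCell[keepCell][dropCell] <- FALSE
      sub <- counts[keepGene, keepCell, drop = FALSE]
    }
    cellsPerGene <- Matrix::rowSums(sub > 0)
    dropGene <- cellsPerGene < thresholds$minCellsPerGene
    if (any(dropGene)) keepGene[keepGene][dropGene] <- FALSE
    if (!any(dropCell) && !any(dropGene)) break
  }
  if (!any(keepCell) || !any(keepGene)) {
    warning("prefilter removed everything; returning empty dataset")
  }
  out <- sce[keepGene, keepCell]
  if (ncol(out) && nrow(out)) out <- addQCMetrics(out)
  out
}

#' Tag QC-outlier cells with reason codes
#'
#' A cell is an outlier iff it violates any of the four criteria: too many
#' reads, too few detected genes, too few housekeeping genes, or too high
#' a mitochondrial fraction. Per-line threshold overrides are honored.
#'
#' @param sce a SingleCellExperiment whose `colData` carries `line`,
#'   `reads`, `genesDetected`, `housekeepingDetected`, `mitoFraction`
#'   (recomputed via [addQCMetrics()] if absent).
#' @param thresholds a [qcThresholds()] list.
#' @return A [S4Vectors::DataFrame] with logical `outlier` and character
#'   `reasons` (comma-separated codes among `reads`, `genes`,
#'   `housekeeping`, `mito`; empty when the cell passes).
#' @export
flagOutliers <- function(sce, thresholds = qcThresholds()) {
  needed <- c("reads", "genesDetected", "housekeepingDetected",
              "mitoFraction")
  if (!all(needed %in% colnames(SummarizedExperiment::colData(sce)))) {
    sce <- addQCMetrics(sce)
  }
  lines <- as.character(sce$line)
  for (ov in c("maxReadsOverride", "minGenesOverride")) {
    unknown <- setdiff(names(thresholds[[ov]]), unique(lines))
    if (length(unknown)) {
      stop(sprintf("override for unknown line id(s): %s",
                   paste(unknown, collapse = ", ")))
    }
  }
  maxReads <- rep(thresholds$maxReads, ncol(sce))
  hit <- lines %in% names(thresholds$maxReadsOverride)
  maxReads[hit] <- thresholds$maxReadsOverride[lines[hit]]
  minGenes <- rep(thresholds$minGenesOutlier, ncol(sce))
  hit <- lines %in% names(thresholds$minGenesOverride)
  minGenes[hit] <- thresholds$minGenesOverride[lines[hit]]

  v <- cbind(reads = sce$reads > maxReads,
             genes = sce$genesDetected < minGenes,
             housekeeping = sce$housekeepingDetected <
               thresholds$minHousekeeping,
             mito = sce$mitoFraction > thresholds$maxMitoFraction)
  reasons <- apply(v, 1L, function(r) {
    paste(colnames(v)[r], collapse = ",")
  })
  S4Vectors::DataFrame(outlier = rowSums(v) > 0, reasons = reasons,
                       row.names = colnames(sce))
}

#' Remove (or keep but tag) outlier cells
#'
#' @param sce a SingleCellExperiment.
#' @param thresholds a [qcThresholds()] list.
#' @param keepFlagged if `TRUE`, outliers are kept and only annotated in
#'   `colData` (audit mode); default removes them.
#' @return The filtered (or annotated) SingleCellExperiment.
#' @export
removeOutliers <- function(sce, thresholds = qcThresholds(),
                           keepFlagged = FALSE) {
  flags <- flagOutliers(sce, thresholds)
  sce$qcOutlier <- flags$outlier
  sce$qcReasons <- flags$reasons
  if (keepFlagged) sce else sce[, !flags$outlier]
}

#' Balance GM and CSF cell numbers within each line
#'
#' Within each line, subsamples the larger condition uniformly without
#' replacement so both conditions contain exactly `min(nGM, nCSF)` cells.
#' Cells are subset, never mutated.
#'
#' @param sce a SingleCellExperiment with `line` and `condition` columns.
#' @param seed integer seed for reproducible subsampling (NULL uses the
#'   current RNG stream).
#' @return The balanced SingleCellExperiment.
#' @export
balanceConditions <- function(sce, seed = NULL) {
  cd <- SummarizedExperiment::colData(sce)
  tab <- table(cd$line, cd$condition)
  missing <- rownames(tab)[apply(tab[, c("GM", "CSF"), drop = FALSE], 1L,
                                 min) == 0]
  if (length(missing)) {
    stop(sprintf("line(s) missing one condition entirely: %s",
                 paste(missing, collapse = ", ")))
  }
  withSeed(seed, {
    keep <- unlist(lapply(rownames(tab), function(ln) {
      quota <- min(tab[ln, c("GM", "CSF")])
      unlist(lapply(c("GM", "CSF"), function(cond) {
        idx <- which(cd$line == ln & cd$condition == cond)
        if (length(idx) > quota) sort(sample(idx, quota)) else idx
      }))
    }))
    sce[, sort(keep)]
  })
}

#' One-call QC: prefilter, outlier removal, condition balancing
#'
#' @inheritParams removeOutliers
#' @param seed passed to [balanceConditions()].
#' @return The QC'd SingleCellExperiment; a per-line QC report (retained
#'   counts and outlier reason tallies) is attached as
#'   `metadata(sce)$qcReport`.
#' @export
runQC <- function(sce, thresholds = qcThresholds(), seed = NULL,
                  keepFlagged = FALSE) {
  pre <- prefilterCells(sce, thresholds)
  flags <- flagOutliers(pre, thresholds)
  filt <- removeOutliers(pre, thresholds, keepFlagged = keepFlagged)
  bal <- balanceConditions(filt, seed = seed)
  reasons <- unlist(strsplit(flags$reasons[flags$outlier], ","))
  report <- list(
    nInput = ncol(sce), nPrefiltered = ncol(pre),
    nOutliers = sum(flags$outlier), nBalanced = ncol(bal),
    reasonTally = table(factor(reasons, levels = c("reads", "genes",
                                                   "housekeeping", "mito"))),
    perLine = as.data.frame(table(line = bal$line,
                                  condition = bal$condition)))
  S4Vectors::metadata(bal)$qcReport <- report
  bal
}
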