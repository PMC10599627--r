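#' Parameters for the synthetic single-cell experiment generator
#'
#' Describes a cohort of patient-derived glioblastoma lines cultured in
#' parallel in glioma medium (GM) and cerebrospinal fluid (CSF), with
#' transcriptional programs whose activity can be shifted by the CSF
#' condition. Defaults emulate the design this pipeline targets: 10 patient
#' lines, two conditions, negative-binomial counts with lognormal library
#' sizes, a 98-gene housekeeping panel and a mitochondrial gene block for
#' QC, and plantable per-program log2 activity shifts.
#'
#' @slot nPatients number of patient lines.
#' @slot nCellsPerCondition cells drawn per line per condition (before QC).
#' @slot nGenes total number of genes.
#' @slot programSizes named integer vector of program gene-list sizes
#'   (AC, MES1, MES2, NPC, OPC, G1S, G2M, quiescence).
#' @slot baselineLogMeanRange range of per-gene baseline log expression
#'   weights (natural log).
#' @slot dispersion negative-binomial dispersion (1/size); scalar or
#'   per-gene.
#' @slot librarySizeLognormal `(meanlog, sdlog)` of per-cell library sizes.
#' @slot mitoGeneCount,housekeepingGeneCount sizes of the two QC panels.
#' @slot csfEffects named numeric: per-program log2 activity shift applied
#'   in CSF. Key `"MES"` expands to both MES1 and MES2.
#' @slot plantedDE data.frame (gene, log2fc) of single-gene condition
#'   effects; the default plants one NUPR1-like stress-response gene up in
#'   CSF.
#' @slot outlierFraction fraction of cells planted to violate exactly one
#'   QC outlier criterion each (reads/genes/housekeeping/mito in rotation).
#' @slot patientSD,cellSD SDs (log2) of patient-level baseline and
#'   cell-level noise on program activity.
#' @slot seed integer seed; the generator is fully reproducible from it.
#' @seealso [ScSimParams()], [simulateCells()]
#' @export
setClass("ScSimParams", slots = c(
  nPatients = "integer", nCellsPerCondition = "integer", nGenes = "integer",
  programSizes = "integer", baselineLogMeanRange = "numeric",
  dispersion = "numeric", librarySizeLognormal = "numeric",
  mitoGeneCount = "integer", housekeepingGeneCount = "integer",
  csfEffects = "numeric", plantedDE = "data.frame",
  outlierFraction = "numeric", patientSD = "numeric", cellSD = "numeric",
  seed = "integer"))

setValidity("ScSimParams", function(object) {
  msg <- character()
  counts <- c(object@nPatients, object@nCellsPerCondition, object@nGenes,
              object@mitoGeneCount, object@housekeepingGeneCount)
  if (any(counts <= 0L)) msg <- c(msg, "all counts must be > 0")
  if (any(object@dispersion <= 0)) msg <- c(msg, "dispersion must be > 0")
  if (any(object@programSizes <= 0L)) {
    msg <- c(msg, "program sizes must be > 0")
  }
  need <- sum(object@programSizes) + object@mitoGeneCount +
    object@housekeepingGeneCount + nrow(object@plantedDE)
  if (need > object@nGenes) {
    msg <- c(msg, sprintf(
      "nGenes (%d) too small for disjoint program/mito/housekeeping/planted lists (%d needed)",
      object@nGenes, need))
  }
  if (object@outlierFraction < 0 || object@outlierFraction >= 1) {
    msg <- c(msg, "outlierFraction must be in [0, 1)")
  }
  unknown <- setdiff(names(object@csfEffects),
                     c(names(object@programSizes), "MES"))
  if (length(unknown)) {
    msg <- c(msg, sprintf("csfEffects names unknown program(s): %s",
                          paste(unknown, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct simulation parameters for the single-cell generator
#'
#' Defaults state the cohort this pipeline is designed for: 10 lines x 2
#' conditions x 800 cells, 2,000 genes, program sizes matching the gene-set
#' collection used downstream (MES split 50+50, G1S 43, G2M 54, quiescence
#' 100), and CSF effects of +1 log2 on the MES program, +0.5 on quiescence
#' and -0.5 on both cell-cycle programs, plus one NUPR1-like gene up 1.5
#' log2 in CSF.
#'
#' @param nPatients,nCellsPerCondition,nGenes cohort dimensions.
#' @param programSizes named gene-list sizes per program.
#' @param baselineLogMeanRange,dispersion,librarySizeLognormal noise model.
#' @param mitoGeneCount,housekeepingGeneCount QC panel sizes.
#' @param csfEffects named log2 activity shifts applied in CSF ("MES"
#'   expands to MES1 and MES2). Use `numeric(0)` for a null world.
#' @param plantedDE data.frame with columns `gene` and `log2fc`.
#' @param outlierFraction fraction of planted QC violators.
#' @param patientSD,cellSD program-activity noise SDs (log2).
#' @param seed integer seed.
#' @return A validated [ScSimParams-class] object.
#' @examples
#' p <- ScSimParams(nPatients = 2, nCellsPerCondition = 50, seed = 1)
#' sce <- simulateCells(p)
#' @export
ScSimParams <- function(nPatients = 10, nCellsPerCondition = 800,
    nGenes = 2000,
    programSizes = c(AC = 50L, MES1 = 50L, MES2 = 50L, NPC = 50L,
                     OPC = 50L, G1S = 43L, G2M = 54L, quiescence = 100L),
    baselineLogMeanRange = c(-2, 2), dispersion = 0.4,
    librarySizeLognormal = c(meanlog = log(12000), sdlog = 0.25),
    mitoGeneCount = 13, housekeepingGeneCount = 98,
    csfEffects = c(MES = 1, quiescence = 0.5, G1S = -0.5, G2M = -0.5),
    plantedDE = data.frame(gene = "NUPR1", log2fc = 1.5),
    outlierFraction = 0.02, patientSD = 0.2, cellSD = 0.3, seed = 1L) {
  new("ScSimParams",
      nPatients = assertScalarCount(nPatients, "nPatients"),
      nCellsPerCondition = assertScalarCount(nCellsPerCondition,
                                             "nCellsPerCondition"),
      nGenes = assertScalarCount(nGenes, "nGenes"),
      programSizes = setNames(as.integer(programSizes),
                              names(programSizes)),
      baselineLogMeanRange = as.numeric(baselineLogMeanRange),
      dispersion = as.numeric(dispersion),
      librarySizeLognormal = as.numeric(librarySizeLognormal),
      mitoGeneCount = assertScalarCount(mitoGeneCount, "mitoGeneCount"),
      housekeepingGeneCount = assertScalarCount(housekeepingGeneCount,
                                                "housekeepingGeneCount"),
      csfEffects = if (length(csfEffects)) csfEffects else numeric(0),
      plantedDE = plantedDE, outlierFraction = as.numeric(outlierFraction),
      patientSD = as.numeric(patientSD), cellSD = as.numeric(cellSD),
      seed = as.integer(seed))
}

# Expand a csfEffects map so key "MES" applies to MES1 and MES2.
expandCsfEffects <- function(effects, programs) {
  out <- setNames(numeric(length(programs)), programs)
  for (nm in names(effects)) {
    if (nm == "MES") {
      out[intersect(c("MES1", "MES2"), programs)] <- effects[[nm]]
    } else out[[nm]] <- effects[[nm]]
  }
  out
}

#' Simulate a two-condition glioblastoma single-cell dataset
#'
#' Draws a gene x cell count matrix under a hierarchical model: each
#' transcriptional program has a per-patient baseline activity
#' (log2-normal), a condition shift in CSF, and per-cell noise; gene means
#' are baseline expression weights scaled by their program's activity;
#' counts are negative binomial with lognormal per-cell library sizes.
#' Housekeeping genes are drawn at high baseline so intact cells detect
#' most of the 98-gene panel; mitochondrial genes contribute roughly 8% of
#' reads at baseline. A configurable fraction of cells is planted to
#' violate exactly one QC outlier criterion each.
#'
#' @param params an [ScSimParams-class] object.
#' @return A [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment]
#'   with a sparse `counts` assay; `colData` columns `line`, `condition`
#'   (factor GM/CSF) and QC metrics (`reads`, `genesDetected`,
#'   `housekeepingDetected`, `mitoFraction`); `rowData` columns `symbol`,
#'   `is_mito`, `is_housekeeping`, `program`; and
#'   `metadata(sce)$groundTruth` recording every planted effect (program
#'   activity shifts per condition, planted DE genes, planted outlier cells
#'   with their violation type, and the per-program gene lists).
#' @examples
#' sce <- simulateCells(ScSimParams(nPatients = 2, nCellsPerCondition = 60,
#'                                  seed = 7))
#' table(sce$line, sce$condition)
#' @export
simulateCells <- function(params) {
  stopifnot(is(params, "ScSimParams"))
  validObject(params)
  withSeed(params@seed, simulateCellsImpl(params))
}

simulateCellsImpl <- function(params) {
  nG <- params@nGenes
  progSizes <- params@programSizes
  programs <- names(progSizes)

  # --- gene annotation: disjoint program / planted / mito / housekeeping ---
  symbols <- sprintf("G%04d", seq_len(nG))
  plantedGenes <- as.character(params@plantedDE$gene)
  mitoIdx <- seq_len(params@mitoGeneCount)
  symbols[mitoIdx] <- sprintf("MT-%d", seq_along(mitoIdx))
  hkIdx <- params@mitoGeneCount + seq_len(params@housekeepingGeneCount)
  symbols[hkIdx] <- sprintf("HK%02d", seq_along(hkIdx))
  cursor <- params@mitoGeneCount + params@housekeepingGeneCount
  program <- rep(NA_character_, nG)
  programGenes <- list()
  for (pg in programs) {
    idx <- cursor + seq_len(progSizes[[pg]])
    program[idx] <- pg
    programGenes[[pg]] <- symbols[idx]
    cursor <- cursor + progSizes[[pg]]
  }
  if (length(plantedGenes)) {
    idx <- cursor + seq_along(plantedGenes)
    symbols[idx] <- plantedGenes
    cursor <- cursor + length(plantedGenes)
  }

  # --- baseline expression weights (relative, natural-log uniform) ---
  w <- exp(runif(nG, params@baselineLogMeanRange[1L],
                 params@baselineLogMeanRange[2L]))
  # housekeeping panel: upper end of the expression continuum (not a
  # detached island, which would defeat expression-bin matching) so
  # >=70/98 are detected in every intact cell
  w[hkIdx] <- exp(runif(length(hkIdx), 1.2, 2.0))
  # mitochondrial block: top of the continuum (about 2-3% of reads at
  # baseline; planted violators are pushed past the 20% threshold later)
  w[mitoIdx] <- exp(runif(length(mitoIdx), 1.6, 2.1))
  # planted DE genes: mid-high so the effect is well powered
  if (length(plantedGenes)) {
    w[match(plantedGenes, symbols)] <- exp(1.5)
  }

  effects <- expandCsfEffects(params@csfEffects, programs)
  dispersion <- rep_len(params@dispersion, nG)

  nPerLine <- params@nCellsPerCondition
  lines <- sprintf("L%02d", seq_len(params@nPatients))
  nCells <- params@nPatients * 2L * nPerLine
  line <- rep(lines, each = 2L * nPerLine)
  condition <- rep(rep(c("GM", "CSF"), each = nPerLine), params@nPatients)
  barcode <- sprintf("%s_%s_%04d", line, condition,
                     sequence(rep(nPerLine, 2L * params@nPatients)))

  # per-patient baseline program activity (log2)
  patientBase <- matrix(rnorm(params@nPatients * length(programs),
                              sd = params@patientSD),
                        nrow = params@nPatients,
                        dimnames = list(lines, programs))

  progIdx <- lapply(programs, function(pg) which(program == pg))
  names(progIdx) <- programs
  plantedIdx <- match(plantedGenes, symbols)
  plantedL2 <- params@plantedDE$log2fc

  libSizes <- rlnorm(nCells, params@librarySizeLognormal[1L],
                     params@librarySizeLognormal[2L])

  # planted QC violators, one criterion each in rotation
  nOut <- floor(params@outlierFraction * nCells)
  outCells <- if (nOut > 0) sort(sample.int(nCells, nOut)) else integer(0)
  outType <- rep(c("reads", "genes", "housekeeping", "mito"),
                 length.out = nOut)
  libSizes[outCells[outType == "reads"]] <- 75000
  libSizes[outCells[outType == "genes"]] <- 450

  hkOut <- outCells[outType == "housekeeping"]
  mtOut <- outCells[outType == "mito"]

  # draw counts per cell block-wise to bound peak memory
  blocks <- split(seq_len(nCells), ceiling(seq_len(nCells) / 2000))
  colBlocks <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    cells <- blocks[[b]]
    mu <- matrix(w, nrow = nG, ncol = length(cells))
    for (pg in programs) {
      act <- patientBase[line[cells], pg] +
        ifelse(condition[cells] == "CSF", effects[[pg]], 0) +
        rnorm(length(cells), sd = params@cellSD)
      mu[progIdx[[pg]], ] <- mu[progIdx[[pg]], ] *
        rep(2^act, each = length(progIdx[[pg]]))
    }
    if (length(plantedIdx)) {
      isCsf <- condition[cells] == "CSF"
      for (k in seq_along(plantedIdx)) {
        mu[plantedIdx[k], isCsf] <- mu[plantedIdx[k], isCsf] *
          2^plantedL2[k]
      }
    }
    mu <- sweep(mu, 2L, colSums(mu), "/")
    mu <- sweep(mu, 2L, libSizes[cells], "*")
    cnt <- matrix(rnbinom(length(mu), mu = mu,
                          size = rep(1 / dispersion, length(cells))),
                  nrow = nG)
    # planted housekeeping violators: keep only 40 panel genes detectable
    loc <- which(cells %in% hkOut)
    if (length(loc)) cnt[hkIdx[-seq_len(40)], loc] <- 0L
    # planted mito violators: scale mito block to ~30% of reads
    for (j in which(cells %in% mtOut)) {
      tot <- sum(cnt[, j])
      mito <- sum(cnt[mitoIdx, j])
      if (tot > mito) {
        cnt[mitoIdx, j] <- round(cnt[mitoIdx, j] *
          0.3 * (tot - mito) / max(1, mito * 0.7))
      }
    }
    colBlocks[[b]] <- methods::as(Matrix::Matrix(cnt, sparse = TRUE),
                                  "CsparseMatrix")
  }
  counts <- do.call(cbind, colBlocks)
  dimnames(counts) <- list(symbols, barcode)

  rowData <- S4Vectors::DataFrame(
    symbol = symbols,
    is_mito = seq_len(nG) %in% mitoIdx,
    is_housekeeping = seq_len(nG) %in% hkIdx,
    program = program, row.names = symbols)
  colData <- S4Vectors::DataFrame(
    line = line, condition = factor(condition, levels = c("GM", "CSF")),
    row.names = barcode)

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), rowData = rowData, colData = colData)
  sce <- addQCMetrics(sce)
  S4Vectors::metadata(sce)$groundTruth <- list(
    csfEffects = effects,
    plantedDE = params@plantedDE,
    outliers = data.frame(cell = barcode[outCells], type = outType,
                          stringsAsFactors = FALSE),
    programGenes = programGenes,
    patientBaseline = patientBase,
    seed = params@seed)
  sce
}

#' Recompute per-cell QC metrics
#'
#' Adds `reads`, `genesDetected`, `housekeepingDetected` and `mitoFraction`
#' to `colData`. Mitochondrial fraction is raw counts on mito-tagged genes
#' divided by total counts.
#'
#' @param sce a SingleCellExperiment with a `counts` assay and `is_mito` /
#'   `is_housekeeping` columns in `rowData`.
#' @return The object with refreshed QC columns.
#' @export
addQCMetrics <- function(sce) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  rd <- SummarizedExperiment::rowData(sce)
  tot <- Matrix::colSums(counts)
  sce$reads <- as.integer(round(tot))
  sce$genesDetected <- as.integer(Matrix::colSums(counts > 0))
  sce$housekeepingDetected <-
    as.integer(Matrix::colSums(counts[rd$is_housekeeping, , drop = FALSE] > 0))
  mito <- Matrix::colSums(counts[rd$is_mito, , drop = FALSE])
  sce$mitoFraction <- ifelse(tot > 0, mito / tot, 0)
  sce
}

#' Gene sets matching the simulated programs
#'
#' Builds the [GeneSetCollection-class] the scoring, state and GSEA stages
#' expect, from a simulated dataset's ground truth: the four state
#' meta-modules (with MES as the 100-gene union of its two 50-gene halves),
#' the two cell-cycle sets and the quiescence signature.
#'
#' @param sce a [simulateCells()] result.
#' @return A `GeneSetCollection` with sets AC, MES, MES1, MES2, NPC, OPC
#'   (category "state"), G1S, G2M ("cycle") and quiescence ("quiescence").
#' @export
defaultGeneSets <- function(sce) {
  gt <- S4Vectors::metadata(sce)$groundTruth
  if (is.null(gt)) stop("no groundTruth metadata; not a simulated dataset?")
  pg <- gt$programGenes
  GeneSetCollection(
    list(AC = pg$AC, MES = c(pg$MES1, pg$MES2), MES1 = pg$MES1,
         MES2 = pg$MES2, NPC = pg$NPC, OPC = pg$OPC, G1S = pg$G1S,
         G2M = pg$G2M, quiescence = pg$quiescence),
    category = c(rep("state", 6L), "cycle", "cycle", "quiescence"))
}
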