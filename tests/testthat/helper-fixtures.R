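# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Small planted-effect cohort: 3 lines x 2 x 300 cells.
smallWorld <- function() {
  memo("smallWorld", {
    sce <- simulateCells(ScSimParams(nPatients = 3,
                                     nCellsPerCondition = 300,
                                     seed = 101))
    logNormalize(runQC(sce, qcThresholds(minGenesOutlier = 500),
                       seed = 102))
  })
}

# Null world: no condition effects, no planted DE, no outliers.
nullParams <- function(nPatients = 1, nCells = 300, seed = 201) {
  ScSimParams(nPatients = nPatients, nCellsPerCondition = nCells,
              csfEffects = numeric(0),
              plantedDE = data.frame(gene = character(0),
                                     log2fc = numeric(0)),
              outlierFraction = 0, seed = seed)
}

nullWorld <- function() {
  memo("nullWorld", logNormalize(simulateCells(nullParams())))
}

# Full-scale stated world: 10 lines x 2 x 800 cells with the default
# planted CSF effects, QC'd and log-normalized. Built once (about 30 s).
acceptanceWorld <- function() {
  memo("acceptanceWorld", {
    sce <- simulateCells(ScSimParams(seed = 1309))
    logNormalize(runQC(sce, qcThresholds(minGenesOutlier = 500),
                       seed = 1310))
  })
}

# Tiny deterministic expression matrix for hand-checked cases.
toyMatrix <- function(nGenes = 30, nCells = 10, seed = 301) {
  withr::with_seed(seed, {
    m <- matrix(rpois(nGenes * nCells, 5), nrow = nGenes,
                dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                sprintf("c%02d", seq_len(nCells))))
    m
  })
}
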