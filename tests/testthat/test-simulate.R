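test_that("simulateCells is reproducible and annotates its ground truth", {
  p <- ScSimParams(nPatients = 2, nCellsPerCondition = 50, seed = 9)
  a <- simulateCells(p)
  b <- simulateCells(p)
  expect_identical(SummarizedExperiment::assay(a, "counts"),
                   SummarizedExperiment::assay(b, "counts"))
  expect_identical(S4Vectors::metadata(a)$groundTruth$outliers,
                   S4Vectors::metadata(b)$groundTruth$outliers)

  expect_equal(dim(a), c(2000L, 200L))
  expect_equal(as.vector(table(a$condition)), c(100L, 100L))

  rd <- SummarizedExperiment::rowData(a)
  expect_equal(sum(rd$is_mito), 13L)
  expect_equal(sum(rd$is_housekeeping), 98L)
  # program, mito and housekeeping annotations are disjoint
  expect_false(any(rd$is_mito & rd$is_housekeeping))
  expect_true(all(is.na(rd$program[rd$is_mito | rd$is_housekeeping])))
  gt <- S4Vectors::metadata(a)$groundTruth
  expect_equal(anyDuplicated(unlist(gt$programGenes)), 0L)
  expect_equal(lengths(gt$programGenes)[c("G1S", "G2M", "quiescence")],
               c(G1S = 43L, G2M = 54L, quiescence = 100L))
})

test_that("overlapping program demands are rejected by validity", {
  expect_error(ScSimParams(nGenes = 100), "too small")
  expect_error(ScSimParams(csfEffects = c(BOGUS = 1)), "unknown program")
})

test_that("a null world has exchangeable conditions", {
  sce <- nullWorld()
  de <- wilcoxonDE(sce)
  # per-gene tests reject at roughly the nominal rate
  rate <- mean(de$p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("null conditions are exchangeable under label permutation", {
  sce <- nullWorld()
  gsc <- defaultGeneSets(sce)
  s <- moduleScore(sce, gsc[["MES"]], seed = 17)
  csf <- sce$condition == "CSF"
  obs <- mean(s[csf]) - mean(s[!csf])
  perm <- withr::with_seed(18, {
    vapply(1:200, function(i) {
      lab <- sample(csf)
      mean(s[lab]) - mean(s[!lab])
    }, 0)
  })
  # the observed condition split is an ordinary member of the
  # permutation distribution
  pPerm <- (1 + sum(abs(perm) >= abs(obs))) / 201
  expect_gt(pPerm, 0.01)
  # and the distribution of per-condition scores is indistinguishable
  ks <- suppressWarnings(ks.test(s[csf], s[!csf]))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted MES shift raises the MES module score in CSF", {
  sce <- smallWorld()
  gsc <- defaultGeneSets(sce)
  s <- moduleScore(sce, gsc[["MES"]], seed = 5)
  csf <- sce$condition == "CSF"
  expect_gt(mean(s[csf]), mean(s[!csf]))
})

test_that("module-score shift grows with the planted effect", {
  diffs <- vapply(c(0.25, 0.75, 1.5), function(eff) {
    sce <- simulateCells(ScSimParams(
      nPatients = 1, nCellsPerCondition = 150,
      csfEffects = c(MES = eff),
      plantedDE = data.frame(gene = character(0), log2fc = numeric(0)),
      outlierFraction = 0, seed = 77))
    sce <- logNormalize(sce)
    gsc <- defaultGeneSets(sce)
    s <- moduleScore(sce, gsc[["MES"]], seed = 5)
    mean(s[sce$condition == "CSF"]) - mean(s[sce$condition == "GM"])
  }, 0)
  expect_true(all(diff(diffs) > 0))
})

test_that("planted outliers violate exactly the intended QC criterion", {
  sce <- memo("outlierWorld", simulateCells(
    ScSimParams(nPatients = 2, nCellsPerCondition = 200,
                outlierFraction = 0.04, seed = 55)))
  gt <- S4Vectors::metadata(sce)$groundTruth
  flags <- flagOutliers(sce, qcThresholds(minGenesOutlier = 500))
  planted <- gt$outliers
  expect_gt(nrow(planted), 0)
  hit <- flags[planted$cell, ]
  expect_true(all(hit$outlier))
  expect_true(all(mapply(grepl, planted$type, hit$reasons)))
  # no spurious flags on unplanted cells
  expect_false(any(flags$outlier[!rownames(flags) %in% planted$cell]))
})

test_that("simulatePlate realizes the configured dose-response", {
  p <- PlateSimParams(trueIC50 = 25, replicateCV = 0, seed = 4,
                      doses = c(0, 12.5, 25, 50, 100))
  plate <- simulatePlate(p)
  v <- plateViability(plate)
  ctrl <- v$viability[v$dose == 0]
  expect_equal(mean(ctrl), 100)
  # at dose = IC50 with zero noise, viability = (top + bottom) / 2
  mid <- mean(v$viability[v$dose == 25])
  expect_equal(mid, (100 + 5) / 2, tolerance = 0.01)
  expect_identical(simulatePlate(p)$nuclei_count, plate$nuclei_count)
})

test_that("simulateSpikeTrains plants detectable events", {
  st <- simulateSpikeTrains(SpikeSimParams(
    nNeurons = 3, backgroundRate = 0,
    plantedBursts = data.frame(neuron = 2, start = 10, n_spikes = 5,
                               isi = 0.05), seed = 1))
  b <- detectBursts(st)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_spikes, 5L)
  expect_equal(b$neuron, "n002")

  st2 <- simulateSpikeTrains(SpikeSimParams(
    nNeurons = 10, backgroundRate = 0,
    plantedNetworkEvents = list(list(start = 100, n_spikes = 50,
                                     isi = 0.02, neurons = 1:10)),
    seed = 2))
  ev <- detectNetworkEvents(st2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_spikes, 50L)
  expect_equal(ev$n_neurons, 10L)
  expect_error(simulateSpikeTrains(SpikeSimParams(
    nNeurons = 2, plantedBursts = data.frame(neuron = 1, start = 419,
                                             n_spikes = 5, isi = 1))),
    "outside")
})
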