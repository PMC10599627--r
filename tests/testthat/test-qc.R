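mkToySce <- function(counts, line = "L01", condition = NULL) {
  n <- ncol(counts)
  if (is.null(condition)) condition <- rep(c("GM", "CSF"), length.out = n)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("c%02d", n |> seq_len())
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    rowData = S4Vectors::DataFrame(
      symbol = rownames(counts),
      is_mito = grepl("^MT", rownames(counts)),
      is_housekeeping = grepl("^HK", rownames(counts)),
      row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(
      line = rep(line, length.out = n),
      condition = factor(condition, levels = c("GM", "CSF")),
      row.names = colnames(counts)))
}

test_that("prefilter enforces both rules to a fixed point", {
  # 6 genes x 5 cells toy; brute-force the surviving set
  m <- matrix(0, 6, 5)
  m[1:3, 1] <- 1   # cell 1: 3 genes
  m[1:2, 2] <- 1   # cell 2: 2 genes
  m[1:3, 3] <- 1
  m[4, 4] <- 1     # cell 4: 1 gene
  m[1:4, 5] <- 1
  sce <- mkToySce(m)
  th <- qcThresholds(minGenesPerCell = 3, minCellsPerGene = 3)
  out <- prefilterCells(sce, th)
  # brute force: cells 1,3,5 have >=3 genes; then genes 1:3 in >=3 cells;
  # cell 5 drops gene 4 -> still 3 genes; fixed point reached
  expect_setequal(colnames(out), c("c01", "c03", "c05"))
  expect_setequal(rownames(out), c("g01", "g02", "g03"))
  cnt <- SummarizedExperiment::assay(out, "counts")
  expect_true(all(Matrix::colSums(cnt > 0) >= 3))
  expect_true(all(Matrix::rowSums(cnt > 0) >= 3))
})

test_that("a 150-gene cell is removed by the 200-gene prefilter", {
  m <- matrix(0, 300, 2)
  m[1:150, 1] <- 1
  m[1:250, 2] <- 1
  sce <- mkToySce(m)
  out <- prefilterCells(sce, qcThresholds(minCellsPerGene = 1))
  expect_equal(colnames(out), "c02")
})

test_that("prefilter of an empty matrix warns, not errors", {
  sce <- mkToySce(matrix(0, 5, 3))
  expect_warning(out <- prefilterCells(sce), "empty")
  expect_equal(ncol(out), 0L)
})

test_that("flagOutliers applies the four criteria and per-line overrides", {
  cd <- S4Vectors::DataFrame(
    line = c("A", "MN1", "A", "A", "A"),
    condition = factor(rep("GM", 5), levels = c("GM", "CSF")),
    reads = c(60000L, 60000L, 10000L, 10000L, 10000L),
    genesDetected = c(3000L, 3000L, 3000L, 3000L, 3000L),
    housekeepingDetected = c(80L, 80L, 65L, 80L, 80L),
    mitoFraction = c(0.1, 0.1, 0.1, 0.25, 0.1),
    row.names = sprintf("c%d", 1:5))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(0, 2, 5, sparse = TRUE,
      dimnames = list(c("g1", "g2"), rownames(cd)))),
    colData = cd)
  th <- qcThresholds(maxReadsOverride = c(MN1 = 80000))
  fl <- flagOutliers(sce, th)
  expect_equal(fl$outlier, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(fl$reasons[1], "reads")
  expect_equal(fl$reasons[3], "housekeeping")  # 65 < 70 of 98
  expect_equal(fl$reasons[4], "mito")          # 0.25 > 0.20
  expect_error(flagOutliers(sce, qcThresholds(
    maxReadsOverride = c(NOPE = 1))), "unknown line")
})

test_that("tightening any threshold never un-flags a cell", {
  sce <- smallWorld()
  base <- qcThresholds(minGenesOutlier = 500)
  f0 <- flagOutliers(sce, base)
  tighter <- list(
    qcThresholds(minGenesOutlier = 500, maxReads = 30000),
    qcThresholds(minGenesOutlier = 900),
    qcThresholds(minGenesOutlier = 500, minHousekeeping = 90),
    qcThresholds(minGenesOutlier = 500, maxMitoFraction = 0.10))
  for (th in tighter) {
    f1 <- flagOutliers(sce, th)
    expect_true(all(f1$outlier[f0$outlier]))
  }
})

test_that("balanceConditions subsets to the per-line minimum", {
  m <- matrix(rpois(50 * 32, 5), 50, 32)
  sce <- mkToySce(m, line = rep(c("A", "B"), each = 16),
                  condition = c(rep("GM", 10), rep("CSF", 6),
                                rep("GM", 8), rep("CSF", 8)))
  bal <- balanceConditions(sce, seed = 1)
  tab <- table(bal$line, bal$condition)
  expect_equal(as.vector(tab["A", ]), c(6L, 6L))
  expect_equal(as.vector(tab["B", ]), c(8L, 8L))
  # already balanced input is a fixed point (counts unchanged)
  bal2 <- balanceConditions(bal, seed = 2)
  expect_equal(table(bal2$line, bal2$condition), tab)
  # determinism
  expect_identical(colnames(balanceConditions(sce, seed = 1)),
                   colnames(bal))
  # subset, never mutate
  cnt <- SummarizedExperiment::assay(bal, "counts")
  orig <- SummarizedExperiment::assay(sce, "counts")[, colnames(bal)]
  expect_identical(as.matrix(cnt), as.matrix(orig))
})

test_that("a line missing one condition is a named error", {
  m <- matrix(rpois(50 * 8, 5), 50, 8)
  sce <- mkToySce(m, line = rep(c("A", "B"), each = 4),
                  condition = c(rep("GM", 4), rep("CSF", 4)))
  expect_error(balanceConditions(sce), "A")
})
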