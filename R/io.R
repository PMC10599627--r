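#' Write / read a single-cell dataset as an MTX triplet
#'
#' `writeCellDataset` writes `matrix.mtx`, `features.tsv`, `barcodes.tsv`
#' and `cell_metadata.tsv` into a directory; `readCellDataset` loads them
#' back into a SingleCellExperiment.
#'
#' @param sce a SingleCellExperiment with a `counts` assay.
#' @param dir output directory (created if needed).
#' @return `writeCellDataset`: the directory, invisibly;
#'   `readCellDataset`: a SingleCellExperiment.
#' @export
writeCellDataset <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  rd <- as.data.frame(SummarizedExperiment::rowData(sce))
  utils::write.table(cbind(gene = rownames(sce), rd),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  utils::write.table(cbind(barcode = colnames(sce), cd),
                     file.path(dir, "cell_metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCellDataset
#' @export
readCellDataset <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  feat <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  cd <- utils::read.table(file.path(dir, "cell_metadata.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  dimnames(counts) <- list(feat$gene, barcodes)
  rowData <- S4Vectors::DataFrame(feat[setdiff(names(feat), "gene")],
                                  row.names = feat$gene)
  cd <- cd[match(barcodes, cd$barcode), ]
  colData <- S4Vectors::DataFrame(cd[setdiff(names(cd), "barcode")],
                                  row.names = barcodes)
  if ("condition" %in% colnames(colData)) {
    colData$condition <- factor(colData$condition, levels = c("GM", "CSF"))
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), rowData = rowData, colData = colData)
}

#' Write / read spike trains as a long-format CSV
#'
#' Columns: `neuron`, `well`, `timestamp` (seconds).
#'
#' @param st a [SpikeTrains-class] object.
#' @param path CSV path.
#' @param window recording window used on read (seconds).
#' @return `readSpikeCsv`: a SpikeTrains object.
#' @export
writeSpikeCsv <- function(st, path) {
  trains <- spikeTimes(st)
  df <- data.frame(
    neuron = rep(names(trains), lengths(trains)),
    well = rep(unname(wells(st)), lengths(trains)),
    timestamp = unlist(trains, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpikeCsv
#' @export
readSpikeCsv <- function(path, window = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sp <- split(df, df$neuron)
  trains <- lapply(sp, function(d) d$timestamp)
  well <- vapply(sp, function(d) d$well[1L], "")
  if (is.null(window)) window <- c(0, max(df$timestamp))
  SpikeTrains(trains, well = well, window = window)
}
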