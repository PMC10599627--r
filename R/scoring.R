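#' Global-scaling log-normalization
#'
#' Each cell's counts are divided by its total, multiplied by a scale
#' factor (10,000 by default) and natural-log transformed:
#' `value = ln(1 + scaleFactor * count / total)`. Zero counts map to zero.
#'
#' @param sce a SingleCellExperiment with a `counts` assay.
#' @param scaleFactor scaling constant (default 10,000).
#' @return The object with a `logcounts` assay added.
#' @export
logNormalize <- function(sce, scaleFactor = 10000) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    stop(sprintf("zero-total cell(s): %s (run QC first)",
                 paste(head(colnames(counts)[tot == 0], 5), collapse = ", ")))
  }
  norm <- counts
  if (is(norm, "sparseMatrix")) {
    norm@x <- log1p(scaleFactor * norm@x /
                      rep.int(tot, diff(norm@p)))
  } else {
    norm <- log1p(sweep(norm, 2L, tot, "/") * scaleFactor)
  }
  SummarizedExperiment::assay(sce, "logcounts") <- norm
  S4Vectors::metadata(sce)$scaleFactor <- scaleFactor
  sce
}

#' Select highly variable genes
#'
#' Ranks genes by a mean-binned normalized dispersion: per-gene mean and
#' dispersion (variance/mean) are computed on the back-transformed
#' normalized data, genes are cut into 20 equal-frequency mean bins, and
#' dispersions are z-scored within bin. The top `n` genes by normalized
#' dispersion are returned; ties break by gene order.
#'
#' @param sce a log-normalized SingleCellExperiment (or a genes x cells
#'   matrix of log-normalized values).
#' @param n number of genes to select (default 2,000).
#' @param nBins number of mean bins (default 20).
#' @return Character vector of gene names, ranked.
#' @export
selectHVG <- function(sce, n = 2000, nBins = 20) {
  m <- if (is(sce, "SummarizedExperiment")) {
    SummarizedExperiment::assay(sce, "logcounts")
  } else sce
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  if (nrow(m) < n) {
    warning(sprintf("only %d genes available (< n = %d); returning all",
                    nrow(m), n))
    n <- nrow(m)
  }
  e <- expm1(m)
  mu <- Matrix::rowMeans(e)
  ex2 <- Matrix::rowMeans(e * e)
  v <- (ex2 - mu^2) * ncol(m) / max(1, ncol(m) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-frequency mean bins; z-score dispersion within bin
  br <- unique(quantile(mu, probs = seq(0, 1, length.out = nBins + 1)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE)
  zd <- disp
  for (b in levels(bin)) {
    i <- which(bin == b)
    s <- sd(disp[i])
    zd[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  zd[v == 0] <- -Inf     # constant genes can never beat a varying gene
  ord <- order(-zd, seq_along(zd))
  rownames(m)[ord[seq_len(n)]]
}

# Assign genes to expression bins by their mean across cells.
# Equal-frequency binning on the rank of the mean (ties by gene order),
# so every bin is populated even with heavily tied means.
expressionBins <- function(avg, nBins) {
  r <- rank(avg, ties.method = "first")
  as.integer(cut(r, breaks = nBins, labels = FALSE, include.lowest = TRUE))
}

#' Expression-bin-matched module score
#'
#' The per-cell score of a gene program, controlling for expression level:
#' all genes are binned (24 bins by default) by their average expression
#' across cells; for each program gene, `nCtrl` control genes are sampled
#' from its bin (with replacement when the bin is smaller than `nCtrl`);
#' the score is the cell's mean expression over the program genes minus
#' its mean expression over the pooled control genes. On data with no
#' program signal the score is centered at zero.
#'
#' @param sce a log-normalized SingleCellExperiment (or matrix of
#'   log-normalized values).
#' @param genes character vector, the gene program. Genes absent from the
#'   matrix are dropped with a warning; an empty intersection is an error.
#' @param nBins number of expression bins (default 24).
#' @param nCtrl control genes sampled per program gene (default 100).
#' @param seed integer seed for control sampling.
#' @return Named numeric vector of per-cell scores.
#' @examples
#' sce <- logNormalize(simulateCells(ScSimParams(nPatients = 2,
#'   nCellsPerCondition = 50, seed = 1)))
#' gsc <- defaultGeneSets(sce)
#' s <- moduleScore(sce, gsc[["MES"]], seed = 1)
#' @export
moduleScore <- function(sce, genes, nBins = 24, nCtrl = 100, seed = NULL) {
  m <- if (is(sce, "SummarizedExperiment")) {
    SummarizedExperiment::assay(sce, "logcounts")
  } else sce
  # canonical order so the score is a function of the gene SET
  genes <- sort(unique(as.character(genes)))
  present <- genes %in% rownames(m)
  if (!any(present)) stop("none of the program genes are in the matrix")
  if (!all(present)) {
    warning(sprintf("%d program gene(s) absent from matrix; dropped",
                    sum(!present)))
    genes <- genes[present]
  }
  avg <- Matrix::rowMeans(m)
  bin <- expressionBins(avg, nBins)
  names(bin) <- rownames(m)
  ctrl <- withSeed(seed, {
    unlist(lapply(genes, function(g) {
      pool <- which(bin == bin[[g]])
      pool <- pool[rownames(m)[pool] != g]
      if (!length(pool)) return(integer(0))
      sample(pool, nCtrl, replace = length(pool) < nCtrl)
    }))
  })
  setScore <- Matrix::colMeans(m[genes, , drop = FALSE])
  # pooled control mean with multiplicity, via weights on unique genes
  u <- sort(unique(ctrl))
  wts <- tabulate(match(ctrl, u))
  ctrlScore <- as.numeric(
    Matrix::crossprod(m[u, , drop = FALSE], wts)) / length(ctrl)
  setScore - setNames(ctrlScore, colnames(m))
}

#' Score every program and derive cycling/quiescence labels
#'
#' Computes all module scores in a gene-set collection, plus the
#' proliferation score (the average of the G1S and G2M scores) and the
#' Cycling/Quiescent labels.
#'
#' @param sce a log-normalized SingleCellExperiment.
#' @param gsc a [GeneSetCollection-class]; must contain sets named `G1S`,
#'   `G2M` and `quiescence` for labels to be derived.
#' @param nBins,nCtrl see [moduleScore()].
#' @param seed integer seed; each set's control draw uses a child seed.
#' @param cyclingMode `"average"` (default; Cycling iff proliferation
#'   score >= 0) or `"max"` (Cycling iff G1S > 0 or G2M > 0). See
#'   [cycleLabels()].
#' @return A [S4Vectors::DataFrame], one row per cell, with one column per
#'   set plus `proliferation`, `cycling` and `quiescent`.
#' @export
scoreCells <- function(sce, gsc, nBins = 24, nCtrl = 100, seed = NULL,
                       cyclingMode = c("average", "max")) {
  cyclingMode <- match.arg(cyclingMode)
  scores <- lapply(seq_along(gsc), function(i) {
    moduleScore(sce, gsc[[i]], nBins = nBins, nCtrl = nCtrl,
                seed = childSeed(seed, i))
  })
  names(scores) <- names(gsc)
  st <- S4Vectors::DataFrame(scores, row.names = colnames(sce))
  if (all(c("G1S", "G2M") %in% names(gsc))) {
    st$proliferation <- (st$G1S + st$G2M) / 2
    st$cycling <- cycleLabels(st, mode = cyclingMode)$cycling
  }
  if ("quiescence" %in% names(gsc)) {
    st$quiescent <- ifelse(st$quiescence >= 0, "Quiescent", "NonQuiescent")
  }
  st
}

#' Cycling / quiescence labels from scores
#'
#' Two cycling definitions are in circulation for this analysis and both
#' are exposed: the default labels a cell Cycling iff its proliferation
#' score (mean of G1S and G2M) is >= 0; `"max"` mode labels it Cycling iff
#' G1S > 0 or G2M > 0 (under which cells with one positive and one
#' negative cycle score are Cycling). Quiescent iff quiescence score >= 0.
#'
#' @param st a data.frame/DataFrame with columns `G1S`, `G2M` (and
#'   `quiescence` if quiescent labels are wanted).
#' @param mode `"average"` or `"max"`.
#' @return A DataFrame with `cycling` (and `quiescent` when available).
#' @export
cycleLabels <- function(st, mode = c("average", "max")) {
  mode <- match.arg(mode)
  prolif <- (st$G1S + st$G2M) / 2
  cycling <- if (mode == "average") {
    ifelse(prolif >= 0, "Cycling", "NonCycling")
  } else {
    ifelse(st$G1S > 0 | st$G2M > 0, "Cycling", "NonCycling")
  }
  out <- S4Vectors::DataFrame(cycling = cycling)
  if (!is.null(st$quiescence)) {
    out$quiescent <- ifelse(st$quiescence >= 0, "Quiescent",
                            "NonQuiescent")
  }
  out
}

#' Fraction of cells expressing a gene
#'
#' @param sce a log-normalized SingleCellExperiment (or matrix).
#' @param gene gene name (must be present).
#' @param cells optional cell subset (indices or names); default all.
#' @return The fraction of the group's cells with expression > 0.
#' @export
fractionExpressing <- function(sce, gene, cells = NULL) {
  m <- if (is(sce, "SummarizedExperiment")) {
    SummarizedExperiment::assay(sce, "logcounts")
  } else sce
  if (!gene %in% rownames(m)) stop(sprintf("gene '%s' not present", gene))
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  if (!ncol(m)) stop("empty cell group")
  sum(m[gene, ] > 0) / ncol(m)
}

#' Spearman correlations between per-cell scores
#'
#' @param st a DataFrame/data.frame of numeric per-cell scores (label
#'   columns are ignored).
#' @return Symmetric matrix of Spearman rank correlations; entries
#'   involving a constant score are `NA`.
#' @export
scoreCorrelations <- function(st) {
  st <- as.data.frame(st)
  st <- st[vapply(st, is.numeric, TRUE)]
  if (nrow(st) < 3L) stop("need at least 3 cells")
  suppressWarnings(out <- cor(st, method = "spearman"))
  diag(out) <- 1
  out
}
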