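#' Balanced downsampling before differential expression
#'
#' Subsamples every line to exactly `quota` cells per condition (uniform,
#' without replacement), so the pooled CSF-vs-GM comparison is balanced
#' across patients: with 10 lines and the default quota of 700 the result
#' has 14,000 cells, 7,000 per condition.
#'
#' @param sce a SingleCellExperiment with `line` and `condition` columns.
#' @param quota cells per line per condition (default 700).
#' @param seed integer seed.
#' @return The downsampled SingleCellExperiment.
#' @export
downsampleBalanced <- function(sce, quota = 700, seed = NULL) {
  cd <- SummarizedExperiment::colData(sce)
  tab <- table(cd$line, cd$condition)
  short <- which(tab < quota, arr.ind = TRUE)
  if (nrow(short)) {
    stop(sprintf(
      "line(s) below the %d-cell quota: %s", quota,
      paste(sprintf("%s/%s=%d", rownames(tab)[short[, 1]],
                    colnames(tab)[short[, 2]], tab[short]),
            collapse = ", ")))
  }
  withSeed(seed, {
    keep <- unlist(lapply(rownames(tab), function(ln) {
      unlist(lapply(colnames(tab), function(cond) {
        idx <- which(cd$line == ln & cd$condition == cond)
        if (length(idx) > quota) sort(sample(idx, quota)) else idx
      }))
    }))
    sce[, sort(keep)]
  })
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(n1+n2, n1) group assignments of the pooled ranks. Handles ties
# (the permutation distribution conditions on the observed values).
wilcoxExactP <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  sums <- colSums(matrix(r[combs], nrow = n1))
  mu <- n1 * (n + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Normal-approximation two-sided p with tie correction (no continuity
# correction), vectorized over genes. ranksum = sum of group-1 ranks.
wilcoxNormalP <- function(ranksum, n1, n2, tieCorrection) {
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tieCorrection / (n * (n - 1)))
  z <- (ranksum - mu) / sqrt(pmax(sigma2, .Machine$double.eps))
  pmin(1, 2 * pnorm(-abs(z)))
}

#' Wilcoxon rank-sum differential expression (CSF vs GM)
#'
#' Per-gene two-sided rank-sum test on log-normalized expression between
#' the two conditions, with Bonferroni correction over all tested genes.
#' Group sizes of 8 or fewer use exact enumeration of the permutation
#' distribution; larger groups use the normal approximation with tie
#' correction. The log2 fold change back-transforms the log-normalized
#' values: `log2(mean(expm1(x_CSF)) + 1) - log2(mean(expm1(x_GM)) + 1)`.
#'
#' @param sce a log-normalized SingleCellExperiment with a binary
#'   `condition` column (levels GM, CSF), or a matrix plus `condition`.
#' @param condition optional condition vector when `sce` is a matrix.
#' @param exactMax largest group size for the exact-enumeration branch.
#' @return data.frame (one row per gene): `gene`, `avg_log2FC` (positive =
#'   up in CSF), `pct_csf`, `pct_gm` (expressing fractions), `p`, `p_adj`
#'   (Bonferroni), `rank_score` = sign(avg_log2FC) * -log10(p_adj).
#'   `attr(, "nTested")`, `attr(, "nPerGroup")` record the test universe.
#' @export
wilcoxonDE <- function(sce, condition = NULL, exactMax = 8) {
  if (is(sce, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(sce, "logcounts")
    condition <- sce$condition
  } else m <- sce
  condition <- as.character(condition)
  stopifnot(all(condition %in% c("GM", "CSF")))
  isCsf <- condition == "CSF"
  n1 <- sum(isCsf); n2 <- sum(!isCsf)
  if (min(n1, n2) < 3L) stop("each group needs at least 3 cells")
  m <- as.matrix(m)

  csf <- m[, isCsf, drop = FALSE]
  gm <- m[, !isCsf, drop = FALSE]
  meanExpCsf <- rowMeans(expm1(csf))
  meanExpGm <- rowMeans(expm1(gm))
  l2fc <- log2(meanExpCsf + 1) - log2(meanExpGm + 1)

  if (max(n1, n2) <= exactMax) {
    p <- vapply(seq_len(nrow(m)), function(g) {
      wilcoxExactP(csf[g, ], gm[g, ])
    }, 0)
  } else {
    ranksum <- numeric(nrow(m))
    tieCorr <- numeric(nrow(m))
    for (g in seq_len(nrow(m))) {
      x <- m[g, ]
      r <- rank(x)
      ranksum[g] <- sum(r[isCsf])
      t <- tabulate(match(x, x))
      tieCorr[g] <- sum(t^3 - t)
    }
    p <- wilcoxNormalP(ranksum, n1, n2, tieCorr)
  }
  pAdj <- pmin(1, p * nrow(m))
  out <- data.frame(
    gene = rownames(m), avg_log2FC = l2fc,
    pct_csf = rowMeans(csf > 0), pct_gm = rowMeans(gm > 0),
    p = p, p_adj = pAdj,
    rank_score = sign(l2fc) * -log10(pmax(pAdj, .Machine$double.xmin)),
    stringsAsFactors = FALSE)
  rownames(out) <- out$gene
  attr(out, "nTested") <- nrow(m)
  attr(out, "nPerGroup") <- c(CSF = n1, GM = n2)
  out
}

#' Top differentially expressed genes per condition
#'
#' @param det a [wilcoxonDE()] table.
#' @param k genes per direction (default 20).
#' @return list with `csf` (top-k by avg_log2FC, descending: up in CSF)
#'   and `gm` (top-k ascending: up in GM); ties break by gene id.
#' @export
topMarkers <- function(det, k = 20) {
  if (k > nrow(det)) {
    warning(sprintf("k = %d exceeds %d genes; returning all", k,
                    nrow(det)))
    k <- nrow(det)
  }
  up <- det$gene[order(-det$avg_log2FC, det$gene)]
  dn <- det$gene[order(det$avg_log2FC, det$gene)]
  list(csf = up[seq_len(k)], gm = dn[seq_len(k)])
}

#' Ranked gene list for preranked GSEA
#'
#' Orders genes by `rank_score = sign(avg_log2FC) * -log10(p_adj)`,
#' descending, ties broken by gene id (so highly expressed CSF genes rank
#' first and highly expressed GM genes last).
#'
#' @param det a [wilcoxonDE()] table.
#' @return Named numeric vector of rank scores, sorted descending.
#' @export
rankGenes <- function(det) {
  ord <- order(-det$rank_score, det$gene)
  setNames(det$rank_score[ord], det$gene[ord])
}
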