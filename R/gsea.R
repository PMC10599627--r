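#' Read / write GMT gene-set files
#'
#' GMT is tab-separated: set name, description, then one gene per field.
#'
#' @param path file path.
#' @param category category label(s) for the sets read (recycled).
#' @return `readGmt`: a [GeneSetCollection-class].
#' @export
readGmt <- function(path, category = "custom") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(ln, 1, 40))
    sets[[f[1L]]] <- f[-(1:2)][nzchar(f[-(1:2)])]
  }
  GeneSetCollection(sets, category = category)
}

#' @rdname readGmt
#' @param gsc a [GeneSetCollection-class] to write.
#' @export
writeGmt <- function(gsc, path) {
  lines <- vapply(seq_along(gsc), function(i) {
    paste(c(names(gsc)[i], setCategories(gsc)[i], gsc[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write RNK ranked-list files
#'
#' Two-column tab-separated (gene, rank score). On read the list is sorted
#' by score descending with ties broken by gene id.
#'
#' @param path file path.
#' @return `readRnk`: named numeric vector sorted descending.
#' @export
readRnk <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene", "score"),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene)) stop("duplicate genes in rank file")
  ord <- order(-df$score, df$gene)
  setNames(df$score[ord], df$gene[ord])
}

#' @rdname readRnk
#' @param ranks named numeric vector of rank scores.
#' @export
writeRnk <- function(ranks, path) {
  utils::write.table(
    data.frame(gene = names(ranks), score = unname(ranks)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Order a rank vector descending with deterministic gene-id tie-break.
orderRanks <- function(ranks) {
  ord <- order(-ranks, names(ranks))
  ranks[ord]
}

# Weighted KS-style enrichment score from hit positions.
# pos: sorted positions of set genes in the ranked list; absr: |r|^p for
# the whole list; N: list length. The running sum is piecewise linear in
# the miss penalty between hits, so its extremes occur immediately before
# or at each hit; this evaluates only those 2*NH candidate points.
esFromPositions <- function(pos, absr, N) {
  NH <- length(pos)
  NR <- sum(absr[pos])
  if (NR == 0) stop("degenerate ranks: all set genes have zero rank score")
  miss <- 1 / (N - NH)
  hitCum <- cumsum(absr[pos]) / NR
  missBefore <- (pos - seq_len(NH)) * miss     # misses strictly before hit i
  atHit <- hitCum - missBefore                 # running sum just after hit i
  beforeHit <- c(0, hitCum[-NH]) - missBefore  # just before hit i
  # between hits the sum only decreases, so extremes occur just after a
  # hit (maxima) or just before one (minima); the end value is always 0
  cand <- c(atHit, beforeHit)
  unname(cand[which.max(abs(cand))])
}

#' Weighted enrichment score of a gene set on a ranked list
#'
#' Walks the ranked list accumulating `|r|^p / NR` at set genes (hits) and
#' subtracting `1/(N - NH)` at misses, where `NR` is the sum of `|r|^p`
#' over the set; the enrichment score (ES) is the running sum's maximum
#' deviation from zero, signed. With the default weight `p = 1` this is
#' the classic "weighted" statistic; the ES is invariant to rescaling all
#' rank scores.
#'
#' @param ranks named numeric vector (rank scores); sorted internally
#'   (descending, gene-id tie-break).
#' @param set character vector of set genes (genes absent from the list
#'   are ignored; empty intersection is an error).
#' @param p hit weight exponent (default 1).
#' @param details if `TRUE`, also return the full running sum and leading
#'   edge.
#' @return The ES (numeric in \[-1, 1\]); with `details = TRUE`, a list
#'   with `ES`, `runningSum` (length N), and `leadingEdge` (set genes at
#'   or before the extremum for positive ES; at or after it for negative
#'   ES).
#' @export
enrichmentScore <- function(ranks, set, p = 1, details = FALSE) {
  ranks <- orderRanks(ranks)
  N <- length(ranks)
  hit <- names(ranks) %in% set
  NH <- sum(hit)
  if (NH == 0L) stop("gene set has no genes in the ranked list")
  if (NH == N) stop("gene set covers the whole ranked list")
  absr <- abs(ranks)^p
  if (!details) return(esFromPositions(which(hit), absr, N))
  NR <- sum(absr[hit])
  if (NR == 0) stop("degenerate ranks: all set genes have zero rank score")
  inc <- ifelse(hit, absr / NR, -1 / (N - NH))
  rs <- cumsum(inc)
  i <- which.max(abs(rs))
  es <- unname(rs[i])
  leading <- if (es >= 0) {
    names(ranks)[hit & seq_len(N) <= i]
  } else {
    names(ranks)[hit & seq_len(N) >= i]
  }
  list(ES = es, runningSum = unname(rs), leadingEdge = leading)
}

#' Preranked GSEA with gene-set permutations
#'
#' For each gene set: the observed weighted ES; a null distribution of ES
#' values from `nPerm` random same-size gene sets drawn from the ranked
#' genes; NES by mean-division normalization (ES divided by the mean |ES|
#' of same-sign null values); a permutation p-value with the add-one
#' estimator `p = (1 + #{same-sign null |ES| >= |ES|}) / (1 + #same-sign
#' nulls)`; and an FDR q-value. With two or more sets, q uses the pooled
#' normalized-null procedure (the fraction of pooled same-sign null NES at
#' least as extreme, divided by the fraction of observed same-sign NES at
#' least as extreme, capped at 1 and monotonized); a single set falls back
#' to q = p.
#'
#' @param ranks named numeric rank vector (see [rankGenes()]).
#' @param gsc a [GeneSetCollection-class] (or named list of gene sets).
#' @param nPerm number of gene-set permutations (default 1000).
#' @param p hit weight exponent (default 1, "weighted").
#' @param seed integer seed.
#' @return data.frame (one row per set): `set`, `size` (genes in list),
#'   `ES`, `NES`, `p_perm`, `FDR_q`, `leading_edge` (comma-separated).
#' @examples
#' ranks <- setNames(seq(3, -3, length.out = 50), sprintf("g%02d", 1:50))
#' gseaPreranked(ranks, list(top = sprintf("g%02d", 1:5)), nPerm = 100,
#'               seed = 1)
#' @export
gseaPreranked <- function(ranks, gsc, nPerm = 1000, p = 1, seed = NULL) {
  sets <- if (is(gsc, "GeneSetCollection")) geneSets(gsc) else gsc
  ranks <- orderRanks(ranks)
  N <- length(ranks)
  absr <- abs(ranks)^p
  genes <- names(ranks)

  obs <- lapply(sets, function(s) {
    enrichmentScore(ranks, s, p = p, details = TRUE)
  })
  es <- vapply(obs, `[[`, 0, "ES")
  sizes <- vapply(sets, function(s) sum(genes %in% s), 0L)

  nulls <- withSeed(seed, {
    lapply(sizes, function(k) {
      vapply(seq_len(nPerm), function(i) {
        pos <- sort(sample.int(N, k))
        # a null set landing entirely on zero-weight genes carries no
        # signal; its ES is the zero-weight limit
        if (sum(absr[pos]) == 0) 0 else esFromPositions(pos, absr, N)
      }, 0)
    })
  })

  nes <- pPerm <- numeric(length(sets))
  nullNes <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    nl <- nulls[[i]]
    same <- nl[sign(nl) == sign(es[i]) | es[i] == 0]
    if (!length(same)) {
      warning(sprintf("set '%s': no same-sign null ES; p at floor",
                      names(sets)[i]))
      pPerm[i] <- 1 / (nPerm + 1)
      nes[i] <- sign(es[i]) * abs(es[i]) / max(abs(nl), .Machine$double.eps)
    } else {
      pPerm[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
      nes[i] <- es[i] / mean(abs(same))
    }
    # meandiv-normalize the null itself (for pooled FDR)
    posMean <- mean(nl[nl >= 0]); negMean <- mean(abs(nl[nl < 0]))
    nn <- nl
    nn[nl >= 0] <- if (is.finite(posMean) && posMean > 0) {
      nl[nl >= 0] / posMean
    } else 0
    nn[nl < 0] <- if (is.finite(negMean) && negMean > 0) {
      nl[nl < 0] / negMean
    } else 0
    nullNes[[i]] <- nn
  }

  fdr <- if (length(sets) >= 2L) {
    pooled <- unlist(nullNes)
    vapply(seq_along(sets), function(i) {
      if (nes[i] >= 0) {
        num <- mean(pooled[pooled >= 0] >= nes[i])
        den <- mean(nes[nes >= 0] >= nes[i])
      } else {
        num <- mean(pooled[pooled < 0] <= nes[i])
        den <- mean(nes[nes < 0] <= nes[i])
      }
      if (!is.finite(num) || !is.finite(den) || den == 0) return(1)
      min(1, num / den)
    }, 0)
  } else {
    pPerm
  }

  data.frame(
    set = names(sets), size = as.integer(sizes), ES = es, NES = nes,
    p_perm = pPerm, FDR_q = fdr,
    leading_edge = vapply(obs, function(o) {
      paste(o$leadingEdge, collapse = ",")
    }, ""),
    row.names = NULL, stringsAsFactors = FALSE)
}
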