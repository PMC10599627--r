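# Independent brute-force oracles used across the suite. These re-derive
# each statistic from its definition by a different route than the package
# implementation.

# Exhaustive two-sided rank-sum p: enumerate every assignment of the pooled
# observations to group 1 and count assignments whose rank-sum deviates
# from its mean at least as much as the observed one.
oracleWilcoxP <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  n <- length(pool)
  r <- rank(pool)
  mu <- n1 * (n + 1) / 2
  obsDev <- abs(sum(r[seq_len(n1)]) - mu)
  hits <- 0L
  total <- 0L
  idx <- utils::combn(n, n1)
  for (j in seq_len(ncol(idx))) {
    dev <- abs(sum(r[idx[, j]]) - mu)
    if (dev >= obsDev - 1e-9) hits <- hits + 1L
    total <- total + 1L
  }
  hits / total
}

# Full running-sum GSEA enrichment score: literal walk over the whole
# ranked list.
oracleES <- function(ranks, set, p = 1) {
  ord <- order(-ranks, names(ranks))
  ranks <- ranks[ord]
  hit <- names(ranks) %in% set
  NR <- sum(abs(ranks[hit])^p)
  NH <- sum(hit)
  N <- length(ranks)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) abs(ranks[i])^p / NR else -1 / (N - NH)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Sliding-scan burst oracle: for a sorted timestamp vector, scan every
# starting spike and grow the longest window with all gaps <= maxIsi;
# emit maximal, disjoint runs of >= minSpikes.
oracleBursts <- function(ts, minSpikes, maxIsi) {
  n <- length(ts)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && ts[j + 1L] - ts[j] <= maxIsi) j <- j + 1L
    if (j - i + 1L >= minSpikes) {
      out[[length(out) + 1L]] <- c(start = ts[i], end = ts[j],
                                   n_spikes = j - i + 1L)
    }
    i <- j + 1L
  }
  if (!length(out)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = numeric(0)))
  }
  as.data.frame(do.call(rbind, out))
}

# Hand 4PL curve for constructing noiseless fixtures.
oracle4PL <- function(d, top, bottom, ic50, hill) {
  ifelse(d <= 0, top, bottom + (top - bottom) / (1 + (d / ic50)^hill))
}
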