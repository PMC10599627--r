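#' Meta-module scores for the four glioblastoma states
#'
#' Thin wrapper over [moduleScore()] that computes the AC-like, MES-like
#' (100-gene combined list), MES1/MES2 (50-gene halves), NPC-like and
#' OPC-like scores a state projection needs.
#'
#' @param sce a log-normalized SingleCellExperiment.
#' @param gsc a [GeneSetCollection-class] containing sets `AC`, `MES`,
#'   `MES1`, `MES2`, `NPC`, `OPC`.
#' @param nBins,nCtrl,seed see [moduleScore()].
#' @return DataFrame of the six per-cell scores.
#' @export
metaModuleScores <- function(sce, gsc, nBins = 24, nCtrl = 100,
                             seed = NULL) {
  need <- c("AC", "MES", "MES1", "MES2", "NPC", "OPC")
  missing <- setdiff(need, names(gsc))
  if (length(missing)) {
    stop(sprintf("gene set(s) missing from collection: %s",
                 paste(missing, collapse = ", ")))
  }
  scores <- lapply(seq_along(need), function(i) {
    moduleScore(sce, gsc[[need[i]]], nBins = nBins, nCtrl = nCtrl,
                seed = childSeed(seed, i))
  })
  names(scores) <- need
  S4Vectors::DataFrame(scores, row.names = colnames(sce))
}

signedLog2 <- function(d) sign(d) * log2(abs(d) + 1)

#' Two-axis cell-state projection and quadrant classification
#'
#' Places each cell on the butterfly-style state plot and assigns one of
#' the four states by quadrant: AC-like (x<0, y<0), MES-like (x>0, y<0),
#' NPC-like (x>0, y>0), OPC-like (x<0, y>0).
#'
#' Three modes are provided:
#' \describe{
#'   \item{`corrected` (default)}{`D = max(OPC, NPC) - max(AC, MES)`;
#'     `y = sign(D) * log2(|D| + 1)`; for `D > 0`,
#'     `x = sign(NPC - OPC) * log2(|NPC - OPC| + 1)`, otherwise
#'     `x = sign(MES - AC) * log2(|MES - AC| + 1)`. This realizes the
#'     quadrant semantics above: a cell's dominant score determines its
#'     quadrant.}
#'   \item{`as_written`}{the formulas exactly as printed in the source
#'     methods text: for `D1 = max(OPC, NPC) - max(AC, MES) > 0`,
#'     `y = log2((OPC - NPC) + 1)`, else `y = -log2((AC - MES) + 1)`; for
#'     `D2 = max(AC, OPC) - max(MES, NPC) < 0`,
#'     `x = -log2((AC - OPC) + 1)`, else `x = log2((MES - NPC) + 1)`.
#'     These formulas can take the log of a non-positive argument (such
#'     cells are flagged `undefined` and excluded from composition) and
#'     misplace some dominant-score cells; the mode is retained for
#'     audit.}
#'   \item{`argmax`}{state = the largest of the four scores; x, y from the
#'     corrected formulas.}
#' }
#' Boundary cells (x = 0 or y = 0) cannot be placed in an open quadrant
#' and fall back to the argmax state; they are counted separately.
#'
#' @param scores DataFrame/data.frame with numeric columns `AC`, `MES`,
#'   `NPC`, `OPC`.
#' @param mode `"corrected"`, `"as_written"` or `"argmax"`.
#' @return A DataFrame with `x`, `y`, `D1`, `D2`, `state` (factor,
#'   `NA` for undefined cells), `boundary`, `undefined`; the mode is in
#'   `metadata(result)$mode`.
#' @examples
#' sc <- data.frame(AC = 0.8, MES = 0.1, NPC = 0.1, OPC = 0.1)
#' projectStates(sc)$state
#' @export
projectStates <- function(scores,
                          mode = c("corrected", "as_written", "argmax")) {
  mode <- match.arg(mode)
  sc <- as.data.frame(scores)[c("AC", "MES", "NPC", "OPC")]
  AC <- sc$AC; MES <- sc$MES; NPC <- sc$NPC; OPC <- sc$OPC
  D1 <- pmax(OPC, NPC) - pmax(AC, MES)
  D2 <- pmax(AC, OPC) - pmax(MES, NPC)
  undefined <- rep(FALSE, nrow(sc))

  if (mode == "as_written") {
    yArg <- ifelse(D1 > 0, (OPC - NPC) + 1, (AC - MES) + 1)
    xArg <- ifelse(D2 < 0, (AC - OPC) + 1, (MES - NPC) + 1)
    undefined <- yArg <= 0 | xArg <= 0
    y <- ifelse(D1 > 0, log2(pmax(yArg, .Machine$double.xmin)),
                -log2(pmax(yArg, .Machine$double.xmin)))
    x <- ifelse(D2 < 0, -log2(pmax(xArg, .Machine$double.xmin)),
                log2(pmax(xArg, .Machine$double.xmin)))
    y[undefined] <- NA_real_
    x[undefined] <- NA_real_
  } else {
    y <- signedLog2(D1)
    x <- ifelse(D1 > 0, signedLog2(NPC - OPC), signedLog2(MES - AC))
  }

  amax <- c("AC", "MES", "NPC", "OPC")[max.col(sc, ties.method = "first")]
  state <- rep(NA_character_, nrow(sc))
  boundary <- rep(FALSE, nrow(sc))
  if (mode == "argmax") {
    state <- amax
  } else {
    ok <- !undefined
    state[ok & x < 0 & y < 0] <- "AC"
    state[ok & x > 0 & y < 0] <- "MES"
    state[ok & x > 0 & y > 0] <- "NPC"
    state[ok & x < 0 & y > 0] <- "OPC"
    boundary <- ok & (x == 0 | y == 0)
    # corrected mode resolves boundary cells by argmax; as_written keeps
    # them unclassified so its documented misplacements stay visible
    if (mode == "corrected") state[boundary] <- amax[boundary]
  }
  out <- S4Vectors::DataFrame(
    x = x, y = y, D1 = D1, D2 = D2,
    state = factor(state, levels = c("AC", "MES", "NPC", "OPC")),
    boundary = boundary, undefined = undefined,
    row.names = rownames(scores))
  S4Vectors::metadata(out)$mode <- mode
  out
}

#' Per-line, per-condition state composition
#'
#' @param assignment a [projectStates()] result.
#' @param line,condition vectors parallel to the assignment rows.
#' @return data.frame with one row per line x condition x state:
#'   `n` cells and `proportion` (summing to 1 over classified cells within
#'   each line x condition); unclassified (undefined-projection) cells are
#'   excluded and their count reported in `attr(, "nUnclassified")`.
#' @export
stateComposition <- function(assignment, line, condition) {
  ok <- !is.na(assignment$state)
  if (!any(ok)) stop("no classified cells")
  grp <- interaction(line, condition, drop = FALSE)
  if (any(table(grp[ok]) == 0)) stop("empty line x condition group")
  tab <- table(line = line[ok], condition = condition[ok],
               state = assignment$state[ok])
  df <- as.data.frame(tab, responseName = "n")
  tot <- as.data.frame(table(line = line[ok], condition = condition[ok]),
                       responseName = "total")
  df <- merge(df, tot, by = c("line", "condition"))
  df$proportion <- ifelse(df$total > 0, df$n / df$total, NA_real_)
  df$total <- NULL
  df <- df[order(df$line, df$condition, df$state), ]
  rownames(df) <- NULL
  attr(df, "nUnclassified") <- sum(!ok)
  df
}
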