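#' Well viability from nuclei counts
#'
#' Normalizes each treated well's nuclei count to the mean of its paired
#' vehicle-control wells:
#' `viability = 100 * count / mean(counts of paired controls)`.
#' Control wells are normalized to their own group mean, so they average
#' 100% by construction.
#'
#' @param plate a data.frame with columns `well`, `line`, `condition`,
#'   `treatment`, `dose`, `nuclei_count`, `control_group` (wells with
#'   `treatment == "vehicle"` or `dose == 0` form the control group).
#' @return The plate table with a `viability` column (percent).
#' @export
plateViability <- function(plate) {
  isCtrl <- plate$treatment == "vehicle" | plate$dose == 0
  ctrlMeans <- tapply(plate$nuclei_count[isCtrl],
                      plate$control_group[isCtrl], mean)
  missing <- setdiff(unique(plate$control_group), names(ctrlMeans))
  if (length(missing)) {
    stop(sprintf("no control wells for group(s): %s",
                 paste(missing, collapse = ", ")))
  }
  cm <- ctrlMeans[plate$control_group]
  if (any(cm == 0)) {
    stop(sprintf("zero control mean in group(s): %s",
                 paste(unique(plate$control_group[cm == 0]),
                       collapse = ", ")))
  }
  plate$viability <- 100 * plate$nuclei_count / as.numeric(cm)
  plate
}

#' Mean viability per line and condition
#'
#' @param plate a [plateViability()] result.
#' @param treatedOnly summarize treated wells only (default TRUE).
#' @return data.frame with `line`, `condition`, `mean_viability`, `sem`,
#'   `n_wells`.
#' @export
summarizeViability <- function(plate, treatedOnly = TRUE) {
  if (treatedOnly) {
    plate <- plate[!(plate$treatment == "vehicle" | plate$dose == 0), ]
  }
  agg <- aggregate(viability ~ line + condition, plate, function(v) {
    c(mean = mean(v), sem = sd(v) / sqrt(length(v)), n = length(v))
  })
  data.frame(line = agg$line, condition = agg$condition,
             mean_viability = agg$viability[, "mean"],
             sem = agg$viability[, "sem"],
             n_wells = as.integer(agg$viability[, "n"]))
}

#' Stratify lines by treatment responsiveness
#'
#' Labels each line responsive / moderate / unresponsive from its mean
#' viability and two cutpoints. Matching the printed interval conventions
#' ("<50%", "50 to 90%", ">90%"), boundary values go to the
#' lower-resistance class: viability < low is responsive, low <= v <= high
#' is moderate, v > high is unresponsive. Presets: temozolomide and
#' trifluoperazine use (50, 90); irradiation and combination treatment use
#' (50, 75).
#'
#' @param meanViability named numeric vector (or
#'   [summarizeViability()] data.frame) of per-line mean viabilities
#'   (percent).
#' @param cutpoints numeric(2), increasing (default `c(50, 90)`).
#' @return factor of labels (`responsive`, `moderate`, `unresponsive`),
#'   named by line.
#' @export
stratifyResponsiveness <- function(meanViability, cutpoints = c(50, 90)) {
  if (is.data.frame(meanViability)) {
    meanViability <- setNames(meanViability$mean_viability,
                              meanViability$line)
  }
  if (length(cutpoints) != 2L || diff(cutpoints) <= 0) {
    stop("cutpoints must be two increasing values")
  }
  lab <- ifelse(meanViability < cutpoints[1L], "responsive",
                ifelse(meanViability <= cutpoints[2L], "moderate",
                       "unresponsive"))
  factor(setNames(lab, names(meanViability)),
         levels = c("responsive", "moderate", "unresponsive"))
}

#' CSF-vs-GM resistance fold change
#'
#' Normalizes each line's viability in both conditions to the mean
#' population survival in GM, then reports the ratio of the normalized
#' values (CSF over GM) per line.
#'
#' @param viabGM,viabCSF named numeric vectors of per-line mean viability
#'   (percent) under the same treatment in GM and CSF.
#' @return data.frame with `line`, `norm_gm`, `norm_csf`, `fold_change`.
#' @export
resistanceFoldChange <- function(viabGM, viabCSF) {
  lines <- intersect(names(viabGM), names(viabCSF))
  if (!length(lines)) stop("no lines measured in both conditions")
  popGM <- mean(viabGM[lines])
  if (popGM == 0 || any(viabGM[lines] == 0)) {
    stop("zero GM survival; fold change undefined")
  }
  normGM <- viabGM[lines] / popGM
  normCSF <- viabCSF[lines] / popGM
  data.frame(line = lines, norm_gm = unname(normGM),
             norm_csf = unname(normCSF),
             fold_change = unname(normCSF / normGM))
}

#' Four-parameter logistic dose-response fit
#'
#' Least-squares fit of
#' `v(d) = bottom + (top - bottom) / (1 + (d / IC50)^hill)`.
#' Initialization: top/bottom from the lowest/highest-dose means, IC50
#' from the log-dose midpoint crossing, hill = 1; IC50 is bounded
#' positive. Falls back from `nls` (port) to Nelder-Mead if needed; a
#' non-converged or non-inhibitory fit is flagged, never an exception.
#'
#' @param dose,viability numeric vectors (dose in micromolar, viability in
#'   percent); dose-0 wells anchor the top asymptote.
#' @return list of class `DoseResponseFit`: `top`, `bottom`, `ic50`,
#'   `hill`, `rss`, `converged`, `reliable` (FALSE when the fitted curve
#'   is non-inhibitory or IC50 lies far outside the dose range).
#' @examples
#' d <- rep(c(0, 12.5, 25, 50, 100), each = 3)
#' v <- 5 + 95 / (1 + (d / 25)^1.5)
#' fit4PL(d, v)$ic50
#' @export
fit4PL <- function(dose, viability) {
  keep <- is.finite(dose) & is.finite(viability)
  dose <- dose[keep]; viability <- viability[keep]
  if (length(unique(dose)) < 4L) stop("need at least 4 distinct doses")
  doseMeans <- tapply(viability, dose, mean)
  ds <- as.numeric(names(doseMeans))
  topInit <- doseMeans[[which.min(ds)]]
  botInit <- min(doseMeans[[which.max(ds)]], topInit - 1e-6)
  half <- (topInit + botInit) / 2
  posD <- ds[ds > 0]
  below <- posD[doseMeans[as.character(posD)] <= half]
  ic50Init <- if (length(below)) {
    exp((log(min(below)) + log(max(posD[posD <= min(below)], min(posD)))) / 2)
  } else exp(mean(log(range(posD))))
  df <- data.frame(d = dose, v = viability)
  fit <- tryCatch(
    nls(v ~ bottom + (top - bottom) / (1 + (d / ic50)^hill), data = df,
        start = list(top = topInit, bottom = botInit, ic50 = ic50Init,
                     hill = 1),
        lower = c(top = -Inf, bottom = -Inf, ic50 = 1e-9, hill = -Inf),
        algorithm = "port",
        control = nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    out <- list(top = cf[["top"]], bottom = cf[["bottom"]],
                ic50 = cf[["ic50"]], hill = cf[["hill"]],
                rss = sum(resid(fit)^2), converged = TRUE)
  } else {
    obj <- function(par) {
      pred <- par[2] + (par[1] - par[2]) /
        (1 + (dose / exp(par[3]))^par[4])
      sum((viability - pred)^2)
    }
    op <- optim(c(topInit, botInit, log(ic50Init), 1), obj,
                control = list(maxit = 2000))
    out <- list(top = op$par[1], bottom = op$par[2],
                ic50 = exp(op$par[3]), hill = op$par[4], rss = op$value,
                converged = op$convergence == 0)
  }
  span <- out$top - out$bottom
  out$reliable <- out$converged && span > 0 && out$hill > 0 &&
    out$ic50 > 0 && out$ic50 <= 100 * max(dose)
  class(out) <- "DoseResponseFit"
  out
}

#' @export
print.DoseResponseFit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: IC50 = %.4g, hill = %.3g, top = %.4g, bottom = %.4g\n",
    x$ic50, x$hill, x$top, x$bottom))
  cat(sprintf("  RSS = %.4g; converged: %s; reliable: %s\n", x$rss,
              x$converged, x$reliable))
  invisible(x)
}

#' Comparative-CT qPCR quantitation
#'
#' `deltaCt = Ct_target - Ct_reference` per sample; `deltaDeltaCt =
#' mean(deltaCt, group) - mean(deltaCt, control group)`; fold change =
#' `2^(-deltaDeltaCt)`. The reference gene models a stable housekeeping
#' normalizer (TATA-binding protein in the assays this reproduces).
#'
#' @param ct data.frame with columns `sample`, `group`, `gene`, `ct`.
#' @param target,reference gene names.
#' @param group,controlGroup group labels to compare.
#' @return list: `fold` (2^-ddCt), `ddct`, `dct_group`, `dct_control`.
#' @export
ddct <- function(ct, target, reference, group, controlGroup) {
  if (!reference %in% ct$gene) {
    stop(sprintf("reference gene '%s' missing", reference))
  }
  if (!target %in% ct$gene) {
    stop(sprintf("target gene '%s' missing", target))
  }
  if (any(!is.finite(ct$ct))) stop("non-finite CT values")
  dctPerSample <- function(g) {
    sub <- ct[ct$group == g, ]
    tgt <- sub[sub$gene == target, ]
    ref <- sub[sub$gene == reference, ]
    m <- merge(tgt[c("sample", "ct")], ref[c("sample", "ct")],
               by = "sample", suffixes = c("_t", "_r"))
    if (!nrow(m)) stop(sprintf("group '%s' lacks paired target/reference", g))
    m$ct_t - m$ct_r
  }
  dg <- mean(dctPerSample(group))
  dc <- mean(dctPerSample(controlGroup))
  dd <- dg - dc
  list(fold = 2^(-dd), ddct = dd, dct_group = dg, dct_control = dc)
}
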