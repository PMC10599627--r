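# rolling mean over a centered window of k samples (k odd), edges padded
# by shrinking the window.
rollMean <- function(x, k) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect spikes on a voltage trace
#'
#' Adaptive thresholding at `thresholdSD` standard deviations above the
#' local mean background noise: a rolling window (10 ms by default)
#' estimates mean and SD; a spike is recorded at each upward threshold
#' crossing, with a refractory hold-off suppressing re-triggers. The
#' 6-SD default reflects the acquisition convention this pipeline models;
#' window and hold-off are exposed because the vendor values are not
#' public. Detection is invariant to rescaling the trace.
#'
#' @param trace numeric voltage trace.
#' @param samplingRate samples per second (e.g. 12,500).
#' @param thresholdSD threshold in noise SDs (default 6).
#' @param noiseWindow rolling-noise window in seconds (default 0.010).
#' @param refractory hold-off in seconds (default 0.001).
#' @return Sorted numeric vector of spike times (seconds); empty trace
#'   gives an empty result.
#' @export
detectSpikes <- function(trace, samplingRate, thresholdSD = 6,
                         noiseWindow = 0.010, refractory = 0.001) {
  n <- length(trace)
  if (!n) return(numeric(0))
  stopifnot(all(is.finite(trace)))
  k <- max(3L, 2L * floor(noiseWindow * samplingRate / 2) + 1L)
  # background-noise stats from a spike-clipped copy of the trace, so
  # large deflections do not inflate their own threshold
  med <- median(trace)
  spread <- mad(trace)
  if (spread == 0) spread <- sd(trace)
  if (is.na(spread) || spread == 0) spread <- 1
  clipped <- pmin(pmax(trace, med - 4 * spread), med + 4 * spread)
  mu <- rollMean(clipped, k)
  m2 <- rollMean(clipped^2, k)
  sdv <- sqrt(pmax(m2 - mu^2, 0))
  globalSd <- sd(trace)
  sdv[sdv == 0] <- if (is.na(globalSd) || globalSd == 0) 1 else globalSd
  thr <- mu + thresholdSD * sdv
  above <- trace > thr
  crossing <- which(above & !c(FALSE, above[-n]))
  if (!length(crossing)) return(numeric(0))
  holdoff <- refractory * samplingRate
  keep <- crossing[1L]
  last <- crossing[1L]
  for (i in crossing[-1L]) {
    if (i - last > holdoff) {
      keep <- c(keep, i)
      last <- i
    }
  }
  (keep - 1L) / samplingRate
}

#' Keep active neurons
#'
#' Retains neurons firing strictly more than `minRate` spikes per minute
#' over the recording window (35 spikes in 7 minutes is exactly 5/min and
#' is removed).
#'
#' @param st a [SpikeTrains-class] object.
#' @param minRate threshold in spikes/minute (default 5).
#' @return The filtered SpikeTrains.
#' @export
filterActive <- function(st, minRate = 5) {
  win <- recordingWindow(st)
  mins <- diff(win) / 60
  if (mins <= 0) stop("zero-length recording window")
  rate <- lengths(spikeTimes(st)) / mins
  subsetNeurons(st, which(rate > minRate))
}

# Maximal runs of >= minSpikes consecutive timestamps with every gap <=
# maxIsi. Greedy-left and maximal: runs are delimited by gaps > maxIsi,
# so they are disjoint and non-extendable.
maximalRuns <- function(ts, minSpikes, maxIsi) {
  n <- length(ts)
  if (n < minSpikes) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0), from = integer(0),
                      to = integer(0)))
  }
  # 1-ns guard so an ISI exactly at the limit is inside the run despite
  # floating-point representation of the timestamps
  breaks <- which(diff(ts) > maxIsi + 1e-9)
  from <- c(1L, breaks + 1L)
  to <- c(breaks, n)
  len <- to - from + 1L
  keep <- len >= minSpikes
  data.frame(start = ts[from[keep]], end = ts[to[keep]],
             n_spikes = len[keep], from = from[keep], to = to[keep])
}

#' Detect bursts per neuron
#'
#' A burst is a maximal run of at least `minSpikes` consecutive spikes of
#' one neuron in which every inter-spike interval is at most `maxIsi`
#' (defaults: 5 spikes, 100 ms). Runs are disjoint and non-extendable.
#'
#' @param st a [SpikeTrains-class] object.
#' @param minSpikes minimum spikes per burst (default 5).
#' @param maxIsi maximum ISI within a burst, seconds (default 0.100).
#' @return data.frame with `neuron`, `well`, `start`, `end`, `n_spikes`.
#' @export
detectBursts <- function(st, minSpikes = 5, maxIsi = 0.100) {
  trains <- spikeTimes(st)
  wl <- wells(st)
  out <- lapply(seq_along(trains), function(i) {
    runs <- maximalRuns(trains[[i]], minSpikes, maxIsi)
    if (!nrow(runs)) return(NULL)
    data.frame(neuron = names(trains)[i], well = unname(wl[i]),
               start = runs$start, end = runs$end,
               n_spikes = runs$n_spikes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(neuron = character(0), well = character(0),
                      start = numeric(0), end = numeric(0),
                      n_spikes = integer(0))
  }
  out
}

#' Detect network events per well
#'
#' Pools all neurons' timestamps within each well, sorts them, and applies
#' the same maximal-run rule with the network thresholds (defaults: 50
#' pooled spikes, 80 ms pooled ISI). Participating neurons are recorded
#' per event.
#'
#' @param st a [SpikeTrains-class] object.
#' @param minSpikes minimum pooled spikes per event (default 50).
#' @param maxIsi maximum pooled ISI, seconds (default 0.080).
#' @return data.frame with `well`, `start`, `end`, `n_spikes`,
#'   `n_neurons`, `neurons` (comma-separated ids).
#' @export
detectNetworkEvents <- function(st, minSpikes = 50, maxIsi = 0.080) {
  if (!length(st)) stop("need at least one neuron")
  trains <- spikeTimes(st)
  wl <- wells(st)
  out <- lapply(unique(wl), function(w) {
    idx <- which(wl == w)
    ts <- unlist(trains[idx], use.names = FALSE)
    owner <- rep(names(trains)[idx], lengths(trains[idx]))
    ord <- order(ts)
    ts <- ts[ord]; owner <- owner[ord]
    runs <- maximalRuns(ts, minSpikes, maxIsi)
    if (!nrow(runs)) return(NULL)
    members <- vapply(seq_len(nrow(runs)), function(k) {
      ids <- unique(owner[runs$from[k]:runs$to[k]])
      paste(sort(ids), collapse = ",")
    }, "")
    data.frame(well = w, start = runs$start, end = runs$end,
               n_spikes = runs$n_spikes,
               n_neurons = lengths(strsplit(members, ",")),
               neurons = members, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(well = character(0), start = numeric(0),
                      end = numeric(0), n_spikes = integer(0),
                      n_neurons = integer(0), neurons = character(0))
  }
  out
}

#' Population event vector
#'
#' Binarizes spikes per neuron per frame, sums across neurons, and
#' smooths with a centered rolling mean over a 500-ms window (default).
#'
#' @param st a [SpikeTrains-class] object.
#' @param frame frame length in seconds (must be > 0).
#' @param window smoothing window in seconds (default 0.5).
#' @return data.frame with `time` (frame centers) and `value`.
#' @export
populationVector <- function(st, frame, window = 0.5) {
  stopifnot(frame > 0)
  win <- recordingWindow(st)
  edges <- seq(win[1L], win[2L], by = frame)
  if (edges[length(edges)] < win[2L]) edges <- c(edges, win[2L])
  nFrames <- length(edges) - 1L
  total <- integer(nFrames)
  for (ts in spikeTimes(st)) {
    if (!length(ts)) next
    f <- pmin(pmax(findInterval(ts, edges, rightmost.closed = TRUE), 1L),
              nFrames)
    total <- total + as.integer(tabulate(f, nFrames) > 0)
  }
  k <- max(1L, 2L * floor(window / frame / 2) + 1L)
  data.frame(time = (edges[-length(edges)] + edges[-1L]) / 2,
             value = rollMean(total, k))
}

#' Area under a metric time series for a treatment phase
#'
#' Trapezoidal AUC of a per-well metric over the annotated phase window,
#' optionally smoothing the series with a two-point moving average first.
#'
#' @param time,value numeric vectors (one well's series).
#' @param phaseStart,phaseEnd phase boundaries (inclusive).
#' @param smooth apply a two-point moving average before integration.
#' @return The AUC (value units x seconds).
#' @export
treatmentAUC <- function(time, value, phaseStart, phaseEnd,
                         smooth = FALSE) {
  ord <- order(time)
  time <- time[ord]; value <- value[ord]
  if (smooth && length(value) >= 2L) {
    value <- c(value[1L], (value[-1L] + value[-length(value)]) / 2)
  }
  keep <- time >= phaseStart & time <= phaseEnd
  t <- time[keep]; v <- value[keep]
  if (length(t) < 2L) stop("need at least 2 timepoints inside the phase")
  sum(diff(t) * (head(v, -1) + tail(v, -1)) / 2)
}

#' Control-normalized percent change from pretreatment
#'
#' Per well and timepoint, the percent change from its pretreatment
#' baseline, normalized to the mean control wells' change. Two
#' conventions are provided: the default ratio-of-ratios
#' `npc = 100 * ((v/v_pre) / (vbar_ctrl/vbar_ctrl_pre) - 1)`, and a
#' subtraction mode `pc - pc_ctrl` where `pc = 100 * (v/v_pre - 1)`.
#'
#' @param values numeric matrix, wells x timepoints.
#' @param baselineIndex column index of the pretreatment baseline.
#' @param controlWells row indices/names of the control (vehicle) wells.
#' @param mode `"ratio"` (default) or `"subtract"`.
#' @return Matrix of normalized percent changes (wells x timepoints);
#'   cells with a zero baseline are `NA`.
#' @export
normalizedPercentChange <- function(values, baselineIndex = 1L,
                                    controlWells,
                                    mode = c("ratio", "subtract")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  base <- values[, baselineIndex]
  rel <- sweep(values, 1L, base, "/")
  rel[base == 0, ] <- NA_real_
  ctrlRel <- colMeans(rel[controlWells, , drop = FALSE], na.rm = TRUE)
  if (mode == "ratio") {
    out <- 100 * (sweep(rel, 2L, ctrlRel, "/") - 1)
    out[, ctrlRel == 0] <- NA_real_
  } else {
    out <- sweep(100 * (rel - 1), 2L, 100 * (ctrlRel - 1), "-")
  }
  dimnames(out) <- dimnames(values)
  out
}
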