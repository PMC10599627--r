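#' Parameters for the synthetic cytotoxicity plate generator
#'
#' Emulates a high-content screening plate: per line and condition, a
#' vehicle-control well group plus treated wells across a dose series, with
#' nuclei counts following a four-parameter logistic (4PL) dose-response
#' and multiplicative replicate noise. Six replicates per dose by default.
#'
#' @slot lines character vector of line ids.
#' @slot doses dose series (micromolar), sorted, non-negative; dose 0 wells
#'   are the paired vehicle controls.
#' @slot trueIC50 named per-line IC50 (micromolar).
#' @slot hill Hill slope of the underlying curve.
#' @slot top,bottom asymptotic viabilities (percent of control).
#' @slot controlMean expected nuclei count of an untreated well.
#' @slot replicateCV coefficient of variation of replicate noise.
#' @slot nReplicates wells per line x dose.
#' @slot seed integer seed.
#' @export
setClass("PlateSimParams", slots = c(
  lines = "character", doses = "numeric", trueIC50 = "numeric",
  hill = "numeric", top = "numeric", bottom = "numeric",
  controlMean = "numeric", replicateCV = "numeric",
  nReplicates = "integer", seed = "integer"))

setValidity("PlateSimParams", function(object) {
  msg <- character()
  if (!length(object@doses)) msg <- c(msg, "empty dose list")
  if (any(object@doses < 0) || is.unsorted(object@doses)) {
    msg <- c(msg, "doses must be non-negative and sorted")
  }
  if (object@bottom <= 0 || object@bottom > object@top) {
    msg <- c(msg, "need 0 < bottom <= top")
  }
  if (any(object@trueIC50 <= 0)) msg <- c(msg, "trueIC50 must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct plate-simulation parameters
#'
#' @param lines line ids (default one line per true IC50 given).
#' @param doses dose series in micromolar; must include 0 for controls.
#' @param trueIC50 per-line true IC50 (micromolar), recycled over lines.
#' @param hill,top,bottom 4PL shape parameters (percent scale).
#' @param controlMean expected untreated nuclei count per well.
#' @param replicateCV replicate coefficient of variation (default 5%).
#' @param nReplicates replicates per dose (default 6).
#' @param seed integer seed.
#' @return A validated [PlateSimParams-class] object.
#' @export
PlateSimParams <- function(lines = NULL,
    doses = c(0, 12.5, 25, 50, 100), trueIC50 = 25, hill = 1.5,
    top = 100, bottom = 5, controlMean = 2000, replicateCV = 0.05,
    nReplicates = 6, seed = 1L) {
  if (is.null(lines)) lines <- sprintf("L%02d", seq_along(trueIC50))
  trueIC50 <- setNames(rep_len(trueIC50, length(lines)), lines)
  new("PlateSimParams", lines = lines, doses = sort(as.numeric(doses)),
      trueIC50 = trueIC50, hill = as.numeric(hill), top = as.numeric(top),
      bottom = as.numeric(bottom), controlMean = as.numeric(controlMean),
      replicateCV = as.numeric(replicateCV),
      nReplicates = assertScalarCount(nReplicates, "nReplicates"),
      seed = as.integer(seed))
}

# 4PL viability (percent of control) at dose d.
fourPL <- function(d, top, bottom, ic50, hill) {
  ifelse(d <= 0, top, bottom + (top - bottom) / (1 + (d / ic50)^hill))
}

#' Simulate a cytotoxicity plate table
#'
#' Nuclei counts are `controlMean x 4PL(dose)/100 x (1 + noise)` with
#' multiplicative Gaussian noise at the configured CV; dose-0 wells form
#' the paired control group for each line.
#'
#' @param params a [PlateSimParams-class] object.
#' @param condition condition label stamped on the wells (default "GM").
#' @return A data.frame with columns `well`, `line`, `condition`,
#'   `treatment`, `dose`, `replicate`, `nuclei_count`, `control_group`, and
#'   attribute `groundTruth` (the true 4PL parameters per line).
#' @examples
#' plate <- simulatePlate(PlateSimParams(trueIC50 = 25, seed = 3))
#' head(plate)
#' @export
simulatePlate <- function(params, condition = "GM") {
  stopifnot(is(params, "PlateSimParams"))
  validObject(params)
  withSeed(params@seed, {
    grid <- expand.grid(replicate = seq_len(params@nReplicates),
                        dose = params@doses, line = params@lines,
                        stringsAsFactors = FALSE)
    viab <- fourPL(grid$dose, params@top, params@bottom,
                   params@trueIC50[grid$line], params@hill)
    noise <- 1 + rnorm(nrow(grid), sd = params@replicateCV)
    counts <- pmax(0, round(params@controlMean * viab / 100 * noise))
    out <- data.frame(
      well = sprintf("%s_%s_d%g_r%d", grid$line, condition, grid$dose,
                     grid$replicate),
      line = grid$line, condition = condition,
      treatment = ifelse(grid$dose == 0, "vehicle", "drug"),
      dose = grid$dose, replicate = grid$replicate,
      nuclei_count = as.integer(counts),
      control_group = sprintf("%s_%s_ctrl", grid$line, condition),
      stringsAsFactors = FALSE)
    attr(out, "groundTruth") <- list(
      top = params@top, bottom = params@bottom, hill = params@hill,
      trueIC50 = params@trueIC50, controlMean = params@controlMean)
    out
  })
}

#' Parameters for the synthetic spike-train generator
#'
#' Background Poisson firing per neuron plus planted bursts (within-neuron
#' spike runs at fixed inter-spike interval) and planted network events
#' (synchronized runs distributed across neurons), inside a recording
#' window of 420 s (the 7-minute minimum recording this models).
#'
#' @slot nNeurons number of neurons.
#' @slot duration recording duration (seconds).
#' @slot backgroundRate per-neuron Poisson rate (Hz).
#' @slot plantedBursts data.frame (neuron, start, n_spikes, isi) with isi
#'   in seconds.
#' @slot plantedNetworkEvents list of lists with fields `start`,
#'   `n_spikes`, `isi`, `neurons` (participating neuron indices).
#' @slot seed integer seed.
#' @export
setClass("SpikeSimParams", slots = c(
  nNeurons = "integer", duration = "numeric", backgroundRate = "numeric",
  plantedBursts = "data.frame", plantedNetworkEvents = "list",
  seed = "integer"))

setValidity("SpikeSimParams", function(object) {
  msg <- character()
  if (object@backgroundRate < 0) msg <- c(msg, "rates must be >= 0")
  pb <- object@plantedBursts
  if (nrow(pb)) {
    ends <- pb$start + (pb$n_spikes - 1) * pb$isi
    if (any(pb$start < 0) || any(ends > object@duration)) {
      msg <- c(msg, "planted burst outside recording window")
    }
    if (any(pb$neuron < 1L | pb$neuron > object@nNeurons)) {
      msg <- c(msg, "planted burst on unknown neuron")
    }
  }
  for (ev in object@plantedNetworkEvents) {
    if (ev$start < 0 ||
        ev$start + (ev$n_spikes - 1) * ev$isi > object@duration) {
      msg <- c(msg, "planted network event outside recording window")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct spike-train simulation parameters
#'
#' @param nNeurons number of neurons (default 16, one per electrode of a
#'   48-well MEA plate well).
#' @param duration recording length in seconds (default 420).
#' @param backgroundRate Poisson background rate in Hz.
#' @param plantedBursts data.frame (neuron, start, n_spikes, isi).
#' @param plantedNetworkEvents list of lists (start, n_spikes, isi,
#'   neurons).
#' @param seed integer seed.
#' @return A validated [SpikeSimParams-class] object.
#' @export
SpikeSimParams <- function(nNeurons = 16, duration = 420,
    backgroundRate = 0.5,
    plantedBursts = data.frame(neuron = integer(), start = numeric(),
                               n_spikes = integer(), isi = numeric()),
    plantedNetworkEvents = list(), seed = 1L) {
  new("SpikeSimParams", nNeurons = assertScalarCount(nNeurons, "nNeurons"),
      duration = as.numeric(duration),
      backgroundRate = as.numeric(backgroundRate),
      plantedBursts = plantedBursts,
      plantedNetworkEvents = plantedNetworkEvents, seed = as.integer(seed))
}

#' Simulate multielectrode-array spike trains
#'
#' @param params a [SpikeSimParams-class] object.
#' @param well well id stamped on all neurons.
#' @return A [SpikeTrains-class] object; `attr(, "groundTruth")` lists the
#'   planted bursts and network events.
#' @examples
#' st <- simulateSpikeTrains(SpikeSimParams(
#'   nNeurons = 2, backgroundRate = 0,
#'   plantedBursts = data.frame(neuron = 1, start = 10, n_spikes = 5,
#'                              isi = 0.05)))
#' nEvents(detectBursts(st))
#' @export
simulateSpikeTrains <- function(params, well = "W1") {
  stopifnot(is(params, "SpikeSimParams"))
  validObject(params)
  withSeed(params@seed, {
    trains <- lapply(seq_len(params@nNeurons), function(i) {
      n <- rpois(1L, params@backgroundRate * params@duration)
      sort(runif(n, 0, params@duration))
    })
    pb <- params@plantedBursts
    for (k in seq_len(nrow(pb))) {
      ts <- pb$start[k] + (seq_len(pb$n_spikes[k]) - 1) * pb$isi[k]
      i <- pb$neuron[k]
      trains[[i]] <- sort(c(trains[[i]], ts))
    }
    for (ev in params@plantedNetworkEvents) {
      ts <- ev$start + (seq_len(ev$n_spikes) - 1) * ev$isi
      members <- rep_len(ev$neurons, length(ts))
      for (j in seq_along(ts)) {
        i <- members[j]
        trains[[i]] <- sort(c(trains[[i]], ts[j]))
      }
    }
    st <- SpikeTrains(trains, well = well, window = c(0, params@duration))
    attr(st, "groundTruth") <- list(
      bursts = pb, networkEvents = params@plantedNetworkEvents,
      seed = params@seed)
    st
  })
}
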