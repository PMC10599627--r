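#' Named collection of gene sets with category labels
#'
#' Container for the gene lists used throughout the pipeline: the four
#' glioblastoma meta-modules (AC-like, MES-like and its two halves, NPC-like,
#' OPC-like), the two cell-cycle programs (G1S, G2M) and a quiescence
#' signature.  Backed by the GMT format on disk (see [readGmt()]).
#'
#' @slot sets named list of character vectors (gene identifiers, no
#'   duplicates within a set).
#' @slot category character vector parallel to `sets`; one of `"state"`,
#'   `"cycle"`, `"quiescence"`, `"custom"`.
#'
#' @seealso [GeneSetCollection()], [readGmt()], [defaultGeneSets()]
#' @export
setClass("GeneSetCollection",
  slots = c(sets = "list", category = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets))) {
    msg <- c(msg, "set names must be unique and non-empty")
  }
  if (length(object@category) != length(object@sets)) {
    msg <- c(msg, "'category' must be parallel to 'sets'")
  }
  bad <- !object@category %in% c("state", "cycle", "quiescence", "custom")
  if (any(bad)) msg <- c(msg, "unknown category label")
  dup <- vapply(object@sets, anyDuplicated, 0L) > 0L
  if (any(dup)) {
    msg <- c(msg, sprintf("duplicate genes within set(s): %s",
                          paste(names(object@sets)[dup], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param category character vector of category labels (recycled if length
#'   1); one of `"state"`, `"cycle"`, `"quiescence"`, `"custom"`.
#' @return A [GeneSetCollection-class] object.
#' @examples
#' gsc <- GeneSetCollection(list(A = c("g1", "g2"), B = c("g3")),
#'                          category = "custom")
#' lengths(geneSets(gsc))
#' @export
GeneSetCollection <- function(sets, category = "custom") {
  if (length(category) == 1L) category <- rep(category, length(sets))
  new("GeneSetCollection", sets = lapply(sets, as.character),
      category = as.character(category))
}

#' @describeIn GeneSetCollection-class the named list of gene sets.
#' @param x,object a `GeneSetCollection`.
#' @export
geneSets <- function(x) x@sets

#' @describeIn GeneSetCollection-class category label per set.
#' @export
setCategories <- function(x) setNames(x@category, names(x@sets))

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

#' @export
setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection with %d set(s)\n", length(object@sets)))
  n <- head(seq_along(object@sets), 10L)
  for (i in n) {
    cat(sprintf("  %-12s [%-10s] %d genes\n", names(object@sets)[i],
                object@category[i], length(object@sets[[i]])))
  }
  if (length(object@sets) > 10L) cat("  ...\n")
})

#' Spike-train container for multielectrode-array recordings
#'
#' Holds per-neuron sorted spike timestamps (seconds), the well each neuron
#' was recorded in, and the common recording window. The nominal acquisition
#' sampling rate (12.5 kHz on the recording system this models) is carried
#' for provenance only.
#'
#' @slot trains named list of strictly increasing numeric vectors
#'   (timestamps, seconds).
#' @slot well character vector, one well id per neuron.
#' @slot window numeric(2), recording window `(start, end)` in seconds.
#' @slot samplingRate numeric(1), Hz; provenance only.
#' @seealso [SpikeTrains()], [detectBursts()], [detectNetworkEvents()]
#' @export
setClass("SpikeTrains",
  slots = c(trains = "list", well = "character", window = "numeric",
            samplingRate = "numeric"))

setValidity("SpikeTrains", function(object) {
  msg <- character()
  if (length(object@well) != length(object@trains)) {
    msg <- c(msg, "'well' must have one entry per neuron")
  }
  if (length(object@window) != 2L || diff(object@window) < 0) {
    msg <- c(msg, "'window' must be (start, end) with end >= start")
  }
  for (i in seq_along(object@trains)) {
    ts <- object@trains[[i]]
    if (length(ts) && (is.unsorted(ts, strictly = TRUE) ||
        ts[1L] < object@window[1L] || ts[length(ts)] > object@window[2L])) {
      msg <- c(msg, sprintf(
        "neuron %d: timestamps must be strictly increasing and inside the window", i))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpikeTrains object
#'
#' @param trains named list of numeric timestamp vectors (seconds); each is
#'   sorted and deduplicated on construction.
#' @param well character vector of well ids, recycled if length 1.
#' @param window numeric(2) recording window in seconds.
#' @param samplingRate acquisition sampling rate in Hz (provenance only).
#' @return A [SpikeTrains-class] object.
#' @export
SpikeTrains <- function(trains, well = "W1", window = c(0, 420),
                        samplingRate = 12500) {
  trains <- lapply(trains, function(ts) sort(unique(as.numeric(ts))))
  if (is.null(names(trains))) {
    names(trains) <- sprintf("n%03d", seq_along(trains))
  }
  if (length(well) == 1L) well <- rep(well, length(trains))
  new("SpikeTrains", trains = trains, well = as.character(well),
      window = as.numeric(window), samplingRate = samplingRate)
}

#' @describeIn SpikeTrains-class the list of per-neuron timestamp vectors.
#' @param x,object a `SpikeTrains` object.
#' @export
spikeTimes <- function(x) x@trains

#' @describeIn SpikeTrains-class well id per neuron.
#' @export
wells <- function(x) setNames(x@well, names(x@trains))

#' @describeIn SpikeTrains-class the recording window (start, end) seconds.
#' @export
recordingWindow <- function(x) x@window

#' @export
setMethod("length", "SpikeTrains", function(x) length(x@trains))

#' @export
setMethod("names", "SpikeTrains", function(x) names(x@trains))

#' @export
setMethod("show", "SpikeTrains", function(object) {
  n <- length(object@trains)
  cat(sprintf("SpikeTrains: %d neuron(s), %d well(s), window [%g, %g] s\n",
              n, length(unique(object@well)), object@window[1L],
              object@window[2L]))
  cat(sprintf("  total spikes: %d\n", sum(lengths(object@trains))))
})

# Subset neurons by index/name, keeping well assignments.
subsetNeurons <- function(x, i) {
  new("SpikeTrains", trains = x@trains[i],
      well = setNames(x@well, names(x@trains))[i],
      window = x@window, samplingRate = x@samplingRate)
}
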