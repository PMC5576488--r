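#' @import methods
#' @importFrom stats approx convolve fft median quantile rnorm runif rpois
#'   rbinom rexp rlnorm sd var cor lm pchisq pbinom wilcox.test ks.test
#'   complete.cases coef
#' @importFrom utils head tail
#' @importFrom tools md5sum
NULL

#' SpikeTrain: ordered spike times for one unit
#'
#' Holds the spike times (seconds from session start) of a single unit
#' together with its anatomical region and mean spike waveform width.
#' Spike times must be strictly increasing.
#'
#' @slot unitId character scalar identifier.
#' @slot region character scalar, \code{"CA1"} or \code{"PFC"}.
#' @slot spikeTimes numeric vector of spike times in seconds, strictly
#'   increasing.
#' @slot spikeWidthMs positive numeric scalar, spike width in milliseconds.
#' @export
setClass("SpikeTrain",
  representation(unitId = "character", region = "character",
                 spikeTimes = "numeric", spikeWidthMs = "numeric"),
  prototype(unitId = NA_character_, region = "CA1",
            spikeTimes = numeric(0), spikeWidthMs = 0.6))

setValidity("SpikeTrain", function(object) {
  msg <- character(0)
  if (length(object@unitId) != 1L || is.na(object@unitId))
    msg <- c(msg, "unitId must be a single non-NA string")
  if (!object@region %in% c("CA1", "PFC"))
    msg <- c(msg, "region must be 'CA1' or 'PFC'")
  st <- object@spikeTimes
  if (anyNA(st)) msg <- c(msg, "spikeTimes contains NA")
  if (length(st) > 1L && any(diff(st) <= 0))
    msg <- c(msg, sprintf("spikeTimes of unit '%s' not strictly increasing",
                          object@unitId))
  if (length(object@spikeWidthMs) != 1L || !is.finite(object@spikeWidthMs) ||
      object@spikeWidthMs <= 0)
    msg <- c(msg, "spikeWidthMs must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a SpikeTrain
#'
#' @param unitId unit identifier.
#' @param region \code{"CA1"} or \code{"PFC"}.
#' @param spikeTimes strictly increasing spike times (s).
#' @param spikeWidthMs spike width (ms).
#' @return A \linkS4class{SpikeTrain}.
#' @examples
#' SpikeTrain("u1", "CA1", c(0.1, 0.5, 1.2), 0.6)
#' @export
SpikeTrain <- function(unitId, region, spikeTimes, spikeWidthMs = 0.6) {
  new("SpikeTrain", unitId = as.character(unitId), region = region,
      spikeTimes = as.numeric(spikeTimes), spikeWidthMs = spikeWidthMs)
}

#' PositionTrace: time-stamped 2-D position with derived speed
#'
#' @slot timeS strictly increasing sample times (s).
#' @slot xCm,yCm position coordinates (cm), same length as \code{timeS}.
#' @slot speedCmS derived speed (cm/s); either empty (not yet computed) or
#'   the same length as \code{timeS}, nonnegative.
#' @export
setClass("PositionTrace",
  representation(timeS = "numeric", xCm = "numeric", yCm = "numeric",
                 speedCmS = "numeric"),
  prototype(timeS = numeric(0), xCm = numeric(0), yCm = numeric(0),
            speedCmS = numeric(0)))

setValidity("PositionTrace", function(object) {
  msg <- character(0)
  n <- length(object@timeS)
  if (length(object@xCm) != n || length(object@yCm) != n)
    msg <- c(msg, "timeS, xCm, yCm must have equal length")
  if (n > 1L && any(diff(object@timeS) <= 0))
    msg <- c(msg, "timeS must be strictly increasing")
  sp <- object@speedCmS
  if (length(sp) && length(sp) != n)
    msg <- c(msg, "speedCmS must be empty or match timeS length")
  if (length(sp) && any(sp < 0, na.rm = TRUE))
    msg <- c(msg, "speedCmS must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a PositionTrace
#' @param timeS sample times (s). @param xCm,yCm coordinates (cm).
#' @param speedCmS optional precomputed speed (cm/s).
#' @return A \linkS4class{PositionTrace}.
#' @export
PositionTrace <- function(timeS, xCm, yCm, speedCmS = numeric(0)) {
  new("PositionTrace", timeS = as.numeric(timeS), xCm = as.numeric(xCm),
      yCm = as.numeric(yCm), speedCmS = as.numeric(speedCmS))
}

#' LfpBundle: aligned multi-tetrode LFP matrix
#'
#' @slot sampleRateHz sampling rate, at least 1000 Hz.
#' @slot channelIds channel (tetrode) labels.
#' @slot samples numeric matrix, time x channel, in microvolts.
#' @slot t0S time of the first sample (s).
#' @export
setClass("LfpBundle",
  representation(sampleRateHz = "numeric", channelIds = "character",
                 samples = "matrix", t0S = "numeric"),
  prototype(sampleRateHz = 1500, channelIds = character(0),
            samples = matrix(numeric(0), 0, 0), t0S = 0))

setValidity("LfpBundle", function(object) {
  msg <- character(0)
  if (object@sampleRateHz < 1000)
    msg <- c(msg, "sampleRateHz must be >= 1000")
  if (ncol(object@samples) != length(object@channelIds))
    msg <- c(msg, "ncol(samples) must equal length(channelIds)")
  if (length(object@t0S) != 1L || !is.finite(object@t0S))
    msg <- c(msg, "t0S must be a finite scalar")
  if (length(msg)) msg else TRUE
})

#' Construct an LfpBundle
#' @param samples time x channel matrix (uV). @param sampleRateHz rate (Hz).
#' @param channelIds channel labels. @param t0S time of first sample (s).
#' @return An \linkS4class{LfpBundle}.
#' @export
LfpBundle <- function(samples, sampleRateHz, channelIds = NULL, t0S = 0) {
  samples <- as.matrix(samples)
  if (is.null(channelIds))
    channelIds <- if (!is.null(colnames(samples))) colnames(samples)
                  else paste0("ch", seq_len(ncol(samples)))
  new("LfpBundle", samples = samples, sampleRateHz = sampleRateHz,
      channelIds = as.character(channelIds), t0S = t0S)
}

#' Session: complete recording session container
#'
#' Bundles the position trace, all unit spike trains, the multi-tetrode LFP,
#' reward-well geometry and beam-break events, and (optionally) the
#' movement/immobility epoch table. All times are seconds from a common
#' session zero; intervals are half-open \code{[start, end)}.
#'
#' @slot position \linkS4class{PositionTrace}.
#' @slot units list of \linkS4class{SpikeTrain}, named by unit id.
#' @slot lfp \linkS4class{LfpBundle}.
#' @slot wells data.frame with columns \code{well_id, x_cm, y_cm, radius_cm}.
#' @slot wellEvents data.frame with columns \code{time_s, well_id, kind}
#'   (\code{"entry"}/\code{"exit"}), alternating per well.
#' @slot epochs data.frame with columns \code{label, start_s, end_s}
#'   (may be empty; filled by \code{\link{segmentMotion}} or the generator).
#' @slot metadata free-form named list.
#' @export
setClass("Session",
  representation(position = "PositionTrace", units = "list",
                 lfp = "LfpBundle", wells = "data.frame",
                 wellEvents = "data.frame", epochs = "data.frame",
                 metadata = "list"))

setValidity("Session", function(object) {
  msg <- character(0)
  for (u in object@units) {
    if (!is(u, "SpikeTrain")) { msg <- c(msg, "units must be SpikeTrains"); break }
    v <- validObject(u, test = TRUE)
    if (!isTRUE(v)) msg <- c(msg, v)
  }
  w <- object@wells
  if (nrow(w)) {
    if (!all(c("well_id", "x_cm", "y_cm", "radius_cm") %in% names(w)))
      msg <- c(msg, "wells must have well_id, x_cm, y_cm, radius_cm")
    else {
      if (any(w$radius_cm <= 0)) msg <- c(msg, "well radius_cm must be > 0")
      if (anyDuplicated(w[, c("x_cm", "y_cm")]))
        msg <- c(msg, "well positions must be distinct")
    }
  }
  ev <- object@wellEvents
  if (nrow(ev)) {
    if (!all(c("time_s", "well_id", "kind") %in% names(ev)))
      msg <- c(msg, "wellEvents must have time_s, well_id, kind")
    else {
      if (!all(ev$kind %in% c("entry", "exit")))
        msg <- c(msg, "wellEvents kind must be entry/exit")
      if (nrow(w) && !all(ev$well_id %in% w$well_id))
        msg <- c(msg, "wellEvents reference unknown well ids")
      for (wid in unique(ev$well_id)) {
        k <- ev$kind[ev$well_id == wid][order(ev$time_s[ev$well_id == wid])]
        if (length(k) > 1L && any(k[-1] == k[-length(k)])) {
          msg <- c(msg, sprintf("entries/exits at well '%s' do not alternate", wid))
          break
        }
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Session
#' @param position a \linkS4class{PositionTrace}.
#' @param units list of \linkS4class{SpikeTrain}.
#' @param lfp an \linkS4class{LfpBundle}.
#' @param wells,wellEvents,epochs data.frames (see class documentation).
#' @param metadata named list.
#' @return A \linkS4class{Session}.
#' @export
Session <- function(position, units, lfp, wells,
                    wellEvents = data.frame(time_s = numeric(0),
                                            well_id = character(0),
                                            kind = character(0)),
                    epochs = data.frame(label = character(0),
                                        start_s = numeric(0),
                                        end_s = numeric(0)),
                    metadata = list()) {
  if (is.null(names(units)) || any(!nzchar(names(units))))
    names(units) <- vapply(units, function(u) u@unitId, character(1))
  new("Session", position = position, units = units, lfp = lfp,
      wells = as.data.frame(wells), wellEvents = as.data.frame(wellEvents),
      epochs = as.data.frame(epochs), metadata = metadata)
}

#' GroundTruth: generator-side labels for a synthetic session
#'
#' @slot unitLabels data.frame: \code{unit_id, label} (\code{MAP},
#'   \code{IAP}, \code{PFC}), \code{home_well} (IAPs), \code{pfc_group},
#'   and per-class PFC gains \code{gain_map, gain_iap, gain_joint}.
#' @slot swrTruth data.frame: \code{start_s, end_s, class}
#'   (\code{MAP-only}/\code{IAP-only}/\code{joint}), \code{amplitude_scale},
#'   \code{participants} (comma-separated unit ids).
#' @slot boutSchedule data.frame: \code{state, start_s, end_s, well_id}.
#' @export
setClass("GroundTruth",
  representation(unitLabels = "data.frame", swrTruth = "data.frame",
                 boutSchedule = "data.frame"))

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s' (%s): %d spikes, width %.2f ms\n",
              object@unitId, object@region, length(object@spikeTimes),
              object@spikeWidthMs))
})

setMethod("show", "PositionTrace", function(object) {
  n <- length(object@timeS)
  cat(sprintf("PositionTrace: %d samples", n))
  if (n) cat(sprintf(", %.1f-%.1f s", object@timeS[1], object@timeS[n]))
  cat(if (length(object@speedCmS)) ", speed computed\n" else ", speed not computed\n")
})

setMethod("show", "LfpBundle", function(object) {
  cat(sprintf("LfpBundle: %d channels x %d samples @ %g Hz (t0 = %g s)\n",
              ncol(object@samples), nrow(object@samples),
              object@sampleRateHz, object@t0S))
})

setMethod("show", "Session", function(object) {
  nc <- sum(vapply(object@units, function(u) u@region == "CA1", logical(1)))
  np <- length(object@units) - nc
  cat("Session\n")
  cat(sprintf("  position : %d samples\n", length(object@position@timeS)))
  cat(sprintf("  units    : %d CA1, %d PFC\n", nc, np))
  cat(sprintf("  lfp      : %d ch @ %g Hz, %.0f s\n", ncol(object@lfp@samples),
              object@lfp@sampleRateHz,
              nrow(object@lfp@samples) / object@lfp@sampleRateHz))
  cat(sprintf("  wells    : %d; well events: %d; epochs: %d\n",
              nrow(object@wells), nrow(object@wellEvents), nrow(object@epochs)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d labelled units, %d injected SWRs, %d bouts\n",
              nrow(object@unitLabels), nrow(object@swrTruth),
              nrow(object@boutSchedule)))
})

# ---- accessors ----

#' @rdname accessors
#' @param object a package object.
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeTrain", function(object) object@spikeTimes)

#' @rdname accessors
#' @export
setGeneric("unitRegion", function(object) standardGeneric("unitRegion"))
#' @rdname accessors
#' @export
setMethod("unitRegion", "SpikeTrain", function(object) object@region)

#' @rdname accessors
#' @export
setGeneric("nSpikes", function(object) standardGeneric("nSpikes"))
#' @rdname accessors
#' @export
setMethod("nSpikes", "SpikeTrain", function(object) length(object@spikeTimes))

#' Accessors for session components
#'
#' \code{sessionUnits}, \code{sessionPosition}, \code{sessionLfp},
#' \code{sessionWells}, \code{sessionWellEvents}, \code{sessionEpochs}
#' extract the corresponding slot; \code{spikeTimes}, \code{unitRegion},
#' \code{nSpikes} operate on \linkS4class{SpikeTrain}.
#'
#' @param session a \linkS4class{Session}.
#' @name accessors
#' @return The extracted component.
#' @export
sessionUnits <- function(session) session@units
#' @rdname accessors
#' @export
sessionPosition <- function(session) session@position
#' @rdname accessors
#' @export
sessionLfp <- function(session) session@lfp
#' @rdname accessors
#' @export
sessionWells <- function(session) session@wells
#' @rdname accessors
#' @export
sessionWellEvents <- function(session) session@wellEvents
#' @rdname accessors
#' @export
sessionEpochs <- function(session) session@epochs
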