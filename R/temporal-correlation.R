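# Spike-train cross-/auto-correlograms, nearby-spike proportion, well-entry
# PETHs, and the PFC-CA1 pattern-similarity and coincidence indices.

# Enumerate all spike pairs (a_i, b_j) with b_j in [a_i + lo, a_i + hi]
# (inclusive) and histogram the lags b_j - a_i over the given edges.
pairLagCounts <- function(a, b, edges) {
  lo <- edges[1]; hi <- edges[length(edges)]
  nlt <- findInterval(a + lo, b, left.open = TRUE)   # b < a + lo
  nle <- findInterval(a + hi, b)                     # b <= a + hi
  cnt <- nle - nlt
  keep <- cnt > 0L
  if (!any(keep)) return(list(counts = integer(length(edges) - 1L), n = 0L))
  bIdx <- sequence(cnt[keep], from = nlt[keep] + 1L)
  lags <- b[bIdx] - rep(a[keep], cnt[keep])
  bin <- findInterval(lags, edges, rightmost.closed = TRUE)
  ok <- bin >= 1L & bin <= length(edges) - 1L
  list(counts = tabulate(bin[ok], nbins = length(edges) - 1L),
       n = sum(ok), lags = lags[ok])
}

#' Spike-train cross-correlogram
#'
#' Histograms all lags \code{t_b - t_a} with magnitude at most half the
#' window, in 10 ms bins by default, normalized so the bins sum to 1.
#' Pairs with 100 or fewer coincident spike events within the window are
#' flagged ineligible, following the inclusion rule used for CA1 pair
#' analyses.
#'
#' @param spikesA,spikesB spike time vectors or \linkS4class{SpikeTrain}s
#'   (reference train A; lags are B relative to A).
#' @param binS bin width (s).
#' @param windowS full window width (s); lags span +/- windowS/2.
#' @param eventTimes optional reference times (e.g. well entries/exits);
#'   when given, only spikes within \code{eventWindowS} of some reference
#'   time enter the correlogram (transition-period restriction).
#' @param eventWindowS half width of the event restriction window (s).
#' @return List of class \code{Correlogram}: \code{lagsS} (bin centers),
#'   \code{values} (normalized, sum 1), \code{counts}, \code{nEvents},
#'   \code{eligible}.
#' @export
crossCorrelogram <- function(spikesA, spikesB, binS = 0.010, windowS = 1,
                             eventTimes = NULL, eventWindowS = 1.5) {
  if (is(spikesA, "SpikeTrain")) spikesA <- spikesA@spikeTimes
  if (is(spikesB, "SpikeTrain")) spikesB <- spikesB@spikeTimes
  if (!is.null(eventTimes) && length(eventTimes)) {
    iv <- normalizeIntervals(cbind(eventTimes - eventWindowS,
                                   eventTimes + eventWindowS))
    spikesA <- spikesA[pointsInIntervals(spikesA, iv)]
    spikesB <- spikesB[pointsInIntervals(spikesB, iv)]
  }
  if (!length(spikesA) || !length(spikesB))
    stop("both spike trains must be nonempty")
  nb <- max(2L, round(windowS / binS))
  edges <- seq(-windowS / 2, windowS / 2, length.out = nb + 1L)
  h <- pairLagCounts(spikesA, spikesB, edges)
  vals <- if (h$n > 0) h$counts / h$n else rep(0, nb)
  structure(list(lagsS = (edges[-1] + edges[-length(edges)]) / 2,
                 values = vals, counts = h$counts, nEvents = h$n,
                 eligible = h$n > 100L),
            class = "Correlogram")
}

#' Spike-train auto-correlogram with optional behavioral-state filter
#'
#' As \code{\link{crossCorrelogram}} with both trains equal; the
#' \code{length(spikes)} zero-lag self pairs are removed. When a
#' \linkS4class{PositionTrace} with speed and a speed range are given, only
#' spikes fired at concurrent speeds within the range enter.
#'
#' @param spikes spike times or \linkS4class{SpikeTrain}.
#' @param binS,windowS bin and window width (s).
#' @param position optional \linkS4class{PositionTrace} with speed.
#' @param speedRange optional two-element range (cm/s), e.g.
#'   \code{c(4, Inf)} for movement spikes.
#' @return A \code{Correlogram}.
#' @export
autoCorrelogram <- function(spikes, binS = 0.010, windowS = 0.5,
                            position = NULL, speedRange = NULL) {
  if (is(spikes, "SpikeTrain")) spikes <- spikes@spikeTimes
  if (!is.null(position) && !is.null(speedRange)) {
    sp <- interpAt(position@timeS, position@speedCmS, spikes, "spike speed")
    spikes <- spikes[sp >= speedRange[1] & sp <= speedRange[2]]
  }
  if (!length(spikes)) stop("no spikes after state filtering")
  nb <- max(2L, round(windowS / binS))
  edges <- seq(-windowS / 2, windowS / 2, length.out = nb + 1L)
  h <- pairLagCounts(spikes, spikes, edges)
  zeroBin <- findInterval(0, edges, rightmost.closed = TRUE)
  counts <- h$counts
  counts[zeroBin] <- counts[zeroBin] - length(spikes)   # self pairs
  n <- h$n - length(spikes)
  vals <- if (n > 0) counts / n else rep(0, nb)
  structure(list(lagsS = (edges[-1] + edges[-length(edges)]) / 2,
                 values = vals, counts = counts, nEvents = n,
                 eligible = n > 100L),
            class = "Correlogram")
}

nearbyDirectional <- function(a, b, nearS, farS) {
  near <- (findInterval(a + nearS, b) -
             findInterval(a - nearS, b, left.open = TRUE)) > 0L
  far <- (findInterval(a + farS, b) -
            findInterval(a - farS, b, left.open = TRUE)) > 0L
  if (!sum(far)) return(NA_real_)
  sum(near) / sum(far)
}

#' Proportion of temporally nearby spikes between two units
#'
#' Of the spikes of one unit that have any spike of the other within
#' +/- \code{farS} (3.3 s, half a typical movement/immobility bout), the
#' fraction that also have one within +/- \code{nearS} (50 ms). The two
#' directions are averaged.
#'
#' @param spikesA,spikesB spike times or \linkS4class{SpikeTrain}s.
#' @param nearS,farS near and far half-windows (s).
#' @return Proportion in [0, 1]; \code{NA} if a denominator is empty.
#' @export
nearbySpikeProportion <- function(spikesA, spikesB, nearS = 0.050, farS = 3.3) {
  if (is(spikesA, "SpikeTrain")) spikesA <- spikesA@spikeTimes
  if (is(spikesB, "SpikeTrain")) spikesB <- spikesB@spikeTimes
  if (!length(spikesA) || !length(spikesB))
    stop("both spike trains must be nonempty")
  mean(c(nearbyDirectional(spikesA, spikesB, nearS, farS),
         nearbyDirectional(spikesB, spikesA, nearS, farS)))
}

#' Peri-event time histogram around reward-well entries
#'
#' Average instantaneous firing rate (100 ms bins, Gaussian-smoothed with
#' sigma = 100 ms) across all well entries in a +/- 5 s window, normalized
#' to the maximum rate in the window.
#'
#' @param spikes spike times or \linkS4class{SpikeTrain}.
#' @param entryTimes well entry times (s), at least one.
#' @param windowS half window (s). @param binS bin width (s).
#' @param smoothingSigmaS Gaussian smoothing sigma (s).
#' @return List of class \code{Peth}: \code{lagsS}, \code{rateHz},
#'   \code{normalizedRate} (max 1 for active units), \code{active}.
#' @export
wellEntryPeth <- function(spikes, entryTimes, windowS = 5, binS = 0.1,
                          smoothingSigmaS = 0.1) {
  if (is(spikes, "SpikeTrain")) spikes <- spikes@spikeTimes
  if (!length(entryTimes)) stop("need at least one well entry")
  nb <- 2L * round(windowS / binS)
  edges <- seq(-windowS, windowS, length.out = nb + 1L)
  h <- pairLagCounts(entryTimes, spikes, edges)
  rate <- h$counts / (length(entryTimes) * binS)
  if (smoothingSigmaS > 0) rate <- gaussianSmooth(rate, smoothingSigmaS / binS)
  mx <- max(rate)
  structure(list(lagsS = (edges[-1] + edges[-length(edges)]) / 2,
                 rateHz = rate,
                 normalizedRate = if (mx > 0) rate / mx else rate,
                 active = mx > 0),
            class = "Peth")
}

#' Pattern similarity of a PFC unit to IAP versus MAP well-entry firing
#'
#' For every (IAP, MAP) pairing, the difference between the Pearson
#' correlation of the PFC unit's well-entry PETH with the IAP PETH and
#' with the MAP PETH, over the common +/- 5 s bins. Values above 0 mean
#' the PFC firing pattern is more similar to IAP firing; below 0, to MAP
#' firing. Pairings involving a constant PETH are skipped.
#'
#' @param pfcPeth a \code{Peth}.
#' @param iapPeths,mapPeths lists of \code{Peth} objects.
#' @return Numeric vector of pairwise correlation differences.
#' @export
patternSimilarityIndex <- function(pfcPeth, iapPeths, mapPeths) {
  p <- pfcPeth$normalizedRate
  if (sd(p) == 0) return(numeric(0))
  corTo <- function(peths) vapply(peths, function(q) {
    v <- q$normalizedRate
    if (sd(v) == 0) NA_real_ else cor(p, v)
  }, numeric(1))
  ci <- corTo(iapPeths); cm <- corTo(mapPeths)
  d <- as.vector(outer(ci, cm, "-"))
  d[!is.na(d)]
}

# z-normalized cross-correlogram with a bin centered on zero lag; counts
# lags t_b - t_a over +/- windowS/2 in binS bins.
zeroCenteredZcorr <- function(a, b, binS, windowS, minCoincidences) {
  half <- round(windowS / 2 / binS)
  edges <- seq(-(half + 0.5) * binS, (half + 0.5) * binS, by = binS)
  h <- pairLagCounts(a, b, edges)
  if (h$n <= minCoincidences) return(NULL)
  z <- (h$counts - mean(h$counts)) / sd(h$counts)
  list(z = z, zeroLag = z[half + 1L], n = h$n)
}

#' Spiking coincidence of a PFC unit with IAPs versus MAPs outside SWRs
#'
#' Spikes inside SWRs are removed from all trains; for each PFC-CA1 pair
#' the cross-correlogram (100 ms bins over a 20 s window) is z-normalized
#' by subtracting the mean and dividing by the SD of all bins, and the
#' value of the bin centered at 0 s lag is taken. The index is the
#' difference of this zero-lag value between every (IAP, MAP) pairing.
#' Pairs with at most \code{minCoincidences} coincident events are skipped.
#'
#' @param pfcSpikes PFC spike times or \linkS4class{SpikeTrain}.
#' @param iapTrains,mapTrains lists of CA1 spike-time vectors or
#'   \linkS4class{SpikeTrain}s.
#' @param swrIntervals two-column matrix (or event data.frame with
#'   \code{start_s,end_s}) of SWR windows to exclude; may be empty.
#' @param binS,windowS correlogram bin and full window (s).
#' @param minCoincidences minimum coincident events per pair.
#' @return Numeric vector of pairwise zero-lag differences (IAP minus MAP).
#' @export
coincidenceIndex <- function(pfcSpikes, iapTrains, mapTrains,
                             swrIntervals = NULL, binS = 0.1, windowS = 20,
                             minCoincidences = 100) {
  getTimes <- function(x) if (is(x, "SpikeTrain")) x@spikeTimes else x
  iv <- if (is.data.frame(swrIntervals))
    cbind(swrIntervals$start_s, swrIntervals$end_s) else swrIntervals
  strip <- function(st) {
    st <- getTimes(st)
    if (!is.null(iv) && nrow(iv)) st[!pointsInIntervals(st, iv)] else st
  }
  p <- strip(pfcSpikes)
  if (!length(p)) return(numeric(0))
  z0 <- function(trains) vapply(trains, function(st) {
    st <- strip(st)
    if (!length(st)) return(NA_real_)
    r <- zeroCenteredZcorr(p, st, binS, windowS, minCoincidences)
    if (is.null(r)) NA_real_ else r$zeroLag
  }, numeric(1))
  zi <- z0(iapTrains); zm <- z0(mapTrains)
  d <- as.vector(outer(zi, zm, "-"))
  d[!is.na(d)]
}
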