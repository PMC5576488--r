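# CA1 unit classification (pyramidal vs interneuron; immobility- vs
# movement-associated place cells), occupancy-normalized rate maps, well
# specificity, spatial coverage and per-spike speed statistics.

#' Pyramidal vs interneuron classification
#'
#' A unit is a putative fast-spiking interneuron when its spike width is
#' below 0.4 ms or its session mean rate is at least 10 Hz; otherwise it is
#' a putative pyramidal cell.
#'
#' @param spikeWidthMs spike width (ms).
#' @param meanRateHz session mean firing rate (Hz).
#' @param widthThresholdMs,rateThresholdHz classification thresholds.
#' @return \code{"pyramidal"} or \code{"interneuron"} (vectorized).
#' @export
classifyCellClass <- function(spikeWidthMs, meanRateHz,
                              widthThresholdMs = 0.4, rateThresholdHz = 10) {
  stopifnot(all(is.finite(spikeWidthMs)), all(is.finite(meanRateHz)))
  ifelse(spikeWidthMs < widthThresholdMs | meanRateHz >= rateThresholdHz,
         "interneuron", "pyramidal")
}

#' Occupancy-normalized firing rate map
#'
#' Spikes are assigned positions by linear interpolation of the tracked
#' trajectory, binned on the occupancy grid, and both spike counts and
#' occupancy are smoothed with a symmetric 2-D Gaussian (sigma = 2 cm,
#' 12 cm extent); the rate is smoothed counts over smoothed occupancy.
#' Bins never visited are \code{NA}, not zero.
#'
#' @param spikes numeric spike times (s) or a \linkS4class{SpikeTrain}.
#' @param occupancy occupancy map from \code{\link{occupancyMap}}.
#' @param position the \linkS4class{PositionTrace} used for the occupancy.
#' @param sigmaCm,extentCm smoothing kernel sigma and total extent (cm).
#' @return List of class \code{RateMap}: \code{rateHz} (matrix),
#'   \code{peakRateHz}, \code{rawCounts}, \code{binEdgesX}, \code{binEdgesY}.
#' @export
rateMap <- function(spikes, occupancy, position, sigmaCm = 2, extentCm = 12) {
  if (is(spikes, "SpikeTrain")) spikes <- spikes@spikeTimes
  t <- position@timeS
  if (length(spikes) && (min(spikes) < t[1] - 1e-9 ||
                         max(spikes) > t[length(t)] + 1e-9))
    stop("spike outside tracked time range")
  ex <- occupancy$binEdgesX; ey <- occupancy$binEdgesY
  sx <- interpAt(t, position@xCm, spikes, "spike position")
  sy <- interpAt(t, position@yCm, spikes, "spike position")
  ix <- findInterval(sx, ex, rightmost.closed = TRUE)
  iy <- findInterval(sy, ey, rightmost.closed = TRUE)
  counts <- matrix(0, length(ex) - 1L, length(ey) - 1L)
  if (length(spikes)) {
    agg <- rowsum(rep(1, length(spikes)), group = (iy - 1L) * (length(ex) - 1L) + ix)
    counts[as.integer(rownames(agg))] <- agg[, 1]
  }
  binCm <- ex[2] - ex[1]
  occ <- occupancy$seconds
  visited <- occ > 0
  sc <- gaussianSmooth2d(counts, sigmaCm / binCm, extentCm / binCm)
  so <- gaussianSmooth2d(occ, sigmaCm / binCm, extentCm / binCm)
  rate <- sc / so
  rate[!visited] <- NA_real_
  structure(list(rateHz = rate, peakRateHz = suppressWarnings(max(rate, na.rm = TRUE)),
                 rawCounts = counts, binEdgesX = ex, binEdgesY = ey),
            class = "RateMap")
}

#' Immobility firing rate at each reward well, SWR periods excluded
#'
#' For each well: spikes inside the immobility-at-well intervals but
#' outside detected SWRs, divided by the at-well immobility time minus the
#' SWR-overlapped time. Wells with no eligible time get \code{NA}.
#'
#' @param spikes spike times (s) or a \linkS4class{SpikeTrain}.
#' @param wellIntervals named list from \code{\link{wellOccupancyIntervals}}.
#' @param swrEvents data.frame with \code{start_s}, \code{end_s} (may be
#'   empty or \code{NULL}).
#' @return Named numeric vector of rates (Hz) per well.
#' @export
immobilityWellRates <- function(spikes, wellIntervals, swrEvents = NULL) {
  if (is(spikes, "SpikeTrain")) spikes <- spikes@spikeTimes
  swrIv <- if (!is.null(swrEvents) && nrow(swrEvents))
    normalizeIntervals(cbind(swrEvents$start_s, swrEvents$end_s))
  else matrix(numeric(0), 0, 2)
  out <- vapply(wellIntervals, function(iv) {
    iv <- normalizeIntervals(iv)
    eligible <- setdiffIntervals(iv, swrIv)
    tt <- totalIntervalTime(eligible)
    if (tt <= 0) return(NA_real_)
    sum(countInIntervals(spikes, eligible)) / tt
  }, numeric(1))
  names(out) <- names(wellIntervals)
  out
}

#' IAP / MAP / excluded place-class assignment
#'
#' Pyramidal units with more than \code{minSpikes} total spikes are
#' immobility-associated place cells (IAP) when their maximum immobility
#' well rate (SWRs excluded) reaches \code{rateThresholdHz} (3 Hz),
#' movement-associated place cells (MAP) otherwise; units at or below the
#' spike minimum are excluded.
#'
#' @param wellRates vector from \code{\link{immobilityWellRates}}.
#' @param totalSpikes total spike count of the unit.
#' @param rateThresholdHz IAP well-rate criterion (Hz).
#' @param minSpikes minimum spike count for inclusion.
#' @return \code{"IAP"}, \code{"MAP"} or \code{"excluded"}.
#' @export
classifyPlaceClass <- function(wellRates, totalSpikes, rateThresholdHz = 3,
                               minSpikes = 200) {
  if (totalSpikes <= minSpikes) return("excluded")
  mx <- suppressWarnings(max(wellRates, na.rm = TRUE))
  if (is.finite(mx) && mx >= rateThresholdHz) "IAP" else "MAP"
}

#' Well specificity index
#'
#' Rates are normalized to their maximum, each well is mapped to a unit
#' vector at equally spaced angles on the circle, and the index is the
#' length of the rate-weighted resultant divided by the summed weights.
#' A value of 1 means firing confined to a single well; 0 means equal
#' firing at all wells.
#'
#' @param wellRates nonnegative per-well rate vector (length >= 2; at least
#'   one positive entry). \code{NA} rates are treated as 0.
#' @return Specificity in [0, 1].
#' @examples
#' wellSpecificity(c(5, 0, 0, 0))  # 1
#' wellSpecificity(c(2, 2, 2, 2))  # 0
#' @export
wellSpecificity <- function(wellRates) {
  r <- as.numeric(wellRates)
  r[is.na(r)] <- 0
  n <- length(r)
  if (n < 2L) stop("well specificity needs at least 2 wells")
  if (all(r <= 0)) return(NA_real_)
  rhat <- r / max(r)
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  res <- sqrt(sum(rhat * cos(ang))^2 + sum(rhat * sin(ang))^2)
  res / sum(rhat)
}

#' Median running speed at spike times
#'
#' @param spikes spike times (s) or a \linkS4class{SpikeTrain}.
#' @param position a \linkS4class{PositionTrace} with speed computed.
#' @return Median interpolated speed (cm/s); \code{NA} without spikes.
#' @export
medianSpeedPerSpike <- function(spikes, position) {
  if (is(spikes, "SpikeTrain")) spikes <- spikes@spikeTimes
  if (!length(spikes)) return(NA_real_)
  if (!length(position@speedCmS)) stop("speed not computed")
  median(interpAt(position@timeS, position@speedCmS, spikes, "spike speed"))
}

#' Spatial coverage of a rate map
#'
#' Fraction of occupied bins (raw occupancy at least
#' \code{minOccupancyS}) whose smoothed rate reaches
#' \code{rateFraction} of the map peak.
#'
#' @param map a \code{RateMap}.
#' @param occupancy the matching occupancy map.
#' @param rateFraction active-bin threshold as a fraction of peak rate.
#' @param minOccupancyS minimum occupancy for a bin to count (s).
#' @return Coverage in [0, 1]; \code{NA} if no bin is occupied.
#' @export
placeCoverage <- function(map, occupancy, rateFraction = 0.2,
                          minOccupancyS = 0.1) {
  occ <- occupancy$seconds >= minOccupancyS
  if (!any(occ)) return(NA_real_)
  if (!is.finite(map$peakRateHz) || map$peakRateHz <= 0) return(0)
  active <- !is.na(map$rateHz) & map$rateHz >= rateFraction * map$peakRateHz
  sum(active & occ) / sum(occ)
}

#' Classify all CA1 units of a session
#'
#' Runs the full unit-selection chain: session mean rate and spike width
#' give the pyramidal/interneuron split; immobility well rates (SWR spikes
#' and time excluded) give the IAP/MAP split for pyramidal units above the
#' spike-count minimum. Also reports the preferred well, well specificity,
#' median speed per spike and spatial coverage per unit.
#'
#' @param session a \linkS4class{Session} with speed computed on its
#'   position trace.
#' @param segments motion segmentation.
#' @param swrEvents detected SWR table (may be empty).
#' @param config pipeline configuration (see \code{\link{defaultConfig}}).
#' @return data.frame: \code{unit_id, cell_class, place_class,
#'   preferred_well, specificity, median_speed, coverage, n_spikes,
#'   mean_rate_hz}.
#' @export
classifyUnits <- function(session, segments, swrEvents = NULL,
                          config = defaultConfig()) {
  pc <- config$place_coding
  pos <- session@position
  if (!length(pos@speedCmS))
    pos <- computeSpeed(pos, config$behavior$speed_smoothing_sigma_s)
  duration <- max(pos@timeS) - min(pos@timeS)
  wellIv <- wellOccupancyIntervals(session, segments)
  occ <- occupancyMap(pos, config$behavior$occupancy_bin_cm)
  ca1 <- Filter(function(u) u@region == "CA1", session@units)
  rows <- lapply(ca1, function(u) {
    ns <- length(u@spikeTimes)
    meanRate <- ns / duration
    cellClass <- classifyCellClass(u@spikeWidthMs, meanRate,
                                   pc$interneuron_width_ms, pc$interneuron_rate_hz)
    wr <- immobilityWellRates(u, wellIv, swrEvents)
    placeClass <- if (cellClass == "pyramidal")
      classifyPlaceClass(wr, ns, pc$iap_rate_threshold_hz, pc$min_spikes)
    else "excluded"
    spec <- if (any(!is.na(wr) & wr > 0)) wellSpecificity(wr) else NA_real_
    pref <- if (all(is.na(wr))) NA_character_ else names(wr)[which.max(wr)]
    rm <- rateMap(u, occ, pos, pc$ratemap_sigma_cm, pc$ratemap_extent_cm)
    data.frame(unit_id = u@unitId, cell_class = cellClass,
               place_class = placeClass, preferred_well = pref,
               specificity = spec,
               median_speed = medianSpeedPerSpike(u, pos),
               coverage = placeCoverage(rm, occ, pc$coverage_rate_fraction,
                                        pc$coverage_min_occupancy_s),
               n_spikes = ns, mean_rate_hz = meanRate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
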