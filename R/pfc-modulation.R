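# PFC SWR-modulation: the modulation index I_SWR, circular-permutation
# significance, four-group classification with expected counts and binomial
# tests, duration-matched and label-permutation controls, and the joint
# event regression.

#' SWR modulation index of a unit for one event class
#'
#' I = (r_SWR - r_window) / r_window, where r_SWR is the mean rate over
#' \code{[start, start + meanDur)} across events (meanDur the mean event
#' duration of the class) and r_window the mean rate in the 1 s window
#' centered on the events. The index is at least -1 and is 0 in
#' expectation for a homogeneous Poisson train.
#'
#' @param spikes spike times or \linkS4class{SpikeTrain}.
#' @param events event table (\code{start_s}, \code{end_s}) of one class.
#' @param windowS surrounding-window length (s), default 1.
#' @param minEvents minimum event count.
#' @return List of class \code{ModulationResult}: \code{iSwr},
#'   \code{rSwrHz}, \code{rWindowHz}, \code{meanDurationS}, \code{nEvents}.
#' @export
modulationIndex <- function(spikes, events, windowS = 1, minEvents = 10) {
  if (is(spikes, "SpikeTrain")) spikes <- spikes@spikeTimes
  nEv <- nrow(events)
  if (nEv < minEvents)
    stop(sprintf("need at least %d events (got %d)", minEvents, nEv))
  meanDur <- mean(events$end_s - events$start_s)
  inIv <- cbind(events$start_s, events$start_s + meanDur)
  rSwr <- sum(countInIntervals(spikes, inIv)) / (nEv * meanDur)
  mid <- events$start_s + meanDur / 2
  winIv <- cbind(mid - windowS / 2, mid + windowS / 2)
  rWin <- sum(countInIntervals(spikes, winIv)) / (nEv * windowS)
  iSwr <- if (rWin > 0) (rSwr - rWin) / rWin else NA_real_
  structure(list(iSwr = iSwr, rSwrHz = rSwr, rWindowHz = rWin,
                 meanDurationS = meanDur, nEvents = nEv),
            class = "ModulationResult")
}

#' Circular-permutation significance test of SWR modulation
#'
#' Builds the event-start-aligned PETH of the unit in a +/- 0.5 s window
#' (10 ms bins). For each of 1000 permutations, the spikes in each event's
#' window are circularly shifted by an offset drawn independently per event
#' (the same shift for all spikes of one event), and a control PETH is
#' formed. The squared deviation of the observed PETH from the mean
#' control PETH, summed over the bins spanning the mean event duration, is
#' compared with the same deviation of each control PETH; the p-value is
#' the fraction of control deviations larger than the observed one
#' (reported no smaller than 1/nPermutations). Direction is the sign of
#' the modulation index when the test is significant.
#'
#' @param spikes spike times or \linkS4class{SpikeTrain}.
#' @param events event table of one class.
#' @param nPermutations permutation count.
#' @param seed integer seed (fixed seed gives identical p on rerun).
#' @param halfWindowS PETH half window (s).
#' @param binS PETH bin width (s).
#' @param smoothingSigmaS Gaussian smoothing applied identically to the
#'   observed and every control PETH before the deviation comparison, so
#'   the statistic compares mean-rate curves rather than raw bin counts;
#'   exchangeability (and hence type-I calibration) is unaffected.
#' @param alpha significance level.
#' @param windowS window for the modulation index (s).
#' @return List: \code{p_value}, \code{direction} ("excited"/"inhibited"/
#'   "n.s."), \code{iSwr}, \code{observedDeviation}, \code{nSpikes}.
#' @export
circularPermutationTest <- function(spikes, events, nPermutations = 1000,
                                    seed = 1, halfWindowS = 0.5, binS = 0.01,
                                    smoothingSigmaS = 0.02,
                                    alpha = 0.05, windowS = 1) {
  if (is(spikes, "SpikeTrain")) spikes <- spikes@spikeTimes
  nEv <- nrow(events)
  W <- 2 * halfWindowS
  nb <- round(W / binS)
  edges <- seq(-halfWindowS, halfWindowS, length.out = nb + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  rel <- numeric(0); evIdx <- integer(0)
  for (i in seq_len(nEv)) {
    s <- events$start_s[i]
    sel <- spikes[spikes >= s - halfWindowS & spikes < s + halfWindowS]
    rel <- c(rel, sel - s); evIdx <- c(evIdx, rep(i, length(sel)))
  }
  if (!length(rel)) stop("no spikes in any event window; test undefined")
  sm <- function(v) if (smoothingSigmaS > 0)
    gaussianSmooth(v, smoothingSigmaS / binS) else v
  histRel <- function(r) sm(tabulate(pmin(pmax(
    floor((r + halfWindowS) / binS) + 1L, 1L), nb), nbins = nb))
  obs <- histRel(rel) / nEv
  meanDur <- mean(events$end_s - events$start_s)
  sel <- centers >= 0 & centers < meanDur
  set.seed(deriveSeed(seed, "circperm"))
  ctrl <- matrix(0, nb, nPermutations)
  for (k in seq_len(nPermutations)) {
    off <- runif(nEv, 0, W)
    shifted <- ((rel + halfWindowS + off[evIdx]) %% W) - halfWindowS
    ctrl[, k] <- histRel(shifted) / nEv
  }
  M <- rowMeans(ctrl)
  devObs <- sum((obs - M)[sel]^2)
  devCtrl <- colSums((ctrl[sel, , drop = FALSE] - M[sel])^2)
  p <- max(mean(devCtrl > devObs), 1 / nPermutations)
  mi <- modulationIndex(spikes, events, windowS = windowS,
                        minEvents = min(nEv, 1L))
  direction <- if (p < alpha) {
    if (!is.na(mi$iSwr) && mi$iSwr > 0) "excited" else "inhibited"
  } else "n.s."
  list(p_value = p, direction = direction, iSwr = mi$iSwr,
       observedDeviation = devObs, nSpikes = length(rel))
}

#' Four-group PFC classification from the per-class significance pair
#'
#' Maps the (IAP-SWR, MAP-SWR) significance pair to the group labels:
#' excitation only during IAP-SWRs, excitation only during MAP-SWRs,
#' inhibition during either or both, excitation during both; units
#' significant for neither class are unclassified.
#'
#' @param sigIap,sigMap \code{"excited"}, \code{"inhibited"} or
#'   \code{"n.s."}.
#' @return Group label string.
#' @export
classifyGroup <- function(sigIap, sigMap) {
  stopifnot(sigIap %in% c("excited", "inhibited", "n.s."),
            sigMap %in% c("excited", "inhibited", "n.s."))
  if (sigIap == "excited" && sigMap == "excited") return("IAP-and-MAP-SWR+")
  if (sigIap == "excited") return("IAP-SWR+")
  if (sigMap == "excited") return("MAP-SWR+")
  if (sigIap == "inhibited" || sigMap == "inhibited") return("IAP/MAP-SWR-")
  "unclassified"
}

#' Expected group counts under random significance combinations
#'
#' Among significantly modulated units, each of the 8 significance
#' combinations (excluding the doubly non-significant one) is taken as
#' equally likely; a group covering \code{combos} combinations has expected
#' count \code{round(combos * n / 8)} (half away from zero).
#'
#' @param nSignificant number of significantly modulated units.
#' @param combosPerGroup named or unnamed integer vector of combination
#'   counts per group (default \code{c(2, 2, 3, 1)} for IAP-SWR+,
#'   MAP-SWR+, IAP/MAP-SWR-, IAP-and-MAP-SWR+).
#' @return Integer vector of expected counts.
#' @examples
#' expectedGroupCounts(70)  # 18 18 26 9
#' @export
expectedGroupCounts <- function(nSignificant,
                                combosPerGroup = c("IAP-SWR+" = 2,
                                                   "MAP-SWR+" = 2,
                                                   "IAP/MAP-SWR-" = 3,
                                                   "IAP-and-MAP-SWR+" = 1)) {
  stopifnot(nSignificant > 0)
  floor(combosPerGroup * nSignificant / 8 + 0.5)
}

#' One-sided exact binomial test of an observed group count
#'
#' Tests the observed count against success probability \code{combos/8}
#' over \code{n} units, one-sided toward the observed deviation.
#'
#' @param observed observed group count.
#' @param n number of significantly modulated units.
#' @param combos significance combinations covered by the group.
#' @return p-value.
#' @examples
#' groupBinomialTest(3, 70, 1)  # ~0.019
#' @export
groupBinomialTest <- function(observed, n, combos) {
  stopifnot(observed >= 0, observed <= n)
  p0 <- combos / 8
  if (observed <= n * p0) pbinom(observed, n, p0)
  else pbinom(observed - 1, n, p0, lower.tail = FALSE)
}

#' Duration-matched event resampling between two classes
#'
#' Resamples (with replacement) events from each class so the two duration
#' distributions match: durations are pooled into quantile bins and each
#' class contributes the per-bin minimum count. Used to control the
#' modulation-index comparison for duration differences between classes.
#'
#' @param eventsA,eventsB event tables with \code{start_s}, \code{end_s}.
#' @param seed integer seed.
#' @param nBins quantile bin count.
#' @return List: \code{eventsA}, \code{eventsB} (resampled tables),
#'   \code{indicesA}, \code{indicesB}.
#' @export
durationMatchedControl <- function(eventsA, eventsB, seed = 1, nBins = 10) {
  stopifnot(nrow(eventsA) > 0, nrow(eventsB) > 0)
  dA <- eventsA$end_s - eventsA$start_s
  dB <- eventsB$end_s - eventsB$start_s
  qs <- quantile(c(dA, dB), probs = seq(0, 1, length.out = nBins + 1L),
                 names = FALSE)
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  binA <- findInterval(dA, qs, rightmost.closed = TRUE)
  binB <- findInterval(dB, qs, rightmost.closed = TRUE)
  set.seed(deriveSeed(seed, "durmatch"))
  idxA <- integer(0); idxB <- integer(0)
  empty <- TRUE
  for (k in seq_len(nBins)) {
    ia <- which(binA == k); ib <- which(binB == k)
    m <- min(length(ia), length(ib))
    if (m == 0) next
    empty <- FALSE
    idxA <- c(idxA, sample(ia, m, replace = TRUE))
    idxB <- c(idxB, sample(ib, m, replace = TRUE))
  }
  if (empty) {
    warning("disjoint duration supports; best-effort match uses all events")
    idxA <- seq_along(dA); idxB <- seq_along(dB)
  }
  list(eventsA = eventsA[idxA, , drop = FALSE],
       eventsB = eventsB[idxB, , drop = FALSE],
       indicesA = idxA, indicesB = idxB)
}

#' Event-label permutation control for class selectivity
#'
#' Shuffles the content-class labels across events and recomputes the
#' per-class modulation indices, yielding a null distribution for the
#' between-class index difference of a unit.
#'
#' @param spikes spike times or \linkS4class{SpikeTrain}.
#' @param events classified event table restricted to the two classes of
#'   interest (uses \code{content_class}).
#' @param classes length-2 character vector of class labels to compare.
#' @param nPermutations shuffle count.
#' @param seed integer seed.
#' @return List: \code{observedDiff} (index of class 1 minus class 2),
#'   \code{nullDiffs}, \code{p_value} (two-sided exceedance of |diff|).
#' @export
labelPermutationControl <- function(spikes, events,
                                    classes = c("IAP-only", "MAP-only"),
                                    nPermutations = 500, seed = 1) {
  if (is(spikes, "SpikeTrain")) spikes <- spikes@spikeTimes
  ev <- events[events$content_class %in% classes, , drop = FALSE]
  stopifnot(length(unique(ev$content_class)) == 2)
  idxOf <- function(lab, labels) which(labels == lab)
  iOf <- function(rows) modulationIndex(spikes, ev[rows, , drop = FALSE],
                                        minEvents = 1L)$iSwr
  obs <- iOf(idxOf(classes[1], ev$content_class)) -
         iOf(idxOf(classes[2], ev$content_class))
  set.seed(deriveSeed(seed, "labelperm"))
  nulls <- numeric(nPermutations)
  for (k in seq_len(nPermutations)) {
    lab <- sample(ev$content_class)
    nulls[k] <- iOf(idxOf(classes[1], lab)) - iOf(idxOf(classes[2], lab))
  }
  list(observedDiff = obs, nullDiffs = nulls,
       p_value = max(mean(abs(nulls) >= abs(obs)), 1 / nPermutations))
}

#' Regression of joint-event modulation on the single-class indices
#'
#' Ordinary least squares of the joint-SWR modulation index on the MAP-SWR
#' and IAP-SWR indices across units, with intercept.
#'
#' @param indices data.frame with columns \code{i_joint}, \code{i_map},
#'   \code{i_iap} (one row per unit, >= 3 complete rows).
#' @return List: \code{r_squared}, \code{coefficients}, \code{fit}.
#' @export
jointModulationRegression <- function(indices) {
  df <- indices[complete.cases(indices[, c("i_joint", "i_map", "i_iap")]), ]
  if (nrow(df) < 3) stop("need at least 3 units with all three indices")
  if (qr(cbind(1, df$i_map, df$i_iap))$rank < 3)
    stop("rank-deficient design: single-class indices are collinear")
  fit <- lm(i_joint ~ i_map + i_iap, data = df)
  list(r_squared = summary(fit)$r.squared, coefficients = coef(fit),
       fit = fit)
}

#' Per-unit PFC SWR-modulation table for a session
#'
#' Applies the PFC selection rule (mean rate above 1 Hz during movement or
#' immobility or both), computes the modulation index and
#' circular-permutation test per unit for MAP-only and IAP-only (and
#' joint, when enough events) SWRs, and assigns the four-group label.
#'
#' @param session a \linkS4class{Session}.
#' @param segments motion segmentation.
#' @param events classified event table.
#' @param config pipeline configuration.
#' @param seed integer seed.
#' @return data.frame with one row per (unit, class) plus the group label
#'   per unit in attribute-free long format: \code{unit_id, swr_class,
#'   i_swr, p_value, direction, group, selected}.
#' @export
pfcModulationTable <- function(session, segments, events,
                               config = defaultConfig(), seed = 1) {
  pcfg <- config$pfc
  moveIv <- segmentsToIntervals(segments, "movement")
  immoIv <- segmentsToIntervals(segments, "immobility")
  evByClass <- list(
    "MAP-only" = events[events$content_class == "MAP-only", , drop = FALSE],
    "IAP-only" = events[events$content_class == "IAP-only", , drop = FALSE],
    "joint" = events[events$content_class == "joint", , drop = FALSE])
  pfc <- Filter(function(u) u@region == "PFC", session@units)
  allRows <- vector("list", length(pfc))
  for (ui in seq_along(pfc)) {
    u <- pfc[[ui]]
    st <- u@spikeTimes
    rMove <- if (totalIntervalTime(moveIv) > 0)
      sum(countInIntervals(st, moveIv)) / totalIntervalTime(moveIv) else 0
    rImmo <- if (totalIntervalTime(immoIv) > 0)
      sum(countInIntervals(st, immoIv)) / totalIntervalTime(immoIv) else 0
    selected <- max(rMove, rImmo) > pcfg$min_rate_hz
    sig <- c("MAP-only" = "n.s.", "IAP-only" = "n.s.")
    unitRows <- NULL
    for (cls in names(evByClass)) {
      ev <- evByClass[[cls]]
      if (!selected || nrow(ev) < pcfg$min_events) {
        unitRows <- rbind(unitRows, data.frame(
          unit_id = u@unitId, swr_class = cls, i_swr = NA_real_,
          p_value = NA_real_, direction = NA_character_, selected = selected,
          stringsAsFactors = FALSE))
        next
      }
      tst <- circularPermutationTest(
        st, ev, nPermutations = pcfg$n_permutations,
        seed = deriveSeed(seed, paste0(u@unitId, cls)),
        halfWindowS = pcfg$peth_halfwindow_s, binS = pcfg$peth_bin_s,
        smoothingSigmaS = pcfg$peth_smoothing_sigma_s, alpha = pcfg$alpha)
      unitRows <- rbind(unitRows, data.frame(
        unit_id = u@unitId, swr_class = cls, i_swr = tst$iSwr,
        p_value = tst$p_value, direction = tst$direction,
        selected = selected, stringsAsFactors = FALSE))
      if (cls %in% names(sig) && !is.na(tst$p_value))
        sig[cls] <- tst$direction
    }
    unitRows$group <- if (selected)
      classifyGroup(sig[["IAP-only"]], sig[["MAP-only"]]) else NA_character_
    allRows[[ui]] <- unitRows
  }
  rows <- do.call(rbind, allRows)
  rownames(rows) <- NULL
  rows
}
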