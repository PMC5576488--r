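# SWR content: class assignment from participating CA1 units, count
# statistics with the independence expectation, permutation coactivity
# z-scores, within-event spike latencies and per-class property summaries.

#' Assign content classes to detected SWRs
#'
#' An event's participants are the classified units with at least one spike
#' in \code{[start_s, end_s)}. Events with only MAP participants are
#' \code{MAP-only}, only IAP participants \code{IAP-only}, both
#' \code{joint}, and none \code{neither} (excluded from count statistics).
#'
#' @param events data.frame from \code{\link{detectSwrs}}.
#' @param unitClasses data.frame with \code{unit_id} and \code{place_class}
#'   (\code{"IAP"}/\code{"MAP"}; other labels ignored), e.g. from
#'   \code{\link{classifyUnits}}.
#' @param units named list of \linkS4class{SpikeTrain}s covering the
#'   classified unit ids.
#' @return The event table with \code{content_class} and
#'   \code{participants} (comma-separated unit ids) columns added.
#' @export
assignContent <- function(events, unitClasses, units) {
  keep <- unitClasses$place_class %in% c("IAP", "MAP")
  uc <- unitClasses[keep, , drop = FALSE]
  nEv <- nrow(events)
  hasMap <- logical(nEv); hasIap <- logical(nEv)
  plist <- vector("list", nEv)
  if (nEv) {
    iv <- cbind(events$start_s, events$end_s)
    for (i in seq_len(nrow(uc))) {
      st <- units[[uc$unit_id[i]]]@spikeTimes
      part <- countInIntervals(st, iv) > 0L
      if (uc$place_class[i] == "MAP") hasMap <- hasMap | part
      else hasIap <- hasIap | part
      for (j in which(part)) plist[[j]] <- c(plist[[j]], uc$unit_id[i])
    }
  }
  events$content_class <- ifelse(hasMap & hasIap, "joint",
                          ifelse(hasMap, "MAP-only",
                          ifelse(hasIap, "IAP-only", "neither")))
  events$participants <- vapply(plist, function(p)
    paste(sort(p), collapse = ","), character(1))
  events
}

#' SWR content counts with independence expectation and chi-square test
#'
#' From classified events (class \code{neither} excluded), counts each
#' class and computes the number of joint events expected if MAP and IAP
#' participation were independent:
#' \code{(n_map_only + n_joint) * (n_iap_only + n_joint) / n_total}.
#' The observed joint/non-joint split is tested against this expectation
#' with a 1-d.f. goodness-of-fit chi-square.
#'
#' @param events data.frame with a \code{content_class} column, or a named
#'   vector/list with counts \code{n_map_only, n_iap_only, n_joint}.
#' @return List of class \code{ContentCounts}: the three counts,
#'   \code{n_total}, \code{expected_joint} (rounded for reporting),
#'   \code{expected_joint_exact}, \code{chi2_stat}, \code{p_value}.
#' @examples
#' contentCounts(c(n_map_only = 12881, n_iap_only = 5009, n_joint = 1311))
#' @export
contentCounts <- function(events) {
  if (is.data.frame(events)) {
    cls <- events$content_class
    nm <- sum(cls == "MAP-only"); ni <- sum(cls == "IAP-only")
    nj <- sum(cls == "joint")
  } else {
    nm <- events[["n_map_only"]]; ni <- events[["n_iap_only"]]
    nj <- events[["n_joint"]]
  }
  nTot <- nm + ni + nj
  if (nTot <= 0) stop("no classified events")
  expJ <- (nm + nj) * (ni + nj) / nTot
  if ((nm + nj) == 0 || (ni + nj) == 0) {
    chi2 <- NA_real_; p <- NA_real_
  } else {
    expNon <- nTot - expJ
    term <- function(obs, ex) if (ex > 0) (obs - ex)^2 / ex
      else if (obs == 0) 0 else Inf
    chi2 <- term(nj, expJ) + term(nTot - nj, expNon)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(n_map_only = nm, n_iap_only = ni, n_joint = nj,
                 n_total = nTot, expected_joint = floor(expJ + 0.5),
                 expected_joint_exact = expJ, chi2_stat = chi2,
                 p_value = p),
            class = "ContentCounts")
}

#' Pairwise SWR coactivity z-score by participation permutation
#'
#' Participation is binarized per event; the observed fraction of events in
#' which both units participate is compared with a null built by
#' independently permuting each unit's participation vector across events
#' (5000 permutations by default). The z-score subtracts the null mean and
#' divides by the null SD. Units participating in no event or in every
#' event give a degenerate result (z undefined).
#'
#' The permutation seed is derived from \code{seed} and the sorted pair of
#' unit ids, so \code{coactivityZ(a, b)} and \code{coactivityZ(b, a)} are
#' identical.
#'
#' @param participationA,participationB logical participation vectors over
#'   the same events.
#' @param nPermutations permutation count.
#' @param seed integer seed.
#' @param unitIds optional length-2 character vector of unit ids used in
#'   seed derivation.
#' @return List of class \code{CoactivityResult}: \code{observed},
#'   \code{nullMean}, \code{nullSd}, \code{z}, \code{degenerate},
#'   \code{nPermutations}.
#' @export
coactivityZ <- function(participationA, participationB, nPermutations = 5000,
                        seed = 1, unitIds = c("a", "b")) {
  a <- as.logical(participationA); b <- as.logical(participationB)
  stopifnot(length(a) == length(b))
  # canonical argument order (by unit id) so the permutation stream, and
  # hence z, is identical for (a, b) and (b, a)
  if (length(unitIds) == 2 && unitIds[1] > unitIds[2]) {
    tmp <- a; a <- b; b <- tmp
  }
  nEv <- length(a)
  observed <- mean(a & b)
  degenerate <- !any(a) || all(a) || !any(b) || all(b)
  if (degenerate)
    return(structure(list(observed = observed, nullMean = NA_real_,
                          nullSd = NA_real_, z = NA_real_, degenerate = TRUE,
                          nPermutations = nPermutations),
                     class = "CoactivityResult"))
  set.seed(deriveSeed(seed, paste(sort(unitIds), collapse = "|")))
  # each unit's participation vector permuted independently per round;
  # rounds laid out as columns and reduced with colSums
  chunk <- 250L
  nullFrac <- numeric(nPermutations)
  done <- 0L
  while (done < nPermutations) {
    k <- min(chunk, nPermutations - done)
    I1 <- vapply(seq_len(k), function(i) sample.int(nEv), integer(nEv))
    I2 <- vapply(seq_len(k), function(i) sample.int(nEv), integer(nEv))
    nullFrac[done + seq_len(k)] <-
      colSums(matrix(a[I1] & b[I2], nEv)) / nEv
    done <- done + k
  }
  mu <- mean(nullFrac); sdv <- sd(nullFrac)
  z <- if (sdv > 0) (observed - mu) / sdv else NA_real_
  structure(list(observed = observed, nullMean = mu, nullSd = sdv, z = z,
                 degenerate = !is.finite(z), nPermutations = nPermutations),
            class = "CoactivityResult")
}

#' Event participation matrix for a set of units
#'
#' @param events event data.frame with \code{start_s}, \code{end_s}.
#' @param units named list of \linkS4class{SpikeTrain}s.
#' @param unitIds unit ids (default: all in \code{units}).
#' @return Logical matrix, events x units.
#' @export
participationMatrix <- function(events, units, unitIds = names(units)) {
  iv <- cbind(events$start_s, events$end_s)
  out <- vapply(unitIds, function(uid)
    countInIntervals(units[[uid]]@spikeTimes, iv) > 0L,
    logical(nrow(events)))
  matrix(out, nrow = nrow(events), dimnames = list(NULL, unitIds))
}

#' Cell-pair eligibility from cross-correlogram peak lag
#'
#' A pair enters coactivity comparisons when its cross-correlogram peak lag
#' magnitude is below 3.3 s (half the duration of a typical
#' movement/immobility bout) and the pair has more than 100 coincident
#' events. The correlogram is computed over a window wider than the lag
#' criterion (default +/- 10 s) so the rule can bind.
#'
#' @param spikesA,spikesB spike times or \linkS4class{SpikeTrain}s.
#' @param maxLagS peak-lag criterion (s).
#' @param windowS full correlogram window (s).
#' @param binS bin width (s).
#' @return List: \code{eligible}, \code{peakLagS}, \code{nEvents}.
#' @export
pairEligibility <- function(spikesA, spikesB, maxLagS = 3.3, windowS = 20,
                            binS = 0.1) {
  cc <- crossCorrelogram(spikesA, spikesB, binS = binS, windowS = windowS)
  if (cc$nEvents == 0)
    return(list(eligible = FALSE, peakLagS = NA_real_, nEvents = 0L))
  peak <- cc$lagsS[which.max(cc$counts)]
  list(eligible = abs(peak) < maxLagS && cc$nEvents > 100L,
       peakLagS = peak, nEvents = cc$nEvents)
}

#' Spike latencies within joint SWRs, by place-cell class
#'
#' For events containing both classes, pools spike time minus event start
#' for MAP and IAP participants separately and compares the two latency
#' distributions with a Wilcoxon rank-sum test.
#'
#' @param events classified event table (uses rows with
#'   \code{content_class == "joint"}; pass a pre-filtered table to override).
#' @param unitClasses data.frame with \code{unit_id}, \code{place_class}.
#' @param units named list of \linkS4class{SpikeTrain}s.
#' @return List: \code{latencies} (data.frame \code{class, latency_s}),
#'   \code{median_iap_s}, \code{median_map_s}, \code{p_value}.
#' @export
inSwrLatency <- function(events, unitClasses, units) {
  ev <- if ("content_class" %in% names(events))
    events[events$content_class == "joint", , drop = FALSE] else events
  res <- list(MAP = numeric(0), IAP = numeric(0))
  if (nrow(ev)) {
    keep <- unitClasses$place_class %in% c("IAP", "MAP")
    uc <- unitClasses[keep, , drop = FALSE]
    for (i in seq_len(nrow(uc))) {
      st <- units[[uc$unit_id[i]]]@spikeTimes
      for (j in seq_len(nrow(ev))) {
        inEv <- st[st >= ev$start_s[j] & st < ev$end_s[j]]
        if (length(inEv))
          res[[uc$place_class[i]]] <- c(res[[uc$place_class[i]]],
                                        inEv - ev$start_s[j])
      }
    }
  }
  p <- if (length(res$MAP) && length(res$IAP))
    suppressWarnings(wilcox.test(res$IAP, res$MAP)$p.value) else NA_real_
  list(latencies = data.frame(
         class = rep(c("MAP", "IAP"), c(length(res$MAP), length(res$IAP))),
         latency_s = c(res$MAP, res$IAP), stringsAsFactors = FALSE),
       median_iap_s = if (length(res$IAP)) median(res$IAP) else NA_real_,
       median_map_s = if (length(res$MAP)) median(res$MAP) else NA_real_,
       p_value = p)
}

#' Per-class SWR duration and band-power summaries with pairwise tests
#'
#' Empirical CDFs of event duration and (when present) z-scored ripple-band
#' power per content class, with two-sample Kolmogorov-Smirnov and Wilcoxon
#' rank-sum comparisons for every class pair having at least 2 events.
#'
#' @param events classified event table with \code{duration_s} and
#'   optionally \code{band_power_z}.
#' @return List: \code{byClass} (per-class n, median duration, median
#'   power), \code{tests} (data.frame of pairwise test results).
#' @export
eventPropertySummary <- function(events) {
  ev <- events[events$content_class %in% c("MAP-only", "IAP-only", "joint"), ,
               drop = FALSE]
  classes <- intersect(c("MAP-only", "IAP-only", "joint"),
                       unique(ev$content_class))
  byClass <- lapply(classes, function(cl) {
    e <- ev[ev$content_class == cl, ]
    list(class = cl, n = nrow(e), median_duration_s = median(e$duration_s),
         median_band_power_z = if ("band_power_z" %in% names(e))
           median(e$band_power_z, na.rm = TRUE) else NA_real_,
         duration_cdf = stats::ecdf(e$duration_s))
  })
  names(byClass) <- classes
  tests <- NULL
  if (length(classes) >= 2) for (i in seq_len(length(classes) - 1L))
    for (j in (i + 1L):length(classes)) {
      a <- ev$duration_s[ev$content_class == classes[i]]
      b <- ev$duration_s[ev$content_class == classes[j]]
      if (length(a) < 2 || length(b) < 2) next
      ks <- suppressWarnings(ks.test(a, b))
      w <- suppressWarnings(wilcox.test(a, b))
      tests <- rbind(tests, data.frame(
        class_a = classes[i], class_b = classes[j], measure = "duration",
        ks_stat = unname(ks$statistic), ks_p = ks$p.value,
        ranksum_p = w$p.value, stringsAsFactors = FALSE))
    }
  list(byClass = byClass, tests = tests)
}
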