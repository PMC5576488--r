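# End-to-end orchestration: simulate/load -> behavior -> SWR detection ->
# unit classification -> content statistics -> PFC modulation -> report.

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config), f)
  unname(tools::md5sum(f))
}

coactivitySummary <- function(events, units, classification, config, seed) {
  cls <- classification[classification$place_class %in% c("IAP", "MAP"), ]
  if (nrow(cls) < 2 || nrow(events) < 10) return(NULL)
  part <- participationMatrix(events, units, cls$unit_id)
  ids <- cls$unit_id
  lab <- cls$place_class
  rows <- NULL
  for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
    r <- coactivityZ(part[, i], part[, j],
                     nPermutations = config$swr_content$n_permutations,
                     seed = seed, unitIds = c(ids[i], ids[j]))
    elig <- pairEligibility(units[[ids[i]]], units[[ids[j]]],
                            maxLagS = config$swr_content$eligibility_max_lag_s)
    type <- paste(sort(c(lab[i], lab[j])), collapse = "-")
    rows <- rbind(rows, data.frame(
      unit_a = ids[i], unit_b = ids[j], pair_type = type,
      observed = r$observed, null_mean = r$nullMean, null_sd = r$nullSd,
      z = r$z, eligible = elig$eligible, stringsAsFactors = FALSE))
  }
  rows
}

#' Run the full analysis pipeline
#'
#' Generates (or takes) a session, derives speed and the motion
#' segmentation, detects SWRs from the consensus ripple-band envelope with
#' the empirical noise threshold, classifies CA1 units, assigns SWR content
#' classes, computes content-count statistics, pairwise coactivity
#' z-scores, in-SWR latencies and per-class event properties, runs the PFC
#' modulation tests with group classification, and summarises well-entry
#' pattern similarity and outside-SWR coincidence per PFC group. The run
#' is a pure function of (session, config, seed): a fixed seed reproduces
#' the report exactly.
#'
#' @param session a \linkS4class{Session}, or \code{NULL} to generate one
#'   from \code{config$generator}.
#' @param config pipeline configuration.
#' @param seed integer seed.
#' @param outDir optional directory; when given, every stage output is
#'   persisted as delimited text/JSON.
#' @param truth optional \linkS4class{GroundTruth} carried into the report.
#' @return List of class \code{ReportBundle}; see the package vignette.
#' @export
runPipeline <- function(session = NULL, config = defaultConfig(), seed = 1,
                        outDir = NULL, truth = NULL) {
  validateConfig(config)
  if (is.null(session)) {
    gen <- generateSession(config, seed)
    session <- gen$session
    truth <- gen$truth
  }
  pos <- computeSpeed(session@position, config$behavior$speed_smoothing_sigma_s)
  segments <- segmentMotion(pos, config$behavior$speed_threshold_cm_s)
  session@position <- pos
  immoIv <- segmentsToIntervals(segments, "immobility")

  lfp <- session@lfp
  filt <- rippleBandpass(lfp, config$swr_detection$ripple_band)
  env <- consensusEnvelope(filt, lfp@sampleRateHz, lfp@t0S, immoIv,
                           config$swr_detection$envelope_smoothing_sigma_ms,
                           config$swr_detection$use_power)
  noise <- estimateNoiseThreshold(env,
                                  percentile = config$swr_detection$noise_percentile,
                                  nBins = config$swr_detection$mode_bins)
  events <- detectSwrs(env, noise, segments,
                       config$swr_detection$min_event_ms / 1000)
  bp <- swrBandPower(lfp, events, config$swr_detection$ripple_band,
                     config$swr_detection$spectrogram_window_s,
                     config$swr_detection$spectrogram_step_s)
  events$band_power_z <- bp$eventZ

  classification <- classifyUnits(session, segments, events, config)
  events <- assignContent(events, classification, session@units)
  counts <- contentCounts(events)
  propSummary <- eventPropertySummary(events)
  latency <- inSwrLatency(events, classification, session@units)
  coact <- coactivitySummary(events, session@units, classification,
                             config, seed)

  pfcTab <- pfcModulationTable(session, segments, events, config, seed)
  groupSummary <- NULL
  if (!is.null(pfcTab)) {
    perUnit <- unique(pfcTab[!is.na(pfcTab$group),
                             c("unit_id", "group"), drop = FALSE])
    sigUnits <- perUnit[perUnit$group != "unclassified", , drop = FALSE]
    nSig <- nrow(sigUnits)
    if (nSig > 0) {
      groups <- c("IAP-SWR+", "MAP-SWR+", "IAP/MAP-SWR-", "IAP-and-MAP-SWR+")
      combos <- c(2, 2, 3, 1)
      observed <- vapply(groups, function(gr) sum(sigUnits$group == gr),
                         numeric(1))
      expected <- expectedGroupCounts(nSig)
      pvals <- vapply(seq_along(groups), function(k)
        groupBinomialTest(observed[k], nSig, combos[k]), numeric(1))
      groupSummary <- data.frame(group = groups, observed = observed,
                                 expected = as.numeric(expected),
                                 combos = combos, binomial_p = pvals,
                                 n_significant = nSig,
                                 stringsAsFactors = FALSE)
    }
  }

  # well-entry PETH similarity and outside-SWR coincidence per PFC group
  entries <- session@wellEvents$time_s[session@wellEvents$kind == "entry"]
  tcfg <- config$temporal
  similarity <- NULL; coincidence <- NULL
  if (length(entries) && !is.null(pfcTab)) {
    peth <- function(u) wellEntryPeth(u, entries, tcfg$peth_window_s,
                                      tcfg$peth_bin_s,
                                      tcfg$peth_smoothing_sigma_s)
    iapIds <- classification$unit_id[classification$place_class == "IAP"]
    mapIds <- classification$unit_id[classification$place_class == "MAP"]
    iapPeths <- lapply(session@units[iapIds], peth)
    mapPeths <- lapply(session@units[mapIds], peth)
    iapTrains <- session@units[iapIds]
    mapTrains <- session@units[mapIds]
    perUnit <- unique(pfcTab[!is.na(pfcTab$group), c("unit_id", "group")])
    for (k in seq_len(nrow(perUnit))) {
      u <- session@units[[perUnit$unit_id[k]]]
      if (length(iapPeths) && length(mapPeths)) {
        simd <- patternSimilarityIndex(peth(u), iapPeths, mapPeths)
        if (length(simd))
          similarity <- rbind(similarity, data.frame(
            unit_id = u@unitId, group = perUnit$group[k],
            median_similarity = median(simd), n_pairs = length(simd),
            stringsAsFactors = FALSE))
      }
      coind <- coincidenceIndex(u, iapTrains, mapTrains, events,
                                tcfg$coincidence_bin_s,
                                tcfg$coincidence_window_s,
                                tcfg$min_coincidences)
      if (length(coind))
        coincidence <- rbind(coincidence, data.frame(
          unit_id = u@unitId, group = perUnit$group[k],
          median_coincidence = median(coind), n_pairs = length(coind),
          stringsAsFactors = FALSE))
    }
  }

  regression <- NULL
  if (!is.null(pfcTab)) {
    wide <- data.frame(
      unit_id = unique(pfcTab$unit_id), stringsAsFactors = FALSE)
    for (cls in c("MAP-only", "IAP-only", "joint")) {
      v <- pfcTab$i_swr[match(paste(wide$unit_id, cls),
                              paste(pfcTab$unit_id, pfcTab$swr_class))]
      wide[[c("MAP-only" = "i_map", "IAP-only" = "i_iap",
              "joint" = "i_joint")[[cls]]]] <- v
    }
    ok <- complete.cases(wide[, c("i_joint", "i_map", "i_iap")])
    if (sum(ok) >= 3)
      regression <- tryCatch(jointModulationRegression(wide[ok, ]),
                             error = function(e) NULL)
  }

  report <- structure(list(
    segments = segments, swr_events = events, noise_threshold = noise$threshold,
    classification = classification, content_counts = counts,
    property_summary = propSummary, latency = latency, coactivity = coact,
    pfc_modulation = pfcTab, group_summary = groupSummary,
    similarity = similarity, coincidence = coincidence,
    regression = regression, truth = truth,
    provenance = list(seed = seed, config_hash = configHash(config),
                      package_version = as.character(utils::packageVersion("ripplecontent")))),
    class = "ReportBundle")

  if (!is.null(outDir)) persistReport(report, outDir)
  report
}

persistReport <- function(report, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  writeCsv17(report$segments, file.path(outDir, "segments.csv"))
  ev <- report$swr_events
  writeCsv17(ev, file.path(outDir, "swr_events.csv"))
  writeCsv17(report$classification, file.path(outDir, "unit_classification.csv"))
  cc <- report$content_counts
  writeLines(jsonlite::toJSON(cc[c("n_map_only", "n_iap_only", "n_joint",
                                   "n_total", "expected_joint",
                                   "expected_joint_exact", "chi2_stat",
                                   "p_value")],
                              auto_unbox = TRUE, digits = NA),
             file.path(outDir, "content_counts.json"))
  if (!is.null(report$coactivity))
    writeCsv17(report$coactivity, file.path(outDir, "coactivity.csv"))
  writeCsv17(report$latency$latencies, file.path(outDir, "latency.csv"))
  if (!is.null(report$pfc_modulation))
    writeCsv17(report$pfc_modulation, file.path(outDir, "pfc_modulation.csv"))
  if (!is.null(report$group_summary))
    writeLines(jsonlite::toJSON(report$group_summary, digits = NA,
                                dataframe = "rows"),
               file.path(outDir, "group_summary.json"))
  if (!is.null(report$similarity))
    writeCsv17(report$similarity, file.path(outDir, "similarity.csv"))
  if (!is.null(report$coincidence))
    writeCsv17(report$coincidence, file.path(outDir, "coincidence.csv"))
  invisible(outDir)
}

#' Verify the published arithmetic anchors
#'
#' Recomputes, from printed inputs alone, every quantity of the source
#' analysis that is checkable without data: the independence expectation
#' for joint SWR counts from the published class counts (12881, 5009,
#' 1311), the class percentages, the pure-event share, the chi-square
#' significance, the expected PFC group counts for 70 modulated units
#' under the 8-combination rule, and the single-well / equal-well
#' specificity anchors.
#'
#' @return data.frame: \code{check}, \code{value}, \code{expected},
#'   \code{pass}.
#' @examples
#' verifyPublishedAnchors()
#' @export
verifyPublishedAnchors <- function() {
  cc <- contentCounts(c(n_map_only = 12881, n_iap_only = 5009, n_joint = 1311))
  eg <- expectedGroupCounts(70)
  rows <- list(
    list("expected joint SWR count", cc$expected_joint, 4671),
    list("expected joint percentage", round(100 * cc$expected_joint_exact / cc$n_total), 24),
    list("MAP-only percentage", round(100 * cc$n_map_only / cc$n_total), 67),
    list("IAP-only percentage", round(100 * cc$n_iap_only / cc$n_total), 26),
    list("joint percentage", round(100 * cc$n_joint / cc$n_total), 7),
    list("pure-event percentage", round(100 * (cc$n_map_only + cc$n_iap_only) / cc$n_total), 93),
    list("chi-square p below 1e-4", as.numeric(cc$p_value < 1e-4), 1),
    list("expected IAP-SWR+ count (n=70)", unname(eg[["IAP-SWR+"]]), 18),
    list("expected MAP-SWR+ count (n=70)", unname(eg[["MAP-SWR+"]]), 18),
    list("expected IAP/MAP-SWR- count (n=70)", unname(eg[["IAP/MAP-SWR-"]]), 26),
    list("expected IAP-and-MAP-SWR+ count (n=70)", unname(eg[["IAP-and-MAP-SWR+"]]), 9),
    list("single-well specificity", wellSpecificity(c(5, 0, 0, 0)), 1),
    list("equal-well specificity", wellSpecificity(c(2, 2, 2, 2)), 0))
  out <- data.frame(
    check = vapply(rows, `[[`, character(1), 1),
    value = vapply(rows, function(r) as.numeric(r[[2]]), numeric(1)),
    expected = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)),
    stringsAsFactors = FALSE)
  out$pass <- abs(out$value - out$expected) < 1e-9
  out
}
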