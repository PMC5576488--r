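# Shared fixtures and independent oracles. Expensive objects (the default
# 30-min session and its detection results) are built once per test run and
# cached in this environment.

fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = fixtureCache)) {
    assign(name, builder(), envir = fixtureCache)
  }
  get(name, envir = fixtureCache)
}

# A short session for cheap structural tests.
smallConfig <- function(lengthS = 240, lfpHz = 1000) {
  cfg <- defaultConfig()
  cfg$generator$session_length_s <- lengthS
  cfg$generator$lfp_sample_rate_hz <- lfpHz
  cfg
}

smallSession <- function() cached("smallSession", function() {
  generateSession(smallConfig(), seed = 11)
})

# The default-scale (30 min) study-condition session plus detection
# outputs, shared by the unit tests that need realistic statistics and by
# the acceptance checks.
defaultSessionFixture <- function() cached("defaultFixture", function() {
  cfg <- defaultConfig()
  gen <- generateSession(cfg, seed = 42)
  s <- gen$session
  pos <- computeSpeed(s@position, cfg$behavior$speed_smoothing_sigma_s)
  s@position <- pos
  seg <- segmentMotion(pos, cfg$behavior$speed_threshold_cm_s)
  immoIv <- cbind(seg$start_s[seg$label == "immobility"],
                  seg$end_s[seg$label == "immobility"])
  t0 <- Sys.time()
  filt <- rippleBandpass(s@lfp, cfg$swr_detection$ripple_band)
  env <- consensusEnvelope(filt, s@lfp@sampleRateHz, s@lfp@t0S, immoIv,
                           cfg$swr_detection$envelope_smoothing_sigma_ms)
  nm <- estimateNoiseThreshold(env)
  events <- detectSwrs(env, nm, seg, cfg$swr_detection$min_event_ms / 1000)
  detectSecs <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  t0 <- Sys.time()
  cls <- classifyUnits(s, seg, events, cfg)
  classifySecs <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  eventsCls <- assignContent(events, cls, s@units)
  list(config = cfg, session = s, truth = gen$truth, segments = seg,
       envelope = env, noise = nm, events = eventsCls,
       classification = cls, detectSecs = detectSecs,
       classifySecs = classifySecs)
})

# Match detected events against truth by any temporal overlap.
matchEvents <- function(truth, detected) {
  ovl <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))
  hit <- vapply(seq_len(nrow(truth)), function(i)
    any(ovl(truth$start_s[i], truth$end_s[i],
            detected$start_s, detected$end_s) > 0), logical(1))
  tp <- vapply(seq_len(nrow(detected)), function(i)
    any(ovl(detected$start_s[i], detected$end_s[i],
            truth$start_s, truth$end_s) > 0), logical(1))
  boundaryErr <- unlist(lapply(which(hit), function(i) {
    j <- which(ovl(truth$start_s[i], truth$end_s[i],
                   detected$start_s, detected$end_s) > 0)[1]
    c(abs(detected$start_s[j] - truth$start_s[i]),
      abs(detected$end_s[j] - truth$end_s[i]))
  }))
  matchedClass <- vapply(seq_len(nrow(truth)), function(i) {
    j <- which(ovl(truth$start_s[i], truth$end_s[i],
                   detected$start_s, detected$end_s) > 0)[1]
    if (is.na(j) || is.null(detected$content_class)) NA_character_
    else detected$content_class[j]
  }, character(1))
  list(recall = mean(hit), precision = mean(tp),
       medianBoundaryErrS = median(boundaryErr), matchedClass = matchedClass)
}

# O(n^2) brute-force correlogram oracle: all pairwise lags, inclusive
# window, identical binning to the implementation.
bruteCorrelogram <- function(a, b, binS, windowS, removeSelf = FALSE) {
  nb <- max(2L, round(windowS / binS))
  edges <- seq(-windowS / 2, windowS / 2, length.out = nb + 1L)
  d <- as.vector(outer(b, a, "-"))
  d <- d[d >= edges[1] & d <= edges[nb + 1L]]
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = nb)
  n <- length(d)
  if (removeSelf) {
    zeroBin <- findInterval(0, edges, rightmost.closed = TRUE)
    counts[zeroBin] <- counts[zeroBin] - length(a)
    n <- n - length(a)
  }
  list(counts = counts, n = n)
}

# Brute-force nearby-spike proportion oracle.
bruteNearby <- function(a, b, nearS, farS) {
  dir <- function(x, y) {
    near <- vapply(x, function(s) any(abs(y - s) <= nearS), logical(1))
    far <- vapply(x, function(s) any(abs(y - s) <= farS), logical(1))
    if (!sum(far)) return(NA_real_)
    sum(near) / sum(far)
  }
  mean(c(dir(a, b), dir(b, a)))
}

# Brute-force immobility well-rate oracle: O(n^2) point-in-interval scan.
bruteWellRate <- function(spikes, intervals, swrIv) {
  inAny <- function(x, iv) any(iv[, 1] <= x & x < iv[, 2])
  keepTime <- 0
  for (i in seq_len(nrow(intervals))) {
    grid <- seq(intervals[i, 1], intervals[i, 2], by = 1e-4)
    if (nrow(swrIv)) {
      inSwr <- vapply(grid, inAny, logical(1), iv = swrIv)
      keepTime <- keepTime + sum(!inSwr) * 1e-4
    } else keepTime <- keepTime + (intervals[i, 2] - intervals[i, 1])
  }
  nSp <- sum(vapply(spikes, function(s)
    inAny(s, intervals) && !(nrow(swrIv) && inAny(s, swrIv)), logical(1)))
  nSp / keepTime
}

poissonTrain <- function(rateHz, lengthS) sort(runif(rpois(1, rateHz * lengthS), 0, lengthS))

# Independent point-in-interval check (linear scan, half-open intervals).
pointsInIntervalsOracle <- function(x, iv) {
  vapply(x, function(p) any(iv[, 1] <= p & p < iv[, 2]), logical(1))
}
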