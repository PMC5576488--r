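makeLfp <- function(x, fs = 1500, nch = 1) {
  LfpBundle(matrix(rep(x, nch), ncol = nch), fs)
}

test_that("ripple band-pass has the required pass/stop behavior", {
  fs <- 1500
  t <- seq(0, 4, by = 1 / fs)
  pass <- rippleBandpass(makeLfp(sin(2 * pi * 200 * t), fs))[, 1]
  mid <- seq(fs, 3 * fs)
  gain200 <- sqrt(mean(pass[mid]^2)) / sqrt(0.5)
  expect_gt(gain200, 0.9); expect_lt(gain200, 1.1)

  stop50 <- rippleBandpass(makeLfp(sin(2 * pi * 50 * t), fs))[, 1]
  atten <- 20 * log10(sqrt(0.5) / sqrt(mean(stop50[mid]^2)))
  expect_gt(atten, 20)

  # Parseval: white-noise variance shrinks by the band fraction
  set.seed(1)
  wn <- rnorm(fs * 30)
  filtered <- rippleBandpass(makeLfp(wn, fs))[, 1]
  expect_lt(abs(var(filtered) / (var(wn) * 100 / 750) - 1), 0.1)

  expect_error(rippleBandpass(LfpBundle(matrix(0, 100, 1), 1000),
                              band = c(150, 600)), "too low")
})

test_that("consensus envelope tracks bursts, resists artifacts, normalizes", {
  fs <- 1500
  t <- seq(0, 20, by = 1 / fs)
  burst <- as.numeric(t > 10 & t < 10.5) * sin(2 * pi * 200 * t)
  m <- matrix(rep(burst, 3), ncol = 3)
  env <- consensusEnvelope(m, fs)
  raw <- env$value * env$normSd + env$normMean
  inBurst <- t > 10.05 & t < 10.45
  expect_lt(max(abs(raw[inBurst] - 1)), 0.1)

  # median suppresses a single-channel artifact
  quiet <- matrix(rnorm(length(t) * 3, sd = 0.01), ncol = 3)
  quiet[t > 5 & t < 5.2, 1] <- quiet[t > 5 & t < 5.2, 1] + 100
  env2 <- consensusEnvelope(quiet, fs)
  raw2 <- env2$value * env2$normSd + env2$normMean
  expect_lt(max(raw2[t > 5 & t < 5.2]), 50)

  # normalization: mean 0, SD 1 over the normalization mask
  expect_lt(abs(mean(env$value[env$immobilityMask])), 1e-8)
  expect_equal(sd(env$value[env$immobilityMask]), 1, tolerance = 1e-6)

  expect_error(consensusEnvelope(m[, 1:2], fs), "at least 3 channels")

  # squared-power convention is a monotone rescaling of the same envelope
  envP <- consensusEnvelope(m, fs, usePower = TRUE)
  rawP <- envP$value * envP$normSd + envP$normMean
  expect_equal(rawP, raw^2, tolerance = 1e-9)
})

test_that("mode-mirrored noise threshold matches the Gaussian closed form", {
  set.seed(7)
  mu <- 5; sigma <- 1
  v <- rnorm(3e5, mu, sigma)
  nm <- estimateNoiseThreshold(v, immobilityMask = rep(TRUE, length(v)))
  closedForm <- mu + qnorm(0.9999) * sigma
  expect_lt(abs(nm$threshold - closedForm) / closedForm, 0.05)
  expect_gte(nm$threshold, nm$modeValue)
  # mirrored distribution is symmetric about the mode
  expect_lt(abs(nm$mirroredQuantile(0.5) - nm$modeValue), 0.05)

  # robust to 1% high-amplitude contamination
  vC <- c(v, rnorm(3e3, mu + 8 * sigma, 0.5 * sigma))
  nmC <- estimateNoiseThreshold(vC, immobilityMask = rep(TRUE, length(vC)))
  expect_lt(abs(nmC$threshold - nm$threshold) / nm$threshold, 0.10)

  # supra-threshold mass of the noise itself is at the percentile level
  expect_lt(mean(v > nm$threshold), 3e-4)

  expect_error(estimateNoiseThreshold(rep(1, 2e4),
                                      immobilityMask = rep(TRUE, 2e4)),
               "degenerate")
  expect_error(estimateNoiseThreshold(rnorm(100),
                                      immobilityMask = rep(TRUE, 100)),
               "10\\^4")
})

fakeEnvelope <- function(value, fs = 1000) {
  structure(list(timeS = (seq_along(value) - 1) / fs, value = value,
                 normMean = 0, normSd = 1, nChannels = 3, sampleRateHz = fs,
                 immobilityMask = rep(TRUE, length(value))),
            class = "ConsensusEnvelope")
}

test_that("event detection enforces duration, boundaries and the speed gate", {
  fs <- 1000
  nm <- structure(list(modeValue = 0, threshold = 3,
                       mirroredQuantile = identity), class = "NoiseModel")
  v <- rep(-0.5, 10 * fs)
  # 15 ms supra-threshold burst: below the minimum duration
  v[2000:2014] <- 5
  expect_equal(nrow(detectSwrs(fakeEnvelope(v, fs), nm)), 0)

  # 30 ms burst: detected, extended to the mean crossings
  v2 <- rep(-0.5, 10 * fs)
  v2[3000:3200] <- 0.5          # above mean, below threshold
  v2[3050:3090] <- 5            # 40 ms above threshold
  ev <- detectSwrs(fakeEnvelope(v2, fs), nm)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, 2999 / fs, tolerance = 2 / fs)
  expect_equal(ev$end_s, 3201 / fs, tolerance = 2 / fs)
  expect_equal(ev$peak_env, 5)

  # the same burst during movement is discarded
  segMove <- data.frame(label = "movement", start_s = 0, end_s = 10)
  expect_equal(nrow(detectSwrs(fakeEnvelope(v2, fs), nm, segMove)), 0)

  # events are sorted, non-overlapping, >= 20 ms
  v3 <- rep(-0.5, 20 * fs)
  for (s in c(2000, 5000, 8000, 11000)) v3[s:(s + 40)] <- 4
  ev3 <- detectSwrs(fakeEnvelope(v3, fs), nm)
  expect_equal(nrow(ev3), 4)
  expect_true(all(diff(ev3$start_s) > 0))
  expect_true(all(ev3$start_s[-1] >= ev3$end_s[-nrow(ev3)]))
  expect_true(all(ev3$duration_s >= 0.02))
})

test_that("threshold is invariant to affine rescaling of the raw LFP", {
  gen <- smallSession()
  s <- gen$session
  pos <- computeSpeed(s@position)
  seg <- segmentMotion(pos)
  immoIv <- cbind(seg$start_s[seg$label == "immobility"],
                  seg$end_s[seg$label == "immobility"])
  fs <- s@lfp@sampleRateHz
  filt <- rippleBandpass(s@lfp)
  env1 <- consensusEnvelope(filt, fs, 0, immoIv)
  env2 <- consensusEnvelope(filt * 7.3, fs, 0, immoIv)
  nm1 <- estimateNoiseThreshold(env1)
  nm2 <- estimateNoiseThreshold(env2)
  expect_equal(nm1$threshold, nm2$threshold, tolerance = 1e-6)
  ev1 <- detectSwrs(env1, nm1, seg)
  ev2 <- detectSwrs(env2, nm2, seg)
  expect_equal(ev1$start_s, ev2$start_s, tolerance = 1e-9)
})

test_that("detector recovers injected events and recall grows with SNR", {
  gen <- smallSession()
  s <- gen$session
  pos <- computeSpeed(s@position)
  seg <- segmentMotion(pos)
  immoIv <- cbind(seg$start_s[seg$label == "immobility"],
                  seg$end_s[seg$label == "immobility"])
  runDetect <- function(sess) {
    filt <- rippleBandpass(sess@lfp)
    env <- consensusEnvelope(filt, sess@lfp@sampleRateHz, 0, immoIv)
    detectSwrs(env, estimateNoiseThreshold(env), seg)
  }
  m <- matchEvents(gen$truth@swrTruth, runDetect(s))
  expect_gt(m$recall, 0.9)
  expect_lt(m$medianBoundaryErrS, 0.015)

  recalls <- vapply(c(2, 3.5, 5), function(snr) {
    cfg <- smallConfig()
    cfg$generator$ripple_snr <- snr
    g <- generateSession(cfg, seed = 11)
    p <- computeSpeed(g$session@position)
    sg <- segmentMotion(p)
    iIv <- cbind(sg$start_s[sg$label == "immobility"],
                 sg$end_s[sg$label == "immobility"])
    filt <- rippleBandpass(g$session@lfp)
    env <- consensusEnvelope(filt, g$session@lfp@sampleRateHz, 0, iIv)
    ev <- detectSwrs(env, estimateNoiseThreshold(env), sg)
    matchEvents(g$truth@swrTruth, ev)$recall
  }, numeric(1))
  expect_true(all(diff(recalls) >= -1e-9))
  expect_gt(recalls[3], 0.9)
})

test_that("noise-only sessions produce few spurious events", {
  cfg <- smallConfig(lengthS = 300)
  cfg$generator$swr_rate_hz <- 0
  g <- generateSession(cfg, seed = 13)
  pos <- computeSpeed(g$session@position)
  seg <- segmentMotion(pos)
  immoIv <- cbind(seg$start_s[seg$label == "immobility"],
                  seg$end_s[seg$label == "immobility"])
  filt <- rippleBandpass(g$session@lfp)
  env <- consensusEnvelope(filt, g$session@lfp@sampleRateHz, 0, immoIv)
  ev <- detectSwrs(env, estimateNoiseThreshold(env), seg)
  expect_lt(nrow(ev), 12)  # well under one spurious event per 25 s
})

test_that("event-aligned band power is z-normalized and elevated in ripples", {
  gen <- smallSession()
  s <- gen$session
  tru <- gen$truth@swrTruth
  bp <- swrBandPower(s@lfp, tru)
  expect_lt(abs(mean(bp$windowZ)), 1e-8)
  expect_equal(sd(bp$windowZ), 1, tolerance = 1e-6)
  expect_gt(mean(bp$eventZ, na.rm = TRUE), 2)

  # random non-event times sit near zero
  set.seed(31)
  sched <- gen$truth@boutSchedule
  immo <- sched[sched$state == "immobility", ]
  rt <- runif(50, 0, max(s@position@timeS) - 1)
  keep <- !pointsInIntervalsOracle(rt, cbind(tru$start_s - 0.3, tru$end_s + 0.3))
  nullEv <- data.frame(start_s = rt[keep])
  bpN <- swrBandPower(s@lfp, nullEv)
  expect_lt(abs(mean(bpN$eventZ, na.rm = TRUE)), 0.5)
})
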