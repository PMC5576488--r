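test_that("generation is deterministic in the seed", {
  cfg <- smallConfig(lengthS = 120)
  a <- generateSession(cfg, seed = 9)
  b <- generateSession(cfg, seed = 9)
  c <- generateSession(cfg, seed = 10)
  expect_identical(a$session@position@xCm, b$session@position@xCm)
  expect_identical(lapply(a$session@units, spikeTimes),
                   lapply(b$session@units, spikeTimes))
  expect_identical(a$session@lfp@samples[1:1000, 1],
                   b$session@lfp@samples[1:1000, 1])
  expect_identical(a$truth@swrTruth$start_s, b$truth@swrTruth$start_s)
  expect_false(identical(a$session@position@xCm, c$session@position@xCm))
})

test_that("bout durations concentrate around the configured mean", {
  cfg <- defaultConfig()
  cfg$generator$session_length_s <- 6900  # ~1000 bouts at 6.6 s
  beh <- generateBehavior(cfg, seed = 21)
  d <- beh$boutSchedule$end_s - beh$boutSchedule$start_s
  d <- d[-length(d)]  # last bout truncated at session end
  expect_gt(length(d), 900)
  expect_lt(abs(mean(d) - 6.6) / 6.6, 0.05)
})

test_that("behavioral states have the intended kinematics", {
  gen <- smallSession()
  cfg <- smallConfig()
  pos <- computeSpeed(gen$session@position)
  sched <- gen$truth@boutSchedule
  immoIv <- cbind(sched$start_s[sched$state == "immobility"],
                  sched$end_s[sched$state == "immobility"])
  moveIv <- cbind(sched$start_s[sched$state == "movement"],
                  sched$end_s[sched$state == "movement"])
  immoMask <- pointsInIntervalsOracle(pos@timeS, immoIv)
  expect_gt(mean(pos@speedCmS[immoMask] < 4), 0.99)
  # movement speed profile peaks above 10 cm/s
  moveMask <- pointsInIntervalsOracle(pos@timeS, moveIv)
  expect_gt(max(pos@speedCmS[moveMask]), 10)
  # session too short for a bout
  cfgBad <- defaultConfig()
  cfgBad$generator$session_length_s <- 5
  expect_error(generateBehavior(cfgBad, 1), "too short")
})

test_that("CA1 generator respects rates and state gating", {
  cfg <- smallConfig(lengthS = 600)
  beh <- generateBehavior(cfg, seed = 31)
  ca1 <- generateCa1Units(cfg, beh, seed = 31)
  sched <- beh$boutSchedule

  # IAP spike count within the Poisson 99% interval for rate x home time
  lab <- ca1$labels
  iapId <- lab$unit_id[lab$label == "IAP"][1]
  home <- lab$home_well[lab$unit_id == iapId]
  sel <- sched$state == "immobility" & sched$well_id == home
  tHome <- sum(sched$end_s[sel] - sched$start_s[sel])
  lambda <- cfg$generator$iap_rate_hz * tHome
  n <- length(spikeTimes(ca1$units[[iapId]]))
  expect_gt(n, qpois(0.005, lambda))
  expect_lt(n, qpois(0.995, lambda))

  # MAP spikes only during movement (content spikes not yet injected)
  mapId <- lab$unit_id[lab$label == "MAP"][1]
  moveIv <- cbind(sched$start_s[sched$state == "movement"],
                  sched$end_s[sched$state == "movement"])
  st <- spikeTimes(ca1$units[[mapId]])
  expect_true(all(pointsInIntervalsOracle(st, moveIv)))

  expect_error({
    cfg0 <- cfg; cfg0$generator$n_map <- 0; cfg0$generator$n_iap <- 0
    generateCa1Units(cfg0, beh, 1)
  }, "at least one CA1 unit")
})

test_that("injected SWRs land inside immobility with multinomial class counts", {
  cfg <- smallConfig(lengthS = 1500, lfpHz = 1000)
  cfg$generator$swr_rate_hz <- 0.6
  gen <- generateSession(cfg, seed = 51)
  tru <- gen$truth@swrTruth
  sched <- gen$truth@boutSchedule
  immoIv <- cbind(sched$start_s[sched$state == "immobility"],
                  sched$end_s[sched$state == "immobility"])
  expect_true(all(pointsInIntervalsOracle(tru$start_s, immoIv)))
  expect_true(all(pointsInIntervalsOracle(tru$end_s - 1e-9, immoIv)))
  expect_gt(nrow(tru), 300)

  counts <- table(factor(tru$class, c("MAP-only", "IAP-only", "joint")))
  p <- cfg$generator$class_probs
  n <- nrow(tru)
  for (k in 1:3) {
    expect_lt(abs(counts[k] - n * p[k]), 2.58 * sqrt(n * p[k] * (1 - p[k])) + 1,
              label = sprintf("class %d count %d vs expected %.1f",
                              k, counts[k], n * p[k]))
  }
  # class counts sum to the event count
  expect_equal(sum(counts), n)
})

test_that("injected bursts raise in-band power by the configured SNR", {
  gen <- smallSession()
  cfg <- smallConfig()
  s <- gen$session; tru <- gen$truth@swrTruth
  filt <- rippleBandpass(s@lfp)
  t <- s@lfp@t0S + (seq_len(nrow(filt)) - 1) / s@lfp@sampleRateHz
  inEv <- pointsInIntervalsOracle(t, cbind(tru$start_s, tru$end_s))
  sched <- gen$truth@boutSchedule
  immoIv <- cbind(sched$start_s[sched$state == "immobility"],
                  sched$end_s[sched$state == "immobility"])
  quietMask <- pointsInIntervalsOracle(t, immoIv) & !inEv
  rmsIn <- sqrt(mean(filt[inEv, 1]^2))
  rmsOut <- sqrt(mean(filt[quietMask, 1]^2))
  expect_gt(rmsIn, cfg$generator$ripple_snr / 2 * rmsOut)
})

test_that("zero SWR rate yields noise-only LFP and empty truth", {
  cfg <- smallConfig(lengthS = 60)
  cfg$generator$swr_rate_hz <- 0
  gen <- generateSession(cfg, seed = 3)
  expect_equal(nrow(gen$truth@swrTruth), 0)
})

test_that("PFC in-event firing matches the configured class gain", {
  cfg <- smallConfig(lengthS = 1200)
  cfg$generator$swr_rate_hz <- 0.5
  beh <- generateBehavior(cfg, seed = 61)
  ca1 <- generateCa1Units(cfg, beh, seed = 61)
  lf <- generateLfpWithSwrs(cfg, beh, ca1, seed = 61)
  pfc <- generatePfcUnits(cfg, beh, lf$swrTruth, seed = 61)
  lab <- pfc$labels
  # a both-excited unit has a flat behavior profile: in-event rate should be
  # gain x baseline
  uid <- lab$unit_id[lab$pfc_group == "both+"][1]
  st <- spikeTimes(pfc$units[[uid]])
  iv <- cbind(lf$swrTruth$start_s, lf$swrTruth$end_s)
  tIn <- sum(iv[, 2] - iv[, 1])
  nIn <- sum(pointsInIntervalsOracle(st, iv))
  lambda <- cfg$generator$pfc_gain_excited * cfg$generator$pfc_baseline_hz * tIn
  expect_gt(nIn, qpois(0.005, lambda))
  expect_lt(nIn, qpois(0.995, lambda))

  # unit gain 1 everywhere: homogeneous Poisson total count
  cfg1 <- cfg
  cfg1$generator$pfc_gain_excited <- 1
  cfg1$generator$pfc_gain_inhibited <- 1
  cfg1$generator$pfc_behavior_gain <- 1
  pfc1 <- generatePfcUnits(cfg1, beh, lf$swrTruth, seed = 62)
  n1 <- length(spikeTimes(pfc1$units[[1]]))
  lam1 <- cfg$generator$pfc_baseline_hz * cfg1$generator$session_length_s
  expect_gt(n1, qpois(0.005, lam1)); expect_lt(n1, qpois(0.995, lam1))

  # reproducibility
  pfcB <- generatePfcUnits(cfg, beh, lf$swrTruth, seed = 61)
  expect_identical(spikeTimes(pfc$units[[1]]), spikeTimes(pfcB$units[[1]]))
})
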