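test_that("cross-correlograms localize known lags and normalize to 1", {
  a <- seq(1, 100, by = 0.5)
  ccSelf <- crossCorrelogram(a, a, binS = 0.01, windowS = 0.2)
  expect_equal(ccSelf$lagsS[which.max(ccSelf$values)], 0, tolerance = 0.006)
  expect_equal(sum(ccSelf$values), 1)

  ccShift <- crossCorrelogram(a, a + 0.1, binS = 0.01, windowS = 0.5)
  expect_lt(abs(ccShift$lagsS[which.max(ccShift$values)] - 0.1), 0.011)
  expect_error(crossCorrelogram(numeric(0), a), "nonempty")

  # transition-period restriction: only spikes near reference times enter
  ccAll <- crossCorrelogram(a, a, 0.01, 0.2)
  ccWin <- crossCorrelogram(a, a, 0.01, 0.2, eventTimes = c(10, 50),
                            eventWindowS = 1.5)
  expect_lt(ccWin$nEvents, ccAll$nEvents)
  # half-open restriction windows, matching the package's convention
  oracleA <- a[(a >= 8.5 & a < 11.5) | (a >= 48.5 & a < 51.5)]
  expect_identical(ccWin$counts,
                   crossCorrelogram(oracleA, oracleA, 0.01, 0.2)$counts)
})

test_that("correlograms equal the quadratic brute-force oracle exactly", {
  set.seed(71)
  for (i in 1:20) {
    a <- poissonTrain(5, 100)
    b <- poissonTrain(5, 100)
    binS <- sample(c(0.01, 0.05, 0.1), 1)
    windowS <- sample(c(0.5, 1, 6.6), 1)
    cc <- crossCorrelogram(a, b, binS, windowS)
    oracle <- bruteCorrelogram(a, b, binS, windowS)
    expect_identical(cc$counts, oracle$counts)
    expect_identical(cc$nEvents, oracle$n)
    # time-reversal symmetry: cross(a,b) at lag = cross(b,a) at -lag
    ccR <- crossCorrelogram(b, a, binS, windowS)
    expect_identical(cc$counts, rev(ccR$counts))
  }
  # autocorrelogram: self pairs removed, matches oracle
  for (i in 1:5) {
    a <- poissonTrain(8, 60)
    ac <- autoCorrelogram(a, 0.01, 0.5)
    oracle <- bruteCorrelogram(a, a, 0.01, 0.5, removeSelf = TRUE)
    expect_identical(ac$counts, oracle$counts)
    expect_identical(ac$nEvents, oracle$n)
    expect_identical(ac$values, rev(ac$values))  # exact symmetry
  }
})

test_that("autocorrelograms are flat for Poisson and rhythmic for theta", {
  set.seed(72)
  a <- poissonTrain(10, 400)
  ac <- autoCorrelogram(a, 0.01, 0.5)
  # flat: chi-square goodness of fit against uniform bins
  expected <- sum(ac$counts) / length(ac$counts)
  chi2 <- sum((ac$counts - expected)^2 / expected)
  expect_gt(pchisq(chi2, length(ac$counts) - 1, lower.tail = FALSE), 1e-3)

  # 8 Hz-modulated train: side peaks at +/- 125 ms
  t <- seq(0, 400, by = 1e-3)
  lam <- 10 * (1 + 0.8 * sin(2 * pi * 8 * t))
  cand <- poissonTrain(18, 400)
  keep <- runif(length(cand)) < approx(t, lam, cand)$y / 18
  theta <- cand[keep]
  acT <- autoCorrelogram(theta, 0.005, 0.4)
  at <- function(lag) acT$values[which.min(abs(acT$lagsS - lag))]
  expect_gt(at(0.125), at(0.0625))
  expect_gt(at(-0.125), at(-0.0625))

  # state filtering selects spikes by concurrent speed
  tt <- seq(0, 100, by = 1 / 30)
  pos <- PositionTrace(tt, rep(0, length(tt)), rep(0, length(tt)),
                       ifelse(tt < 50, 0, 10))
  sp <- c(seq(1, 49, by = 0.1), seq(51, 99, by = 0.1))
  acS <- autoCorrelogram(sp, 0.01, 0.5, position = pos,
                         speedRange = c(4, Inf))
  expect_lt(acS$nEvents, autoCorrelogram(sp, 0.01, 0.5)$nEvents)
})

test_that("nearby-spike proportion matches definitions and the oracle", {
  a <- seq(1, 50, by = 0.7)
  expect_equal(nearbySpikeProportion(a, a), 1)
  # partner spikes offset by 1 s, trains 4 s apart: far yes, near no
  b <- seq(1, 50, by = 4) + 1
  a2 <- seq(1, 50, by = 4)
  expect_equal(nearbySpikeProportion(a2, b), 0)
  set.seed(73)
  for (i in 1:10) {
    x <- poissonTrain(2, 60)
    y <- poissonTrain(2, 60)
    expect_equal(nearbySpikeProportion(x, y), bruteNearby(x, y, 0.05, 3.3))
  }
})

test_that("well-entry PETHs align, normalize, and recover PFC tuning", {
  entries <- c(100, 200, 300)
  spikes <- sort(c(entries + runif(30, 0, 1)))
  p <- wellEntryPeth(spikes, entries)
  expect_equal(max(p$normalizedRate), 1)
  expect_true(p$active)
  peakLag <- p$lagsS[which.max(p$normalizedRate)]
  expect_gt(peakLag, 0); expect_lt(peakLag, 1.2)
  expect_lt(max(p$normalizedRate[p$lagsS < -0.5]), 0.2)

  # immobility-onset synthetic PFC unit peaks within 1 s after entry
  gen <- defaultSessionFixture()
  truth <- gen$truth@unitLabels
  uid <- truth$unit_id[!is.na(truth$pfc_group) & truth$pfc_group == "IAP+"][1]
  ent <- gen$session@wellEvents$time_s[gen$session@wellEvents$kind == "entry"]
  pPfc <- wellEntryPeth(gen$session@units[[uid]], ent)
  expect_lt(abs(pPfc$lagsS[which.max(pPfc$normalizedRate)]), 1)

  expect_error(wellEntryPeth(spikes, numeric(0)), "at least one")
})

test_that("pattern similarity is signed toward the matching CA1 class", {
  mk <- function(v) structure(list(normalizedRate = v), class = "Peth")
  base <- sin(seq(0, 2 * pi, length.out = 100))
  pfc <- mk(base)
  iap <- mk(base)                      # identical
  map <- mk(-base)                     # anticorrelated
  d <- patternSimilarityIndex(pfc, list(iap), list(map))
  expect_equal(d, 2, tolerance = 1e-9)

  set.seed(74)
  dNull <- patternSimilarityIndex(mk(rnorm(100)),
                                  lapply(1:20, function(i) mk(rnorm(100))),
                                  lapply(1:20, function(i) mk(rnorm(100))))
  expect_lt(abs(median(dNull)), 0.3)
  # pairings involving a constant PETH are skipped, others retained
  expect_length(patternSimilarityIndex(pfc, list(mk(rep(1, 100))), list(map)),
                0)
  expect_length(patternSimilarityIndex(pfc, list(mk(rep(1, 100)), iap),
                                       list(map)), 1)
})

test_that("coincidence index detects shared rate modulation at zero lag", {
  set.seed(75)
  T <- 1200
  # common slow rate modulation drives both trains
  tgrid <- seq(0, T, by = 0.1)
  onOff <- rep(rep(c(1, 0), each = 33), length.out = length(tgrid))
  mkTrain <- function(base, gain) {
    cand <- poissonTrain(base * (1 + gain), T)
    keep <- runif(length(cand)) <
      (base * (1 + gain * approx(tgrid, onOff, cand)$y)) / (base * (1 + gain))
    cand[keep]
  }
  pfc <- mkTrain(4, 3)
  ca1Coupled <- mkTrain(3, 3)
  ca1Indep <- poissonTrain(3, T)
  dCoupled <- coincidenceIndex(pfc, list(ca1Coupled), list(ca1Indep))
  expect_gt(dCoupled, 2)
  dIndep <- coincidenceIndex(poissonTrain(4, T), list(poissonTrain(3, T)),
                             list(poissonTrain(3, T)))
  expect_lt(abs(dIndep), 3)

  # synthetic PFC groups are ordered IAP-locked > 0 > MAP-locked
  gen <- defaultSessionFixture()
  truth <- gen$truth@unitLabels
  cls <- gen$classification
  iapT <- gen$session@units[cls$unit_id[cls$place_class == "IAP"]]
  mapT <- gen$session@units[cls$unit_id[cls$place_class == "MAP"]]
  med <- function(grp) {
    uid <- truth$unit_id[!is.na(truth$pfc_group) & truth$pfc_group == grp][1]
    median(coincidenceIndex(gen$session@units[[uid]], iapT, mapT,
                            gen$events))
  }
  expect_gt(med("IAP+"), 0)
  expect_lt(med("MAP+"), 0)
})
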