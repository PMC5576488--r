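mkEvents <- function(n, durS = 0.1, gapS = 2, t0 = 10) {
  starts <- seq(t0, by = gapS, length.out = n)
  data.frame(start_s = starts, end_s = starts + durS)
}

test_that("modulation index follows its closed-form limits", {
  set.seed(91)
  ev <- mkEvents(200)
  # homogeneous Poisson: index near 0
  sp <- poissonTrain(10, max(ev$end_s) + 5)
  mi <- modulationIndex(sp, ev)
  expect_lt(abs(mi$iSwr), 0.2)

  # silent inside events, active outside: index -1
  spOut <- sp[!pointsInIntervalsOracle(sp, cbind(ev$start_s - 0.001,
                                                 ev$start_s + mi$meanDurationS))]
  miOut <- modulationIndex(spOut, ev)
  expect_equal(miOut$iSwr, -1, tolerance = 0.02)

  expect_error(modulationIndex(sp, ev[1:5, ]), "at least 10")
  expect_gte(mi$iSwr, -1)
})

test_that("circular permutation test is calibrated, powerful and reproducible", {
  set.seed(92)
  ev <- mkEvents(60)
  T <- max(ev$end_s) + 5
  # deterministic on a fixed seed
  sp <- poissonTrain(5, T)
  p1 <- circularPermutationTest(sp, ev, 200, seed = 7)
  p2 <- circularPermutationTest(sp, ev, 200, seed = 7)
  expect_identical(p1$p_value, p2$p_value)
  # p lies on the achievable grid
  expect_true(p1$p_value >= 1 / 200 && p1$p_value <= 1)

  # strong gain-5 modulation is maximally significant
  gain5 <- function() {
    base <- poissonTrain(6, T)
    extra <- unlist(lapply(seq_len(nrow(ev)), function(i)
      runif(rpois(1, 4 * 6 * 0.1), ev$start_s[i], ev$end_s[i])))
    sort(c(base, extra))
  }
  pG <- circularPermutationTest(gain5(), ev, 1000, seed = 8)
  expect_lte(pG$p_value, 0.001)
  expect_equal(pG$direction, "excited")

  # inhibition is detected and signed correctly
  spI <- poissonTrain(8, T)
  spI <- spI[!pointsInIntervalsOracle(spI, cbind(ev$start_s, ev$end_s))]
  pI <- circularPermutationTest(spI, ev, 500, seed = 9)
  expect_lt(pI$p_value, 0.05)
  expect_equal(pI$direction, "inhibited")

  expect_error(circularPermutationTest(c(5000), ev, 100, 1), "no spikes")
})

test_that("group mapping covers all nine significance combinations", {
  expect_equal(classifyGroup("excited", "n.s."), "IAP-SWR+")
  expect_equal(classifyGroup("excited", "inhibited"), "IAP-SWR+")
  expect_equal(classifyGroup("n.s.", "excited"), "MAP-SWR+")
  expect_equal(classifyGroup("inhibited", "excited"), "MAP-SWR+")
  expect_equal(classifyGroup("n.s.", "inhibited"), "IAP/MAP-SWR-")
  expect_equal(classifyGroup("inhibited", "n.s."), "IAP/MAP-SWR-")
  expect_equal(classifyGroup("inhibited", "inhibited"), "IAP/MAP-SWR-")
  expect_equal(classifyGroup("excited", "excited"), "IAP-and-MAP-SWR+")
  expect_equal(classifyGroup("n.s.", "n.s."), "unclassified")
  expect_error(classifyGroup("maybe", "n.s."))
})

test_that("expected group counts and the 8-combination bookkeeping hold", {
  eg <- expectedGroupCounts(70)
  expect_equal(unname(eg), c(18, 18, 26, 9))
  # the four groups cover all 8 significance combinations (the doubly
  # non-significant combination is excluded from the accounting)
  expect_equal(sum(c(2, 2, 3, 1)), 8)
  expect_equal(unname(expectedGroupCounts(8)), c(2, 2, 3, 1))
})

test_that("group binomial test agrees with an exact CDF summation oracle", {
  k <- 0:3
  oracle <- sum(choose(70, k) * (1 / 8)^k * (7 / 8)^(70 - k))
  expect_equal(groupBinomialTest(3, 70, 1), oracle)
  expect_lt(groupBinomialTest(3, 70, 1), 0.05)
  expect_equal(groupBinomialTest(3, 70, 1), 0.019, tolerance = 0.05)

  # central observation is not significant
  expect_gt(groupBinomialTest(round(70 / 8), 70, 1), 0.4)

  # closed form for observed = 0 of 8
  expect_equal(groupBinomialTest(0, 8, 1), (7 / 8)^8)

  # upper-tail direction
  kU <- 20:70
  oracleU <- sum(choose(70, kU) * (1 / 8)^kU * (7 / 8)^(70 - kU))
  expect_equal(groupBinomialTest(20, 70, 1), oracleU)
})

test_that("duration matching equalizes duration distributions", {
  set.seed(93)
  mkEv <- function(durs) data.frame(start_s = seq_along(durs) * 2,
                                    end_s = seq_along(durs) * 2 + durs)
  a <- mkEv(rlnorm(150, log(0.08), 0.3))
  b <- mkEv(rlnorm(150, log(0.08), 0.3))
  mSame <- durationMatchedControl(a, b, seed = 3)
  ksSame <- suppressWarnings(ks.test(mSame$eventsA$end_s - mSame$eventsA$start_s,
                                     mSame$eventsB$end_s - mSame$eventsB$start_s))
  expect_gt(ksSame$p.value, 0.05)

  # different distributions become indistinguishable after matching
  c2 <- mkEv(rlnorm(200, log(0.05), 0.25))
  d2 <- mkEv(rlnorm(200, log(0.12), 0.25))
  ksBefore <- suppressWarnings(ks.test(c2$end_s - c2$start_s,
                                       d2$end_s - d2$start_s))
  expect_lt(ksBefore$p.value, 1e-4)
  mDiff <- durationMatchedControl(c2, d2, seed = 3)
  ksAfter <- suppressWarnings(ks.test(mDiff$eventsA$end_s - mDiff$eventsA$start_s,
                                      mDiff$eventsB$end_s - mDiff$eventsB$start_s))
  expect_gt(ksAfter$p.value, 0.01)

  # seed reproducibility
  mRep <- durationMatchedControl(c2, d2, seed = 3)
  expect_identical(mDiff$indicesA, mRep$indicesA)
})

test_that("label permutation isolates class-selective modulation", {
  set.seed(94)
  n <- 60
  evA <- mkEvents(n, t0 = 10, gapS = 4)
  evB <- mkEvents(n, t0 = 12, gapS = 4)
  ev <- rbind(cbind(evA, content_class = "IAP-only"),
              cbind(evB, content_class = "MAP-only"))
  T <- max(ev$end_s) + 5
  base <- poissonTrain(5, T)
  extra <- unlist(lapply(seq_len(n), function(i)
    runif(rpois(1, 2), evA$start_s[i], evA$end_s[i])))
  selective <- sort(c(base, extra))
  rSel <- labelPermutationControl(selective, ev, nPermutations = 300, seed = 5)
  expect_gt(abs(rSel$observedDiff), quantile(abs(rSel$nullDiffs), 0.95))
  expect_lt(rSel$p_value, 0.05)

  rNull <- labelPermutationControl(base, ev, nPermutations = 300, seed = 5)
  expect_gt(rNull$p_value, 0.05)
})

test_that("joint-index regression recovers constructed relations", {
  set.seed(95)
  n <- 40
  iMap <- rnorm(n, 0, 0.5); iIap <- rnorm(n, 0, 0.5)
  exact <- data.frame(i_map = iMap, i_iap = iIap,
                      i_joint = 0.5 * iMap + 0.5 * iIap)
  fit <- jointModulationRegression(exact)
  expect_equal(fit$r_squared, 1)
  expect_equal(unname(fit$coefficients[-1]), c(0.5, 0.5), tolerance = 1e-9)

  # independent noise: R^2 below the 95th null percentile
  noise <- data.frame(i_map = iMap, i_iap = iIap, i_joint = rnorm(n, 0, 0.5))
  r2 <- jointModulationRegression(noise)$r_squared
  nullR2 <- replicate(200, {
    jointModulationRegression(data.frame(i_map = iMap, i_iap = iIap,
                                         i_joint = sample(noise$i_joint)))$r_squared
  })
  expect_lt(r2, quantile(nullR2, 0.99))

  # noisy construction: R^2 near the theoretical value
  sdN <- 0.25
  constructed <- data.frame(i_map = iMap, i_iap = iIap,
                            i_joint = 0.6 * iMap + 0.4 * iIap + rnorm(n, 0, sdN))
  r2c <- jointModulationRegression(constructed)$r_squared
  varSig <- 0.36 * var(iMap) + 0.16 * var(iIap)
  expect_equal(r2c, varSig / (varSig + sdN^2), tolerance = 0.25)

  expect_error(jointModulationRegression(exact[1:2, ]), "at least 3")
  degen <- data.frame(i_map = iMap, i_iap = iMap, i_joint = iIap)
  expect_error(jointModulationRegression(degen), "rank-deficient")
})
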