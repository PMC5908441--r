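test_that("burst detection follows the >3 spikes / <40 ms ISI rule", {
  # 4 spikes at 10 ms ISIs: one burst, duration 30 ms
  b <- detectBursts(spikeTrain(c(0, 0.01, 0.02, 0.03)))
  expect_equal(nrow(b), 1)
  expect_equal(b$duration, 30)
  expect_equal(b$n, 4L)
  expect_equal(b$intraburstFreq, 3 / 0.030)
  # all ISIs >= 40 ms: no burst
  expect_equal(nrow(detectBursts(spikeTrain(c(0, 0.05, 0.10, 0.15)))), 0)
  # exactly 40 ms is not < 40 ms
  expect_equal(nrow(detectBursts(spikeTrain(c(0, 0.04, 0.08, 0.12)))), 0)
  # 3-spike runs count only when minBurstSpikes is lowered to 3
  tr3 <- spikeTrain(c(0, 0.01, 0.02))
  expect_equal(nrow(detectBursts(tr3)), 0)
  expect_equal(nrow(detectBursts(tr3, analysisConfig(minBurstSpikes = 3))), 1)
})

test_that("burst detection equals the brute-force scanner on random trains", {
  set.seed(101)
  cfg <- analysisConfig()
  for (i in 1:2000) {
    n <- sample(2:60, 1)
    tt <- randomTrain(n, span = runif(1, 0.5, 4))
    tt <- tt[c(TRUE, diff(tt) > 1e-6)]
    got <- detectBursts(spikeTrain(tt), cfg)
    want <- oracleBursts(tt)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n, as.integer(want$n))
    }
  }
})

test_that("burst membership invariants hold on random trains", {
  set.seed(55)
  cfg <- analysisConfig()
  for (i in 1:50) {
    tt <- randomTrain(80, span = 4)
    tt <- tt[c(TRUE, diff(tt) > 1e-6)]
    b <- detectBursts(spikeTrain(tt), cfg)
    if (!nrow(b)) next
    # bursts are disjoint
    expect_true(all(b$start[-1] > b$end[-nrow(b)]))
    # every spike inside a burst has a neighbor closer than 40 ms
    for (k in seq_len(nrow(b))) {
      sp <- tt[tt >= b$start[k] & tt <= b$end[k]]
      isi <- diff(sp)
      expect_true(all(isi < 0.040))
      expect_gte(length(sp), 4)
    }
  }
})

test_that("burst detection is translation-invariant", {
  tt <- c(0, 0.01, 0.02, 0.03, 0.5, 0.51, 0.52, 0.53, 0.54)
  b0 <- detectBursts(spikeTrain(tt))
  b1 <- detectBursts(spikeTrain(tt + 1000))
  expect_equal(b1$start, b0$start + 1000)
  expect_equal(b1$duration, b0$duration)
})

test_that("firing rates use complete 1 s windows per state", {
  ep <- epochSet(c(0, 10), c(10, 20), c("LM", "IM"))
  # 50 Hz regular spiking during LM only
  tr <- spikeTrain(seq(0, 9.999, by = 0.02))
  fr <- firingRates(tr, ep)
  expect_equal(fr$mean[fr$state == "LM"], 50)
  expect_equal(fr$sd[fr$state == "LM"], 0)
  expect_equal(fr$mean[fr$state == "IM"], 0)
  # empty train: zero everywhere
  fr0 <- firingRates(spikeTrain(numeric()), ep)
  expect_equal(fr0$mean, c(0, 0))
  # a state shorter than one window is unavailable
  ep2 <- epochSet(c(0, 10), c(10, 10.5), c("LM", "IM"))
  fr2 <- firingRates(tr, ep2)
  expect_true(is.na(fr2$mean[fr2$state == "IM"]))
})

test_that("Poisson spiking recovers its rate and count variance", {
  set.seed(8)
  rate <- 40; dur <- 300
  n <- rpois(1, rate * dur)
  tr <- spikeTrain(sort(runif(n, 0, dur)))
  ep <- epochSet(0, dur, "IM")
  fr <- firingRates(tr, ep)
  expect_lt(abs(fr$mean - rate) / rate, 0.02)
  expect_lt(abs(fr$sd - sqrt(rate)) / sqrt(rate), 0.10)
})

test_that("interburst intervals stay within state epochs", {
  ep <- epochSet(c(0, 10), c(1, 11), c("LM", "LM"))
  mkBurst <- function(t0) t0 + c(0, 0.01, 0.02, 0.03)
  tr <- spikeTrain(c(mkBurst(0.0), mkBurst(0.2), mkBurst(0.4),
                     mkBurst(10.1), mkBurst(10.4)))
  b <- detectBursts(tr)
  bs <- burstStatistics(b, ep)
  # within-epoch gaps only: 200, 200 (epoch 1) and 300 (epoch 2) ms
  expect_equal(bs$ibiMedian[bs$state == "LM"], 200)
  expect_equal(bs$nBursts[bs$state == "LM"], 5L)
  # one burst alone: duration defined, no interburst interval
  one <- burstStatistics(detectBursts(spikeTrain(mkBurst(0.5))),
                         epochSet(0, 5, "IM"))
  expect_equal(one$durationMedian, 30)
  expect_true(is.na(one$ibiMedian))
  # a state without bursts carries the unavailable sentinel
  none <- burstStatistics(detectBursts(spikeTrain(c(0.1, 0.5))),
                          epochSet(0, 5, "WS"))
  expect_true(is.na(none$durationMedian))
})

test_that("lm-im index follows its closed form", {
  expect_equal(lmImIndex(50, 50), 0)
  expect_equal(lmImIndex(55.2, 39.8), (55.2 - 39.8) / (55.2 + 39.8))
  expect_equal(round(lmImIndex(55.2, 39.8), 3), 0.162)
  expect_equal(lmImIndex(10, 0), 1)
  expect_true(is.na(lmImIndex(0, 0)))
})

test_that("autocorrelogram peaks reflect rhythmic spacing", {
  tr <- spikeTrain(seq(0, 20, by = 0.1))
  ac <- autocorrelogram(tr, binwidth = 0.005, maxLag = 0.35)
  expect_equal(ac$peakLag, 0.1, tolerance = 0.006)
  peaks <- ac$lags[ac$counts > max(ac$counts) * 0.5]
  expect_true(all(abs((peaks %% 0.1 + 0.05) %% 0.1 - 0.05) < 0.006))
  # zero-lag self-pairs excluded
  expect_equal(ac$counts[abs(ac$lags) < 0.0025], 0)
  expect_error(autocorrelogram(spikeTrain(0.5)), "at least 2")
})

test_that("a 6.5 Hz bursting unit peaks near 154 ms", {
  sch <- epochSet(0, 120, "IM")
  spec <- sessionSpec(duration = 120, schedule = sch, rngSeed = 17,
                      imRhythmFreq = 6.5,
                      stateRate = c(LM = 0, SM = 0, WS = 0, IM = 40))
  truth <- generateLfp(spec)
  spk <- generateSpikes(spec, truth)
  ac <- autocorrelogram(spk$train, binwidth = 0.005, maxLag = 0.3)
  expect_lt(abs(ac$peakLag - 1 / 6.5), 0.0075)
})

test_that("homogeneous Poisson trains have a flat correlogram", {
  set.seed(4)
  tr <- spikeTrain(sort(runif(6000, 0, 300)))
  ac <- autocorrelogram(tr, binwidth = 0.01, maxLag = 0.3)
  pos <- ac$counts[ac$lags > 0.02]
  expect_lt((max(pos) - min(pos)) / mean(pos), 0.35)
})

test_that("spikes per cycle counts every cycle including empty ones", {
  troughs <- seq(0, 10, by = 0.125)
  tr <- spikeTrain(troughs[-length(troughs)] + 0.06)
  spc <- spikesPerCycle(tr, troughs)
  expect_equal(unname(spc["mean"]), 1)
  expect_equal(unname(spc["sd"]), 0)
  spc0 <- spikesPerCycle(spikeTrain(numeric()), troughs)
  expect_equal(unname(spc0), c(0, 0))
})

test_that("burst incidence x spikes-per-burst is bounded by the rate", {
  ses <- defaultSession()
  cfg <- analysisConfig()
  b <- detectBursts(ses$train, cfg)
  fr <- firingRates(ses$train, ses$schedule, cfg)
  bs <- burstStatistics(b, ses$schedule, cfg)
  for (st in c("LM", "IM")) {
    iv <- septorhythm:::epochIntervals(ses$schedule, st)
    bSt <- b[septorhythm:::pointsInIntervals(b$start, iv), ]
    inc <- bs$incidenceMean[bs$state == st]
    rate <- fr$mean[fr$state == st]
    # burst spikes cannot outnumber all spikes: incidence times mean
    # spikes per burst is bounded by the state's mean rate (small slack
    # for window edge effects)
    expect_lte(inc * mean(bSt$n), rate * 1.05)
  }
})
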