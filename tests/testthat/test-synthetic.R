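test_that("pure 8 Hz theta yields troughs exactly 125 ms apart", {
  sch <- epochSet(0, 10, "LM")
  spec <- sessionSpec(duration = 10, schedule = sch, rngSeed = 1,
                      thetaFreq = c(LM = 8, SM = 7, WS = 0, IM = 0),
                      noiseAmp = 0, gammaAmp = 0, liaAmp = 0, deltaAmp = 0)
  truth <- generateLfp(spec)
  d <- diff(eventTimes(truth$thetaTroughs))
  expect_equal(d, rep(0.125, length(d)), tolerance = 1e-6)
})

test_that("zero ripple rate gives an empty true-ripple set", {
  spec <- sessionSpec(duration = 30, rngSeed = 2, rippleRate = 0)
  truth <- generateLfp(spec)
  expect_length(truth$ripples, 0)
})

test_that("ripples are confined to immobility epochs", {
  ses <- defaultSession()
  rw <- eventWindows(ses$truth$ripples)
  imIv <- septorhythm:::epochIntervals(ses$schedule, "IM")
  expect_true(all(septorhythm:::pointsInIntervals(rw$time, imIv)))
})

test_that("theta/delta band-power ratio is higher in LM than IM (Welch oracle)", {
  ses <- defaultSession()
  x <- samples(ses$lfp)
  bandPower <- function(seg, band) {
    sp <- stats::spec.pgram(stats::ts(seg, frequency = 1000),
                            spans = 15, plot = FALSE, detrend = TRUE)
    sum(sp$spec[sp$freq >= band[1] & sp$freq <= band[2]])
  }
  lmSeg <- x[5001:25000]    # inside the first LM block
  imSeg <- x[55001:75000]   # inside the first IM block
  ratioLm <- bandPower(lmSeg, c(5, 12)) / bandPower(lmSeg, c(2, 4))
  ratioIm <- bandPower(imSeg, c(5, 12)) / bandPower(imSeg, c(2, 4))
  expect_gt(ratioLm, ratioIm)
  expect_gt(ratioLm, 2)
  expect_lt(ratioIm, 1)
})

test_that("gamma envelope peaks at the configured theta coupling phase", {
  ses <- defaultSession()
  # the envelope crest of a supra-threshold cycle sits half a gamma
  # period after its trough; crest phases concentrate at the theta peak
  crest <- eventTimes(ses$truth$gammaTroughs) + 0.5 / 65
  ph <- phaseAtTimes(ses$truth$thetaTroughs, crest)
  ph <- ph[!is.na(ph)]
  cs <- circularStats(ph)
  expect_lt(septorhythm:::circDistDeg(cs$meanPhase, 180), 10)
  expect_gt(cs$r, 0.5)
})

test_that("generated per-state rates land within 10% of targets at 300 s", {
  ses <- cachedSession("long", function()
    generateSession(sessionSpec(duration = 300, rngSeed = 9)))
  fr <- firingRates(ses$train, ses$schedule)
  targets <- c(LM = 55, SM = 45, WS = 40, IM = 40)
  for (st in names(targets)) {
    got <- fr$mean[fr$state == st]
    expect_lt(abs(got - targets[[st]]) / targets[[st]], 0.10,
              label = sprintf("state %s rate %.1f", st, got))
  }
})

test_that("true bursts accommodate: successive ISIs non-decreasing", {
  ses <- defaultSession()
  b <- ses$truth$bursts
  b <- b[order(b$start), ]
  tt <- spikeTimes(ses$train)
  # only bursts whose span does not touch a neighbor, so the extracted
  # spikes belong to that burst alone
  isolated <- c(TRUE, b$start[-1] > b$end[-nrow(b)] + 0.005) &
              c(b$end[-nrow(b)] < b$start[-1] - 0.005, TRUE)
  checked <- 0L
  for (i in which(isolated)[seq_len(min(sum(isolated), 300))]) {
    sp <- tt[tt >= b$start[i] - 1e-9 & tt <= b$end[i] + 1e-9]
    if (length(sp) < 3 || length(sp) != b$n[i]) next
    isis <- diff(sp)
    expect_true(all(diff(isis) >= -1e-9))
    checked <- checked + 1L
  }
  expect_gt(checked, 50)
})

test_that("kappa = 0 gives uniform spike phases, large kappa recovers mu", {
  sch <- epochSet(c(0, 60), c(60, 120), c("LM", "IM"))
  mk <- function(kappa) {
    spec <- sessionSpec(duration = 120, schedule = sch, rngSeed = 21,
                        spikePhaseKappa = kappa, accommodationDecay = 0)
    truth <- generateLfp(spec)
    spk <- generateSpikes(spec, truth)
    lmIv <- septorhythm:::epochIntervals(sch, "LM")
    s <- spikeTimes(spk$train)
    s <- s[septorhythm:::pointsInIntervals(s, lmIv)]
    ph <- phaseAtTimes(truth$thetaTroughs, s)
    circularStats(ph[!is.na(ph)])
  }
  unif <- mk(0)
  expect_lt(unif$r, 0.08)
  locked <- mk(50)
  expect_lt(septorhythm:::circDistDeg(locked$meanPhase, 178), 5)
  expect_gt(locked$r, 0.4)
})

test_that("a rate beyond the burst geometry is refused", {
  spec <- sessionSpec(duration = 30, rngSeed = 3,
                      stateRate = c(LM = 300, SM = 45, WS = 40, IM = 40))
  truth <- generateLfp(spec)
  expect_error(generateSpikes(spec, truth), "incompatible")
})

test_that("LM minus IM rate index is positive for the default unit", {
  ses <- defaultSession()
  fr <- firingRates(ses$train, ses$schedule)
  idx <- lmImIndex(fr$mean[fr$state == "LM"], fr$mean[fr$state == "IM"])
  expect_gt(idx, 0)
})

test_that("generation is reproducible from the seed", {
  a <- generateSession(sessionSpec(duration = 15, rngSeed = 77))
  b <- generateSession(sessionSpec(duration = 15, rngSeed = 77))
  expect_identical(spikeTimes(a$train), spikeTimes(b$train))
  expect_identical(samples(a$lfp), samples(b$lfp))
})

test_that("a session shorter than one theta cycle is rejected", {
  sch <- epochSet(0, 0.05, "LM")
  expect_error(generateLfp(sessionSpec(duration = 0.05, schedule = sch)),
               "shorter than one theta cycle")
})
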