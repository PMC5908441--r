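pureLfp <- function(freq, duration = 10, rate = 1000, amp = 1) {
  t <- seq(0, duration, by = 1 / rate)
  lfp(amp * sin(2 * pi * freq * t), rate = rate)
}

test_that("pure sinusoids are labeled theta or non-theta by frequency", {
  te8 <- detectThetaEpochs(pureLfp(8))
  expect_equal(unique(epochLabels(te8)), "theta")
  te3 <- detectThetaEpochs(pureLfp(3))
  expect_equal(unique(epochLabels(te3)), "non_theta")
  expect_error(detectThetaEpochs(lfp(rnorm(100), 1000)), "shorter")
})

test_that("theta epochs partition the trace", {
  ses <- defaultSession()
  te <- detectThetaEpochs(ses$lfp)
  expect_equal(duration(te), duration(ses$lfp), tolerance = 1e-3)
})

test_that("theta epochs recover the locomotion periods of an LM/IM session", {
  truth <- lmImSession()
  te <- detectThetaEpochs(truth$lfp)
  thIv <- septorhythm:::epochIntervals(te, "theta")
  lm <- as.data.frame(epochsWithLabel(truth$schedule, "LM"))
  j <- septorhythm:::intervalJaccard(thIv, cbind(lm$start, lm$end))
  expect_gt(j, 0.8)
})

test_that("theta phase is 0 at troughs and 180 at the peak", {
  x <- pureLfp(8)
  ph <- thetaPhase(x)
  tt <- eventTimes(ph$troughs)
  # trough of sin() at 3/4 of the period
  expect_equal(diff(tt), rep(0.125, length(tt) - 1), tolerance = 1e-3)
  # phase at a trough ~ 0 (or 360), at the following peak ~ 180
  mid <- tt[5] + 0.125 / 2
  phases <- phaseAtTimes(tt, c(tt[5], mid))
  expect_lt(min(phases[1], 360 - phases[1]), 1)
  expect_equal(phases[2], 180, tolerance = 1)
})

test_that("phase interpolation matches the trough-fraction oracle on an
           asymmetric cycle", {
  # troughs at 0 and 0.15 s; waveform maximum placed at 0.04 s
  troughs <- c(0, 0.15, 0.30)
  expect_equal(phaseAtTimes(troughs, 0.04), 360 * 0.04 / 0.15)
  expect_false(isTRUE(all.equal(phaseAtTimes(troughs, 0.04), 180)))
  expect_equal(phaseAtTimes(troughs, 0.15 + 0.075), 180)
  expect_true(is.na(phaseAtTimes(troughs, 0.31)))
})

test_that("theta phase is monotone within each cycle and covers [0, 360)", {
  x <- pureLfp(8)
  ph <- thetaPhase(x)$phase
  ph <- ph[!is.na(ph)]
  expect_true(all(ph >= 0 & ph < 360))
  d <- diff(ph)
  # within-cycle steps increase; wraps are large negative jumps
  expect_true(all(d > 0 | d < -300))
})

test_that("constant-amplitude gamma yields zero supra-threshold troughs", {
  # 16 samples per cycle: every sampled cycle is identical, so the cycle
  # amplitude s.d. is exactly zero and the strict > mean + 1 s.d. rule
  # can never fire
  rate <- 65 * 16
  t <- seq(0, 5, by = 1 / rate)
  x <- lfp(sin(2 * pi * 65 * t), rate)
  ev <- detectGammaTroughs(x)
  expect_length(ev, 0)
  # incoherent sampling leaves sub-percent amplitude wobble; at most a
  # handful of cycles may cross the strict threshold
  ev2 <- detectGammaTroughs(pureLfp(65, duration = 5))
  expect_lt(length(ev2), 0.02 * 65 * 5)
})

test_that("only amplified gamma cycles cross the cycle-amplitude threshold", {
  rate <- 1000
  t <- seq(0, 10, by = 1 / rate)
  period <- 1 / 65
  cyc <- floor(t / period)
  set.seed(8)
  bigCycles <- sort(sample(unique(cyc)[-c(1, length(unique(cyc)))], 60))
  amp <- ifelse(cyc %in% bigCycles, 5, 1)
  x <- lfp(amp * sin(2 * pi * 65 * t), rate)
  ev <- detectGammaTroughs(x)
  # detected troughs fall inside amplified cycles (half-period slack at
  # the boundaries, where the filter smears amplitude)
  trCyc <- floor(eventTimes(ev) / period)
  expect_gt(length(ev), 40)
  expect_gt(mean(trCyc %in% c(bigCycles - 1, bigCycles, bigCycles + 1)),
            0.95)
})

test_that("flat traces contain no SWRs", {
  x <- lfp(rep(0, 5000), 1000)
  expect_length(detectSwr(x), 0)
})

test_that("injected ripple bursts are recovered without false positives", {
  rate <- 1000
  dur <- 120
  set.seed(31)
  noise <- septorhythm:::powerLawNoise(dur * rate, 1, 1)
  t <- (seq_len(dur * rate) - 1) / rate
  centers <- seq(1, dur - 1, length.out = 60)
  x <- noise
  for (tc in centers) {
    i <- which(t >= tc - 0.025 & t <= tc + 0.025)
    x[i] <- x[i] + 8 * sd(noise) *
      exp(-(t[i] - tc)^2 / (2 * 0.009^2)) * sin(2 * pi * 150 * (t[i] - tc))
  }
  ev <- detectSwr(lfp(x, rate))
  det <- eventTimes(ev)
  hits <- vapply(centers, function(v) any(abs(det - v) < 0.025), logical(1))
  expect_gte(sum(hits), 54)
  outside <- vapply(det, function(v) all(abs(centers - v) > 0.050),
                    logical(1))
  expect_equal(sum(outside), 0)
})

test_that("SWR windows bracket their event and report extents", {
  ses <- defaultSession()
  ev <- detectSwr(ses$lfp)
  w <- eventWindows(ev)
  expect_true(all(w$start <= w$time & w$time <= w$end))
  expect_true(all(w$end - w$start > 0.01))
})

test_that("LIA falling crossings respect period and minimum interval", {
  x3 <- pureLfp(3, duration = 5)
  ev <- detectLiaCycles(x3)
  d <- diff(eventTimes(ev))
  expect_equal(d, rep(1 / 3, length(d)), tolerance = 0.01)
  # a 10 Hz oscillation has 100 ms crossings; thinning enforces >= 200 ms
  x10 <- pureLfp(10, duration = 5)
  d10 <- diff(eventTimes(detectLiaCycles(x10)))
  expect_true(all(d10 >= 0.2 - 1e-9))
})

test_that("LIA crossing count matches generator truth on non-theta data", {
  sch <- epochSet(0, 60, "IM")
  spec <- sessionSpec(duration = 60, schedule = sch, rngSeed = 13,
                      rippleRate = 0)
  truth <- generateLfp(spec)
  det <- detectLiaCycles(truth$lfp)
  nTrue <- length(truth$liaCrossings)
  expect_gt(nTrue, 20)
  expect_lt(abs(length(det) - nTrue) / nTrue, 0.10)
})

test_that("event correlation localizes constructed lags", {
  a <- eventSet(seq(1, 50), "theta_trough")
  cc0 <- eventCorrelation(a, a, window = 0.3, binwidth = 0.01)
  expect_equal(cc0$lag[which.max(cc0$count)], 0, tolerance = 1e-9)
  expect_equal(sum(cc0$count[abs(cc0$lag) > 0.005]), 0)
  b <- eventSet(seq(1, 50) + 0.1, "gamma_trough")
  cc <- eventCorrelation(b, a, window = 0.3, binwidth = 0.01)
  expect_lt(abs(cc$lag[which.max(cc$count)] - 0.1), 0.011)
})

test_that("gamma-theta correlogram peaks near half the theta period", {
  ses <- defaultSession()
  cc <- eventCorrelation(ses$truth$gammaTroughs, ses$truth$thetaTroughs,
                         window = 0.12, binwidth = 0.01)
  # the correlogram is symmetric (gamma peaks before and after each
  # trough); the positive-lag peak sits at half the 8 Hz theta period
  pos <- cc[cc$lag > 0.02, ]
  peak <- pos$lag[which.max(pos$count)]
  expect_lt(abs(peak - 0.0625), 0.015)
})

test_that("detectors are offset-invariant and shift-equivariant", {
  ses <- lmImSession()
  x <- ses$lfp
  xOff <- lfp(samples(x) + 5, samplingRate(x), startTime(x))
  expect_equal(eventTimes(detectGammaTroughs(xOff)),
               eventTimes(detectGammaTroughs(x)), tolerance = 1e-9)
  expect_equal(eventTimes(detectSwr(xOff)), eventTimes(detectSwr(x)),
               tolerance = 1e-9)
  xShift <- lfp(samples(x), samplingRate(x), startTime(x) + 100)
  expect_equal(eventTimes(detectSwr(xShift)),
               eventTimes(detectSwr(x)) + 100, tolerance = 1e-9)
  expect_equal(eventTimes(thetaPhase(xShift)$troughs),
               eventTimes(thetaPhase(x)$troughs) + 100, tolerance = 1e-9)
})

test_that("zero-phase filtering keeps noiseless trough times to 1 sample", {
  rate <- 1000
  t <- seq(0, 20, by = 1 / rate)
  x <- lfp(sin(2 * pi * 8 * t), rate)
  tt <- eventTimes(thetaPhase(x)$troughs)
  analytic <- seq(3 / 32, 20, by = 0.125)  # troughs of sin at 3T/4 + kT
  interior <- tt[tt > 1 & tt < 19]
  err <- vapply(interior, function(v) min(abs(analytic - v)), numeric(1))
  expect_lt(max(err), 1 / rate + 1e-9)
})
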