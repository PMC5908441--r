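test_that("spike phases interpolate on the trough clock", {
  troughs <- seq(0, 10, by = 0.125)
  expect_equal(assignPhase(spikeTrain(0.125), troughs)[1], 0)
  expect_equal(assignPhase(spikeTrain(0.125 + 0.0625), troughs)[1], 180)
  # uncovered spikes are dropped and counted
  ph <- assignPhase(spikeTrain(c(0.2, 50)), troughs)
  expect_length(ph, 1)
  expect_equal(attr(ph, "nDropped"), 1L)
  expect_error(assignPhase(spikeTrain(99), troughs), "no spikes covered")
})

test_that("von Mises spike phases are recovered distributionally", {
  set.seed(12)
  troughs <- seq(0, 200, by = 0.125)
  drawn <- septorhythm:::rVonMises(3000, 200, 3)
  cycle <- sample(length(troughs) - 1L, 3000, replace = TRUE)
  tt <- sort(troughs[cycle] + drawn / 360 * 0.125)
  tt <- tt[c(TRUE, diff(tt) > 1e-9)]
  ph <- assignPhase(spikeTrain(tt), troughs)
  expect_equal(length(ph) + attr(ph, "nDropped"), length(tt))
  # KS on circular ranks against the generating distribution
  ranks <- ecdf(drawn)(ph)
  ks <- suppressWarnings(stats::ks.test(ranks, "punif"))
  expect_gt(ks$p.value, 0.01)
  cs <- circularStats(ph)
  expect_lt(septorhythm:::circDistDeg(cs$meanPhase, 200), 5)
})

test_that("circular statistics match closed forms", {
  expect_error(circularStats(numeric()), "at least one")
  all90 <- circularStats(rep(90, 20))
  expect_equal(all90$meanPhase, 90)
  expect_equal(all90$r, 1)
  two <- circularStats(c(0, 90))
  expect_equal(two$meanPhase, 45)
  expect_equal(two$r, cos(pi / 4), tolerance = 1e-12)
  grid <- circularStats(seq(0, 360 - 0.36, by = 0.36))
  expect_lt(grid$r, 1e-10)
  expect_equal(grid$p, 1, tolerance = 1e-6)
})

test_that("circular statistics are rotation-equivariant and
           duplication-invariant", {
  set.seed(3)
  ph <- septorhythm:::rVonMises(200, 130, 2)
  base <- circularStats(ph)
  for (delta in c(30, 123.4, 270)) {
    rot <- circularStats((ph + delta) %% 360)
    expect_equal(rot$meanPhase, (base$meanPhase + delta) %% 360,
                 tolerance = 1e-8)
    expect_equal(rot$r, base$r, tolerance = 1e-12)
    expect_equal(rot$p, base$p, tolerance = 1e-9)
  }
  dup <- circularStats(c(ph, ph))
  expect_equal(dup$r, base$r, tolerance = 1e-12)
  expect_equal(dup$meanPhase, base$meanPhase, tolerance = 1e-9)
})

test_that("Rayleigh p agrees with a Monte Carlo null within 0.01", {
  # null distribution of r for uniform phases, 1e5 draws per n
  set.seed(42)
  for (n in c(8, 50, 500)) {
    draws <- 1e5
    chunk <- 1e7 %/% n
    rs <- numeric(0)
    remaining <- draws
    while (remaining > 0) {
      m <- min(chunk, remaining)
      a <- matrix(runif(n * m, 0, 2 * pi), nrow = n)
      rs <- c(rs, sqrt(colMeans(cos(a))^2 + colMeans(sin(a))^2))
      remaining <- remaining - m
    }
    for (rObs in quantile(rs, c(0.8, 0.95, 0.99))) {
      pMc <- mean(rs >= rObs)
      R <- n * rObs
      pF <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
      expect_lt(abs(pF - pMc), 0.01,
                label = sprintf("n=%d r=%.3f formula %.4f vs MC %.4f",
                                n, rObs, pF, pMc))
    }
  }
})

test_that("gamma coupling is gated on cross-frequency coupling", {
  ses <- defaultSession()
  truth <- ses$truth
  gl <- gammaCoupling(ses$train, truth$gammaTroughs, truth$thetaTroughs)
  expect_equal(gl$status, "ok")
  # spikes placed exactly at gamma troughs measure phase 0/360
  atTroughs <- spikeTrain(eventTimes(truth$gammaTroughs))
  gl0 <- gammaCoupling(atTroughs, truth$gammaTroughs, truth$thetaTroughs)
  expect_equal(gl0$status, "ok")
  expect_lt(min(gl0$stats$meanPhase, 360 - gl0$stats$meanPhase), 2)
  # gamma troughs decoupled from theta: refuse
  set.seed(5)
  fake <- eventSet(sort(runif(300, 1, 100)), "gamma_trough")
  glBad <- gammaCoupling(ses$train, fake, truth$thetaTroughs,
                         allGammaTroughs = fake)
  expect_equal(glBad$status, "refused")
})

test_that("a gamma-locked unit is recovered near its locking phase", {
  ses <- defaultSession()
  truth <- ses$truth
  gt <- eventTimes(truth$gammaTroughs)
  # keep troughs whose cycle closes one carrier period later, so the
  # placed phase is exact on the trough clock
  gPeriod <- 1 / 65
  allGt <- attr(truth$gammaTroughs, "allTroughs")
  gt <- gt[vapply(gt, function(g) {
    nxt <- allGt[allGt > g + 1e-9]
    length(nxt) > 0 && abs(nxt[1] - g - gPeriod) < 1e-6
  }, logical(1))]
  set.seed(9)
  # spikes at 160 deg of each supra-threshold gamma cycle, jittered
  tt <- sort(gt + (160 + rnorm(length(gt), 0, 10)) / 360 * gPeriod)
  gl <- gammaCoupling(spikeTrain(tt), truth$gammaTroughs,
                      truth$thetaTroughs)
  expect_equal(gl$status, "ok")
  expect_lt(septorhythm:::circDistDeg(gl$stats$meanPhase, 160), 10)
})

test_that("LFP-LFP trough coupling recovers constructed shifts", {
  t <- seq(0, 30, by = 1e-3)
  ref <- lfp(sin(2 * pi * 8 * t), 1000)
  refTroughs <- thetaPhase(ref)$troughs
  self <- lfpTroughCoupling(ref, refTroughs)
  expect_lt(min(self$meanPhase, 360 - self$meanPhase), 3)
  expect_gt(self$r, 0.99)
  quarter <- lfp(sin(2 * pi * 8 * (t - 0.125 / 4)), 1000)
  shifted <- lfpTroughCoupling(quarter, refTroughs)
  expect_equal(shifted$meanPhase, 90, tolerance = 3)
  short <- lfp(sin(2 * pi * 8 * seq(0, 5, by = 1e-3)), 1000)
  expect_error(lfpTroughCoupling(short, refTroughs), "10 s")
})

test_that("independent noise traces are uncoupled in most seeds", {
  ok <- 0L
  nSeeds <- 20L
  for (s in seq_len(nSeeds)) {
    set.seed(1000 + s)
    a <- lfp(septorhythm:::powerLawNoise(60000, 1, 1), 1000)
    b <- lfp(septorhythm:::powerLawNoise(60000, 1, 1), 1000)
    refTroughs <- thetaPhase(a)$troughs
    cs <- lfpTroughCoupling(b, refTroughs)
    if (cs$p > 0.05) ok <- ok + 1L
  }
  expect_gte(ok / nSeeds, 0.9)
})

test_that("phase histograms are circular, normalized and mean-preserving", {
  h1 <- phaseHistogram(rep(100, 50), binwidth = 20, smoothSd = 0)
  expect_equal(sum(h1$density), 1)
  expect_equal(sum(h1$density > 0), 1)
  set.seed(2)
  ph <- septorhythm:::rVonMises(2000, 330, 3)  # mass across the wrap
  h <- phaseHistogram(ph, binwidth = 20, smoothSd = 1)
  expect_equal(sum(h$density), 1, tolerance = 1e-12)
  binMean <- function(hh) {
    rad <- septorhythm:::degToRad(hh$phase)
    septorhythm:::wrapDeg(septorhythm:::radToDeg(
      atan2(sum(hh$density * sin(rad)), sum(hh$density * cos(rad)))))
  }
  raw <- phaseHistogram(ph, binwidth = 20, smoothSd = 0)
  expect_lt(septorhythm:::circDistDeg(binMean(h), binMean(raw)), 1)
})
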