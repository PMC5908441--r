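#' Construct a SessionSpec
#'
#' Builds a synthetic-session specification with defaults chosen to mirror
#' the recorded data: 8 Hz theta during locomotion (7 Hz during small
#' movements and whisking at reduced amplitude), irregular <5 Hz activity
#' and a 3 Hz delta component outside locomotion, 65 Hz mid-gamma whose
#' envelope peaks at the theta peak (coupling phase 180 deg), ripple events
#' only during immobility, and a unit bursting near the theta peak at about
#' 55 Hz during locomotion and 40 Hz during immobility.
#'
#' @param duration session length, seconds.
#' @param schedule optional \linkS4class{EpochSet}; by default the session
#'   alternates LM / SM / WS / IM blocks.
#' @param rngSeed integer seed.
#' @param ... further slot overrides of \linkS4class{SessionSpec}.
#' @return A valid \linkS4class{SessionSpec}.
#' @examples
#' sp <- sessionSpec(duration = 60, rngSeed = 7)
#' @export
sessionSpec <- function(duration = 300, schedule = NULL, rngSeed = 1, ...) {
  if (is.null(schedule)) schedule <- defaultSchedule(duration)
  defaults <- list(
    duration = duration, schedule = schedule, rate = 1000,
    thetaFreq = c(LM = 8, SM = 7, WS = 0, IM = 0),
    thetaAmp = c(LM = 1, SM = 0.7, WS = 0, IM = 0),
    deltaAmp = 0.5, deltaFreq = 3,
    gammaFreq = 65, gammaAmp = 0.08, gammaDepth = 4,
    gammaCouplingPhase = 180,
    rippleRate = 0.25, rippleFreq = 160, rippleDuration = 0.06,
    rippleAmp = 0.6,
    liaAmp = 0.9, liaBand = c(0.5, 4.5),
    noiseAmp = 0.05, noiseExponent = 1,
    spikePhaseMu = 178, spikePhaseKappa = 4,
    stateRate = c(LM = 55, SM = 45, WS = 40, IM = 40),
    burstSpikesMean = 7, intraburstStartFreq = 115,
    accommodationDecay = 0.08, imRhythmFreq = 6.5,
    cycleSkipProb = 0, rngSeed = rngSeed)
  args <- utils::modifyList(defaults, list(...))
  do.call(new, c(list("SessionSpec"), args))
}

# LM / SM / WS / IM blocks tiling the duration
defaultSchedule <- function(duration) {
  block <- c(LM = 30, SM = 10, WS = 10, IM = 30)
  starts <- numeric(); ends <- numeric(); labs <- character()
  t <- 0; i <- 1L
  while (t < duration - 1e-9) {
    st <- names(block)[(i - 1L) %% 4L + 1L]
    len <- min(block[[st]], duration - t)
    starts <- c(starts, t); ends <- c(ends, t + len); labs <- c(labs, st)
    t <- t + len; i <- i + 1L
  }
  epochSet(starts, ends, labs)
}

# 1/f^alpha Gaussian noise via spectral shaping
powerLawNoise <- function(n, alpha, amp) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                 # symmetric frequency index
  X <- X / f^(alpha / 2)
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  amp * x / stats::sd(x)
}

# per-sample state labels from the schedule
stateAtSamples <- function(schedule, times) {
  o <- order(schedule@start)
  idx <- findInterval(times, schedule@start[o])
  idx[idx < 1L] <- 1L
  idx[idx > length(o)] <- length(o)
  schedule@label[o][idx]
}

# smooth 0/1 state masks to avoid hard amplitude edges (100 ms ramps)
smoothMask <- function(mask, rate) {
  movingAverage(as.numeric(mask), round(0.1 * rate))
}

#' Generate a synthetic LFP with exact ground truth
#'
#' Synthesizes the LFP as a sum of components driven by the behavioral
#' schedule: theta (state-dependent frequency and amplitude, phase advances
#' continuously), a delta sinusoid and band-limited irregular slow activity
#' (LIA) outside locomotion-type theta states, a mid-gamma carrier whose
#' envelope is modulated by theta phase (maximal at the configured coupling
#' phase), ripple bursts at Poisson times during immobility, and 1/f^alpha
#' background noise. Ground-truth event lists are exact by construction:
#' theta troughs are the zero-phase times inside theta states, gamma
#' troughs are carrier troughs whose clean cycle amplitude exceeds the mean
#' by one s.d., ripple windows are the injection windows, and LIA crossings
#' are the falling zero-crossings of the clean slow component under the
#' 0.2 s minimum-interval rule.
#'
#' @param spec a \linkS4class{SessionSpec}.
#' @return A list with \code{lfp} (\linkS4class{Lfp}), \code{thetaTroughs},
#'   \code{gammaTroughs}, \code{ripples}, \code{liaCrossings}
#'   (\linkS4class{EventSet}s), \code{thetaPhaseFun} (function: time ->
#'   degrees, \code{NA} outside theta states) and \code{schedule}.
#' @export
generateLfp <- function(spec) {
  validObject(spec)
  rate <- spec@rate
  minTheta <- min(spec@thetaFreq[spec@thetaFreq > 0], 8)
  if (spec@duration < 1 / minTheta)
    stop("duration shorter than one theta cycle")
  set.seed(spec@rngSeed)
  n <- round(spec@duration * rate)
  tms <- (seq_len(n) - 1) / rate
  st <- stateAtSamples(spec@schedule, tms)
  thFreq <- unname(spec@thetaFreq[st])
  thAmp <- unname(spec@thetaAmp[st])
  thetaOn <- thAmp > 0

  # theta phase advances at the state's frequency (8 Hz fallback keeps the
  # oscillator coherent through non-theta states, where amplitude is 0)
  instFreq <- ifelse(thFreq > 0, thFreq, 8)
  phi <- 2 * pi * cumsum(instFreq) / rate     # radians, trough at 2*pi*k
  ampSm <- smoothMask(thAmp, rate)
  theta <- -ampSm * cos(phi)

  # exact theta troughs: phase multiples of 2*pi inside theta states
  k <- floor(phi / (2 * pi))
  crossIdx <- which(diff(k) >= 1L)
  trTimes <- vapply(crossIdx, function(i) {
    target <- 2 * pi * k[i + 1L]
    tms[i] + (target - phi[i]) / (phi[i + 1L] - phi[i]) / rate
  }, numeric(1))
  trState <- thetaOn[pmin(crossIdx + 1L, n)]
  thetaTroughs <- trTimes[trState]

  # slow components outside theta states
  nonThetaMask <- smoothMask(!thetaOn, rate)
  delta <- spec@deltaAmp * sin(2 * pi * spec@deltaFreq * tms)
  liaClean <- if (spec@liaAmp > 0) {
    raw <- powerLawNoise(n, 0, 1)
    liaBand <- bandpassFilter(raw, rate, spec@liaBand, order = 2)
    spec@liaAmp * liaBand / stats::sd(liaBand)
  } else numeric(n)
  slow <- nonThetaMask * (delta + liaClean)

  # gamma with theta-phase-locked envelope
  couplingRad <- degToRad(spec@gammaCouplingPhase)
  bump <- ((1 + cos(phi - couplingRad)) / 2)^4
  env <- spec@gammaAmp * (1 + spec@gammaDepth * bump * smoothMask(thetaOn, rate))
  gamma <- env * cos(2 * pi * spec@gammaFreq * tms)

  # exact gamma troughs: carrier troughs ranked by clean cycle amplitude
  gPeriod <- 1 / spec@gammaFreq
  gTroughAll <- seq(gPeriod / 2, spec@duration - gPeriod / 2, by = gPeriod)
  gIdx <- pmin(pmax(round(gTroughAll * rate) + 1L, 1L), n)
  # clean cycle amplitude as the detector measures it: crest envelope plus
  # the deeper bounding trough envelope
  gMid <- pmin(pmax(round((gTroughAll + gPeriod / 2) * rate) + 1L, 1L), n)
  nextIdx <- c(gIdx[-1L], gIdx[length(gIdx)])
  cycAmp <- env[gMid] + pmax(env[gIdx], env[nextIdx])
  gThr <- mean(cycAmp) + stats::sd(cycAmp)
  gammaTroughs <- gTroughAll[cycAmp > gThr]

  # ripples during immobility
  imIv <- epochIntervals(spec@schedule, "IM")
  ripple <- numeric(n)
  ripCenters <- numeric()
  if (spec@rippleRate > 0 && nrow(imIv) > 0L) {
    for (i in seq_len(nrow(imIv))) {
      span <- imIv[i, 2L] - imIv[i, 1L]
      pad <- spec@rippleDuration
      if (span < 3 * pad) next
      nev <- stats::rpois(1, spec@rippleRate * span)
      if (nev < 1L) next
      cand <- sort(stats::runif(nev, imIv[i, 1L] + pad, imIv[i, 2L] - pad))
      cand <- cand[c(TRUE, diff(cand) > 2.5 * spec@rippleDuration)]
      ripCenters <- c(ripCenters, cand)
    }
    sigma <- spec@rippleDuration / 6
    for (tc in ripCenters) {
      i0 <- max(1L, round((tc - spec@rippleDuration / 2) * rate) + 1L)
      i1 <- min(n, round((tc + spec@rippleDuration / 2) * rate) + 1L)
      tt <- tms[i0:i1]
      ripple[i0:i1] <- ripple[i0:i1] +
        spec@rippleAmp * exp(-(tt - tc)^2 / (2 * sigma^2)) *
        sin(2 * pi * spec@rippleFreq * (tt - tc))
    }
  }
  ripples <- if (length(ripCenters))
    eventSet(ripCenters, "swr",
             windowStart = ripCenters - spec@rippleDuration / 2,
             windowEnd = ripCenters + spec@rippleDuration / 2)
    else eventSet(numeric(), "swr")

  noise <- if (spec@noiseAmp > 0)
    powerLawNoise(n, spec@noiseExponent, spec@noiseAmp) else numeric(n)

  x <- lfp(theta + slow + gamma + ripple + noise, rate = rate, t0 = 0)

  # true LIA falling crossings: the detector's own definition (smoothing,
  # DC removal, 0.2 s minimum interval) applied to the noiseless slow
  # component, restricted to non-theta states
  liaTimes <- numeric()
  if (any(!thetaOn)) {
    cleanLia <- detectLiaCycles(lfp(slow, rate = rate, t0 = 0))
    keep <- !thetaOn[pmin(pmax(round(eventTimes(cleanLia) * rate) + 1L, 1L),
                          n)]
    liaTimes <- eventTimes(cleanLia)[keep]
  }

  thetaPhaseFun <- function(at) {
    ph <- rep(NA_real_, length(at))
    if (length(thetaTroughs) >= 2L)
      ph <- phaseAtTimes(thetaTroughs, at)
    ph
  }

  gammaEv <- eventSet(gammaTroughs, "gamma_trough")
  attr(gammaEv, "allTroughs") <- gTroughAll

  list(lfp = x,
       thetaTroughs = eventSet(thetaTroughs, "theta_trough"),
       gammaTroughs = gammaEv,
       ripples = ripples,
       liaCrossings = eventSet(liaTimes, "lia_falling"),
       thetaPhaseFun = thetaPhaseFun,
       schedule = spec@schedule)
}

#' Generate a synthetic spike train with true burst annotations
#'
#' Two-level process: burst placements are drawn per rhythm cycle (the true
#' theta cycles during theta states, an internal rhythm of
#' \code{spec@imRhythmFreq} Hz otherwise) with a per-state probability
#' chosen so the expected rate matches \code{spec@stateRate}; each accepted
#' cycle receives one burst whose center phase is drawn von
#' Mises(\code{spikePhaseMu}, \code{spikePhaseKappa}). Within a burst the
#' spike count is Poisson-distributed around \code{burstSpikesMean}
#' (minimum \code{minBurstSpikes}) and inter-spike intervals start at
#' \code{1/intraburstStartFreq} and grow by the accommodation factor, so
#' successive intervals are non-decreasing whenever the decay is positive.
#'
#' @param spec a \linkS4class{SessionSpec}.
#' @param truth the ground-truth list from \code{\link{generateLfp}} (for
#'   the true theta troughs and schedule).
#' @param cfg an \linkS4class{AnalysisConfig} (burst geometry bounds).
#' @return A list with \code{train} (\linkS4class{SpikeTrain}) and
#'   \code{bursts} (data.frame of true burst start/end/n).
#' @export
generateSpikes <- function(spec, truth, cfg = analysisConfig()) {
  validObject(spec)
  if (spec@intraburstStartFreq < max(spec@stateRate))
    stop("requested rate incompatible with burst geometry: ",
         "intraburst frequency below the target rate")
  set.seed(spec@rngSeed + 1L)
  nbMean <- spec@burstSpikesMean
  minSpk <- max(2, cfg@minBurstSpikes)
  troughs <- eventTimes(truth$thetaTroughs)
  sch <- spec@schedule
  spikes <- numeric()
  burstStart <- numeric(); burstEnd <- numeric(); burstN <- integer()

  emitBurst <- function(center) {
    nSpk <- max(minSpk, stats::rpois(1, nbMean - minSpk) + minSpk)
    isi0 <- 1 / spec@intraburstStartFreq
    isis <- isi0 * (1 + spec@accommodationDecay)^(seq_len(nSpk - 1L) - 1L)
    isis <- isis * stats::runif(nSpk - 1L, 1, 1.12)
    if (spec@accommodationDecay > 0) isis <- cummax(isis)
    off <- c(0, cumsum(isis))
    center - mean(off) + off   # center of mass at the drawn phase
  }

  for (i in seq_len(length(sch))) {
    stLab <- sch@label[i]
    s <- sch@start[i]; e <- sch@end[i]
    target <- spec@stateRate[[stLab]]
    if (target <= 0) next
    if (spec@thetaFreq[[stLab]] > 0) {
      inEp <- troughs[troughs >= s & troughs < e]
      if (length(inEp) < 2L) next
      f <- spec@thetaFreq[[stLab]]
      pBurst <- target / (f * nbMean)
      if (pBurst > 1)
        stop("requested rate incompatible with burst geometry in state ",
             stLab)
      skipNext <- FALSE
      for (j in seq_len(length(inEp) - 1L)) {
        if (skipNext) { skipNext <- FALSE; next }
        if (stats::runif(1) > pBurst) next
        period <- inEp[j + 1L] - inEp[j]
        phase <- rVonMises(1L, spec@spikePhaseMu, spec@spikePhaseKappa)
        center <- inEp[j] + phase / 360 * period
        sp <- emitBurst(center)
        spikes <- c(spikes, sp)
        burstStart <- c(burstStart, sp[1L])
        burstEnd <- c(burstEnd, sp[length(sp)])
        burstN <- c(burstN, length(sp))
        # occasional burst spanning two cycles: the next cycle stays empty
        skipNext <- spec@cycleSkipProb > 0 &&
          stats::runif(1) < spec@cycleSkipProb
      }
    } else {
      f <- spec@imRhythmFreq
      pBurst <- target / (f * nbMean)
      if (pBurst > 1)
        stop("requested rate incompatible with burst geometry in state ",
             stLab)
      centers <- seq(s + 1 / (2 * f), e - 1 / (2 * f), by = 1 / f)
      centers <- centers + stats::rnorm(length(centers), 0, 0.01)
      for (ce in centers) {
        if (stats::runif(1) > pBurst) next
        sp <- emitBurst(ce)
        spikes <- c(spikes, sp)
        burstStart <- c(burstStart, sp[1L])
        burstEnd <- c(burstEnd, sp[length(sp)])
        burstN <- c(burstN, length(sp))
      }
    }
  }
  spikes <- sort(spikes)
  spikes <- spikes[spikes >= 0 & spikes <= spec@duration]
  if (length(spikes) > 1L)
    spikes <- spikes[c(TRUE, diff(spikes) > 2e-3)]
  list(train = spikeTrain(spikes, "synthetic"),
       bursts = data.frame(start = burstStart, end = burstEnd, n = burstN))
}

#' Generate a full synthetic session
#'
#' Runs \code{\link{generateLfp}} and \code{\link{generateSpikes}} and adds
#' behavior channels consistent with the schedule: a wheel-encoder counter
#' ticking at about 15 cm/s during LM, short tick pulses during SM, and a
#' whisking flag during WS.
#'
#' @param spec a \linkS4class{SessionSpec}.
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return A list with \code{lfp}, \code{train}, \code{truth} (ground-truth
#'   lists incl. true bursts), \code{counter} (integer counter at
#'   \code{cfg@speedInterval} resolution), \code{whisk} (logical) and
#'   \code{schedule}.
#' @export
generateSession <- function(spec, cfg = analysisConfig()) {
  truth <- generateLfp(spec)
  spk <- generateSpikes(spec, truth, cfg)
  dt <- cfg@speedInterval
  tms <- seq(0, spec@duration - dt, by = dt)
  st <- stateAtSamples(spec@schedule, tms)
  lmSpeed <- 0.15  # m/s on the wheel surface during locomotion
  ticksPerStep <- lmSpeed * dt * cfg@encoderEdgesPerRev /
    (pi * cfg@wheelDiameter)
  inc <- numeric(length(tms))
  inc[st == "LM"] <- ticksPerStep
  # SM: sub-second movement pulses (0.9 s on, 0.1 s off) so the movement
  # flag cycles without ever spanning the locomotion minimum duration
  smIdx <- which(st == "SM")
  if (length(smIdx)) {
    rel <- (tms[smIdx] - min(tms[smIdx])) %% 1
    # leading 0.1 s gap lets the flag drop at the LM -> SM transition
    inc[smIdx][rel >= 0.1] <- 3
  }
  counter <- floor(cumsum(inc))
  whisk <- st == "WS"
  truth$bursts <- spk$bursts
  list(lfp = truth$lfp, train = spk$train, truth = truth,
       counter = counter, counterTimes = tms, whisk = whisk,
       schedule = spec@schedule)
}
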