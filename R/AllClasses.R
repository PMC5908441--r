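#' @import methods
NULL

BEHAVIOR_STATES <- c("LM", "SM", "WS", "IM")
EVENT_KINDS <- c("theta_trough", "gamma_trough", "swr", "lia_falling")

#' Continuous local field potential trace
#'
#' A uniformly sampled voltage trace. Sample \code{i} (1-based) occurs at
#' time \code{t0 + (i - 1) / rate} seconds. All oscillation detectors in the
#' package operate on this class.
#'
#' @slot samples numeric vector of voltages (arbitrary units).
#' @slot rate sampling rate in Hz.
#' @slot t0 time of the first sample, seconds.
#' @export
setClass("Lfp",
  representation(samples = "numeric", rate = "numeric", t0 = "numeric"),
  prototype(samples = numeric(), rate = 1000, t0 = 0))

setValidity("Lfp", function(object) {
  msg <- character()
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (length(object@samples) < 2L)
    msg <- c(msg, "an Lfp needs at least 2 samples")
  if (anyNA(object@samples))
    msg <- c(msg, "samples must not contain NA")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Sorted spike time stamps of one unit
#'
#' @slot times strictly increasing spike times in seconds.
#' @slot unitId unit label.
#' @export
setClass("SpikeTrain",
  representation(times = "numeric", unitId = "character"),
  prototype(times = numeric(), unitId = "unit"))

setValidity("SpikeTrain", function(object) {
  msg <- character()
  if (anyNA(object@times))
    msg <- c(msg, "spike times must not contain NA")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, sprintf("spike times of unit '%s' are non-monotonic",
                          object@unitId[1L]))
  if (length(object@unitId) != 1L)
    msg <- c(msg, "unitId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Labeled non-overlapping time intervals
#'
#' Holds behavioral-state epochs (labels LM, SM, WS, IM) or network-state
#' epochs (e.g. theta / non_theta). Intervals sharing a label never overlap.
#'
#' @slot start,end interval bounds in seconds, start < end.
#' @slot label character label per interval.
#' @export
setClass("EpochSet",
  representation(start = "numeric", end = "numeric", label = "character"),
  prototype(start = numeric(), end = numeric(), label = character()))

setValidity("EpochSet", function(object) {
  msg <- character()
  n <- length(object@start)
  if (length(object@end) != n || length(object@label) != n)
    msg <- c(msg, "start, end and label must have equal length")
  else {
    if (any(object@end <= object@start))
      msg <- c(msg, "every epoch must satisfy start < end")
    for (lab in unique(object@label)) {
      i <- which(object@label == lab)
      o <- i[order(object@start[i])]
      if (length(o) > 1L &&
          any(object@start[o][-1L] < object@end[o][-length(o)] - 1e-9))
        msg <- c(msg, sprintf("epochs labeled '%s' overlap", lab))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Point events with optional windows
#'
#' Detected LFP events: theta troughs, mid-gamma troughs, SWRs (which carry
#' a (start, end] window each) or LIA falling zero-crossings.
#'
#' @slot times increasing event times, seconds.
#' @slot kind one of \code{"theta_trough"}, \code{"gamma_trough"},
#'   \code{"swr"}, \code{"lia_falling"}.
#' @slot windowStart,windowEnd per-event windows (length 0 if absent;
#'   required for kind \code{"swr"}).
#' @export
setClass("EventSet",
  representation(times = "numeric", kind = "character",
                 windowStart = "numeric", windowEnd = "numeric"),
  prototype(times = numeric(), kind = "theta_trough",
            windowStart = numeric(), windowEnd = numeric()))

setValidity("EventSet", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% EVENT_KINDS)
    msg <- c(msg, sprintf("kind must be one of: %s",
                          paste(EVENT_KINDS, collapse = ", ")))
  if (is.unsorted(object@times))
    msg <- c(msg, "event times must be increasing")
  nw <- length(object@windowStart)
  if (length(object@windowEnd) != nw)
    msg <- c(msg, "windowStart and windowEnd must have equal length")
  if (nw > 0L) {
    if (nw != length(object@times))
      msg <- c(msg, "windows must match the number of events")
    else if (any(object@windowStart > object@times + 1e-9) ||
             any(object@times > object@windowEnd + 1e-9))
      msg <- c(msg, "each event must satisfy start <= time <= end")
  }
  if (identical(object@kind, "swr") && length(object@times) > 0L && nw == 0L)
    msg <- c(msg, "swr events require windows")
  if (length(msg)) msg else TRUE
})

#' Analysis configuration
#'
#' Every numeric constant of the analysis, exposed as one object. Defaults
#' are the values used throughout: 5-12 Hz theta, 2-4 Hz delta, 55-80 Hz
#' mid-gamma, 130-230 Hz ripple band; bursts are runs of spikes with
#' inter-spike intervals under 40 ms containing at least
#' \code{minBurstSpikes} spikes; gamma cycles count when their amplitude
#' exceeds the mean cycle amplitude by 1 s.d., ripple power must exceed the
#' mean by 4 s.d.; LIA cycles come from 0.08 s smoothing, 0.2 s DC removal
#' and a 0.2 s minimum interval; rates use 1 s windows; units with fewer
#' than 20 SWRs are refused by the SWR modulation test; 1000 shuffles and
#' 10000 permutations; the wheel encoder gives 2000 edges per revolution of
#' a 0.146 m cylinder, speed is computed every 10 ms and 1 V encodes
#' 0.6912 m/s.
#'
#' @slot thetaBand,deltaBand,midGammaBand,rippleBand numeric(2), Hz.
#' @slot isiMax maximum intra-burst inter-spike interval, seconds.
#' @slot minBurstSpikes minimum spikes per burst (default 4, i.e. "more
#'   than 3 spikes").
#' @slot gammaAmpSdThreshold,ripplePowerSdThreshold detection thresholds in
#'   s.d. above the mean.
#' @slot liaSmoothWindow,liaDcWindow,liaMinInterval LIA parameters, seconds.
#' @slot rateWindow window for rates and burst incidence, seconds.
#' @slot thetaDeltaRatioThreshold power-ratio threshold for theta periods.
#' @slot thetaEpochMergeGap gap closed when merging theta epochs, seconds.
#' @slot minSwrCount minimum SWRs for the modulation test.
#' @slot nShuffles,nPermutations Monte Carlo sizes.
#' @slot speedCalibration m/s per volt for voltage-coded speed.
#' @slot encoderEdgesPerRev quadrature edges per wheel revolution.
#' @slot wheelDiameter wheel diameter, meters.
#' @slot speedInterval speed sampling step, seconds.
#' @slot lmSpeedThreshold,lmMinDuration locomotion rule: minimum mean speed
#'   (m/s) and minimum duration (s) of a movement period scored as LM.
#' @slot peakPhaseWindow numeric(2), degrees; "around the theta peak" window
#'   used by the classification (trough-origin convention, 180 deg = peak).
#' @slot rngSeed integer seed for shuffles and permutations.
#' @export
setClass("AnalysisConfig",
  representation(
    thetaBand = "numeric", deltaBand = "numeric", midGammaBand = "numeric",
    rippleBand = "numeric", isiMax = "numeric", minBurstSpikes = "numeric",
    gammaAmpSdThreshold = "numeric", ripplePowerSdThreshold = "numeric",
    liaSmoothWindow = "numeric", liaDcWindow = "numeric",
    liaMinInterval = "numeric", rateWindow = "numeric",
    thetaDeltaRatioThreshold = "numeric", thetaEpochMergeGap = "numeric",
    minSwrCount = "numeric", nShuffles = "numeric", nPermutations = "numeric",
    speedCalibration = "numeric", encoderEdgesPerRev = "numeric",
    wheelDiameter = "numeric", speedInterval = "numeric",
    lmSpeedThreshold = "numeric", lmMinDuration = "numeric",
    peakPhaseWindow = "numeric", rngSeed = "numeric"),
  prototype(
    thetaBand = c(5, 12), deltaBand = c(2, 4), midGammaBand = c(55, 80),
    rippleBand = c(130, 230), isiMax = 0.040, minBurstSpikes = 4,
    gammaAmpSdThreshold = 1, ripplePowerSdThreshold = 4,
    liaSmoothWindow = 0.08, liaDcWindow = 0.2, liaMinInterval = 0.2,
    rateWindow = 1, thetaDeltaRatioThreshold = 2, thetaEpochMergeGap = 0.5,
    minSwrCount = 20, nShuffles = 1000, nPermutations = 10000,
    speedCalibration = 0.6912, encoderEdgesPerRev = 2000,
    wheelDiameter = 0.146, speedInterval = 0.01,
    lmSpeedThreshold = 0.01, lmMinDuration = 1,
    peakPhaseWindow = c(90, 270), rngSeed = 1))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  for (bn in c("thetaBand", "deltaBand", "midGammaBand", "rippleBand")) {
    b <- slot(object, bn)
    if (length(b) != 2L || b[1L] <= 0 || b[1L] >= b[2L])
      msg <- c(msg, sprintf("%s must be c(low, high) with 0 < low < high", bn))
  }
  pos <- c("isiMax", "minBurstSpikes", "gammaAmpSdThreshold",
           "ripplePowerSdThreshold", "liaSmoothWindow", "liaDcWindow",
           "liaMinInterval", "rateWindow", "thetaDeltaRatioThreshold",
           "minSwrCount", "nShuffles", "nPermutations", "speedCalibration",
           "encoderEdgesPerRev", "wheelDiameter", "speedInterval",
           "lmMinDuration")
  for (pn in pos) {
    v <- slot(object, pn)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", pn))
  }
  if (length(object@peakPhaseWindow) != 2L)
    msg <- c(msg, "peakPhaseWindow must have length 2")
  if (length(msg)) msg else TRUE
})

#' Synthetic session specification
#'
#' Parameters of the synthetic session generator. The generator emulates:
#' state-dependent 5-12 Hz theta with a 2-4 Hz delta component and
#' irregular <5 Hz activity (LIA) between theta periods; 55-80 Hz mid-gamma
#' whose amplitude peaks at the theta peak; 130-230 Hz ripple events during
#' immobility; and a unit firing rhythmic accommodating bursts phase-locked
#' near the theta peak, with state-dependent mean rates (about 55 Hz in
#' locomotion, 40 Hz in immobility), burst incidence above 3 Hz, median
#' burst durations of 60-120 ms, intraburst frequencies of 75-150 Hz and
#' interburst intervals of 130-270 ms.
#'
#' @slot duration session length, seconds.
#' @slot schedule an \code{EpochSet} over LM/SM/WS/IM covering the session.
#' @slot rate LFP sampling rate, Hz.
#' @slot thetaFreq named numeric, theta frequency per state (Hz); states
#'   with frequency 0 carry no theta (LIA instead).
#' @slot thetaAmp named numeric, theta amplitude per state.
#' @slot deltaAmp,deltaFreq delta component amplitude and frequency.
#' @slot gammaFreq,gammaAmp,gammaDepth,gammaCouplingPhase mid-gamma carrier
#'   frequency (Hz), base amplitude, envelope modulation depth and coupling
#'   phase in degrees of the theta cycle (180 = theta peak).
#' @slot rippleRate,rippleFreq,rippleDuration,rippleAmp ripple events during
#'   IM: rate (events/s), carrier frequency (Hz), duration (s), amplitude.
#' @slot liaAmp,liaBand amplitude and band (Hz) of the irregular slow
#'   activity present in non-theta states.
#' @slot noiseAmp,noiseExponent amplitude and spectral exponent of the
#'   1/f^alpha background noise.
#' @slot spikePhaseMu,spikePhaseKappa preferred theta phase (degrees) and
#'   von Mises concentration of burst placement.
#' @slot stateRate named numeric, target mean firing rate per state (Hz).
#' @slot burstSpikesMean mean spikes per burst (geometry of the unit).
#' @slot intraburstStartFreq first intra-burst ISI is 1/this (Hz).
#' @slot accommodationDecay per-spike multiplicative ISI growth (>= 0);
#'   positive values give accommodating (lengthening-ISI) bursts.
#' @slot imRhythmFreq burst-pacing rhythm during non-theta states, Hz.
#' @slot cycleSkipProb probability that a burst spans into the next theta
#'   cycle (the data show occasional two-cycle bursts; no rate is reported,
#'   default 0).
#' @slot rngSeed integer seed; all randomness flows from it.
#' @export
setClass("SessionSpec",
  representation(
    duration = "numeric", schedule = "EpochSet", rate = "numeric",
    thetaFreq = "numeric", thetaAmp = "numeric",
    deltaAmp = "numeric", deltaFreq = "numeric",
    gammaFreq = "numeric", gammaAmp = "numeric", gammaDepth = "numeric",
    gammaCouplingPhase = "numeric",
    rippleRate = "numeric", rippleFreq = "numeric",
    rippleDuration = "numeric", rippleAmp = "numeric",
    liaAmp = "numeric", liaBand = "numeric",
    noiseAmp = "numeric", noiseExponent = "numeric",
    spikePhaseMu = "numeric", spikePhaseKappa = "numeric",
    stateRate = "numeric", burstSpikesMean = "numeric",
    intraburstStartFreq = "numeric", accommodationDecay = "numeric",
    imRhythmFreq = "numeric", cycleSkipProb = "numeric",
    rngSeed = "numeric"))

setValidity("SessionSpec", function(object) {
  msg <- character()
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (object@rate < 250) msg <- c(msg, "LFP rate must be >= 250 Hz")
  sch <- object@schedule
  if (length(sch@start) == 0L)
    msg <- c(msg, "schedule must contain at least one epoch")
  else {
    o <- order(sch@start)
    cover <- abs(sum(sch@end - sch@start) - object@duration) < 1e-6
    contiguous <- length(o) == 1L ||
      all(abs(sch@start[o][-1L] - sch@end[o][-length(o)]) < 1e-6)
    if (!cover || !contiguous || abs(sch@start[o][1L]) > 1e-9)
      msg <- c(msg, "schedule must tile [0, duration) without gaps")
    if (!all(sch@label %in% BEHAVIOR_STATES))
      msg <- c(msg, "schedule labels must be LM/SM/WS/IM")
  }
  amps <- c(object@thetaAmp, object@deltaAmp, object@gammaAmp,
            object@rippleAmp, object@liaAmp, object@noiseAmp)
  if (any(amps < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (object@spikePhaseKappa < 0) msg <- c(msg, "kappa must be >= 0")
  if (any(object@cycleSkipProb < 0 | object@cycleSkipProb > 1))
    msg <- c(msg, "cycleSkipProb must lie in [0, 1]")
  for (nm in c("thetaFreq", "thetaAmp", "stateRate")) {
    v <- slot(object, nm)
    if (!all(BEHAVIOR_STATES %in% names(v)))
      msg <- c(msg, sprintf("%s must be named with LM, SM, WS, IM", nm))
  }
  if (length(msg)) msg else TRUE
})
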