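#' Detect theta and non-theta periods from an LFP
#'
#' The trace is band-pass filtered for theta (5-12 Hz) and delta (2-4 Hz)
#' and a windowed power ratio is computed in sliding windows of
#' \code{cfg@rateWindow} seconds (step one quarter window). Windows whose
#' theta/delta power ratio is at least \code{cfg@thetaDeltaRatioThreshold}
#' are theta; theta epochs separated by less than
#' \code{cfg@thetaEpochMergeGap} seconds are merged. The returned epochs
#' partition the trace into \code{"theta"} and \code{"non_theta"}.
#'
#' @param x an \linkS4class{Lfp} sampled at >= 250 Hz.
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return An \linkS4class{EpochSet} with labels \code{theta} and
#'   \code{non_theta}.
#' @export
detectThetaEpochs <- function(x, cfg = analysisConfig()) {
  stopifnot(is(x, "Lfp"))
  rate <- samplingRate(x)
  if (rate < 250) stop("detectThetaEpochs needs a sampling rate >= 250 Hz")
  win <- cfg@rateWindow
  n <- length(samples(x))
  wlen <- floor(win * rate)
  if (n < wlen) stop("trace shorter than one analysis window")
  th <- bandpassFilter(samples(x), rate, cfg@thetaBand, order = 4)
  de <- bandpassFilter(samples(x), rate, cfg@deltaBand, order = 4)
  step <- max(1L, floor(wlen / 4))
  starts <- seq(1L, n - wlen + 1L, by = step)
  ratio <- vapply(starts, function(s) {
    i <- s:(s + wlen - 1L)
    pt <- mean(th[i]^2); pd <- mean(de[i]^2)
    if (pd <= 0) Inf else pt / pd
  }, numeric(1))
  isTheta <- ratio >= cfg@thetaDeltaRatioThreshold
  t0 <- startTime(x)
  tEnd <- t0 + (n - 1L) / rate
  iv <- asIntervals(numeric(), numeric())
  if (any(isTheta)) {
    ws <- t0 + (starts[isTheta] - 1L) / rate
    iv <- normalizeIntervals(asIntervals(ws, ws + win))
    # morphological closing: dilate ends by the merge gap, merge, erode back
    gap <- cfg@thetaEpochMergeGap
    iv <- normalizeIntervals(asIntervals(iv[, 1L], iv[, 2L] + gap))
    iv[, 2L] <- iv[, 2L] - gap
    iv[, 2L] <- pmin(iv[, 2L], tEnd)
    iv[, 1L] <- pmax(iv[, 1L], t0)
  }
  nonTheta <- intervalSetdiff(asIntervals(t0, tEnd), iv)
  epochSet(c(iv[, 1L], nonTheta[, 1L]), c(iv[, 2L], nonTheta[, 2L]),
           c(rep("theta", nrow(iv)), rep("non_theta", nrow(nonTheta))))
}

#' Theta phase by linear interpolation between troughs
#'
#' Theta phase is defined on the trough-origin convention: the trace is
#' band-pass filtered in the theta band, troughs are detected as local
#' minima, and phase increases linearly from 0 deg at each trough to
#' 360 deg at the next. Samples before the first and after the last trough
#' carry \code{NA} phase. The peak of a symmetric cycle maps to 180 deg.
#'
#' @param x an \linkS4class{Lfp}.
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return A list with \code{phase} (degrees per sample, \code{NA} outside
#'   the trough span) and \code{troughs} (an \linkS4class{EventSet} of kind
#'   \code{theta_trough}).
#' @export
thetaPhase <- function(x, cfg = analysisConfig()) {
  stopifnot(is(x, "Lfp"))
  tr <- bandTroughs(samples(x), samplingRate(x), cfg@thetaBand,
                    t0 = startTime(x), order = 4)
  if (length(tr$times) < 2L)
    stop("fewer than two detectable theta troughs")
  phase <- phaseAtTimes(tr$times, sampleTimes(x))
  list(phase = phase,
       troughs = eventSet(tr$times, "theta_trough"))
}

#' Interpolated phase of time points on a trough clock
#'
#' Given increasing trough times defining cycles, returns for each query
#' time the linearly interpolated phase in degrees: 0 at a trough rising to
#' 360 at the next trough. Times outside the first..last trough span get
#' \code{NA}.
#'
#' @param troughTimes increasing trough times (seconds) or an
#'   \linkS4class{EventSet}.
#' @param at query times, seconds.
#' @return Numeric vector of phases in [0, 360) with \code{NA} outside the
#'   covered span.
#' @export
phaseAtTimes <- function(troughTimes, at) {
  if (is(troughTimes, "EventSet")) troughTimes <- eventTimes(troughTimes)
  if (length(troughTimes) < 2L) stop("need at least two troughs")
  idx <- findInterval(at, troughTimes)
  out <- rep(NA_real_, length(at))
  ok <- idx >= 1L & idx < length(troughTimes)
  i <- idx[ok]
  frac <- (at[ok] - troughTimes[i]) / (troughTimes[i + 1L] - troughTimes[i])
  out[ok] <- (frac * 360) %% 360
  # a query exactly on the last trough is phase 0 of a cycle that never opens
  out[at == troughTimes[length(troughTimes)]] <- 0
  out
}

#' Detect high-amplitude mid-gamma troughs
#'
#' The trace is band-pass filtered in the mid-gamma band (55-80 Hz), every
#' trough-to-trough cycle's amplitude (peak-to-trough difference) is
#' measured, and the troughs of cycles whose amplitude strictly exceeds the
#' mean cycle amplitude by \code{cfg@gammaAmpSdThreshold} standard
#' deviations are returned.
#'
#' @param x an \linkS4class{Lfp} sampled at >= 400 Hz.
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return An \linkS4class{EventSet} of kind \code{gamma_trough}; the full
#'   gamma-band trough series (needed to close cycles for spike-phase
#'   measurements) is attached as attribute \code{allTroughs}.
#' @export
detectGammaTroughs <- function(x, cfg = analysisConfig()) {
  stopifnot(is(x, "Lfp"))
  rate <- samplingRate(x)
  if (rate < 400) stop("detectGammaTroughs needs a sampling rate >= 400 Hz")
  tr <- bandTroughs(samples(x), rate, cfg@midGammaBand,
                    t0 = startTime(x), order = 4)
  k <- length(tr$index)
  if (k < 3L) return(eventSet(numeric(), "gamma_trough"))
  # guard against residual filter settle: cycles within 50 ms of either
  # trace edge are excluded from amplitude statistics and detection
  margin <- 0.05
  t0 <- startTime(x); tEnd <- t0 + duration(x)
  valid <- which(tr$times[-k] > t0 + margin &
                 tr$times[-1L] < tEnd - margin)
  if (!length(valid)) return(eventSet(numeric(), "gamma_trough"))
  amp <- vapply(valid, function(i) {
    seg <- tr$filtered[tr$index[i]:tr$index[i + 1L]]
    max(seg) - min(seg)
  }, numeric(1))
  # amplitude variation at numerical noise level means the oscillation is
  # constant-amplitude: the strict > mean + 1 s.d. rule then never fires
  if (stats::sd(amp) < 1e-4 * mean(amp))
    return(eventSet(numeric(), "gamma_trough"))
  thr <- mean(amp) + cfg@gammaAmpSdThreshold * stats::sd(amp)
  keep <- valid[amp > thr]
  ev <- eventSet(tr$times[keep], "gamma_trough")
  attr(ev, "allTroughs") <- tr$times
  ev
}

#' Detect sharp-wave-associated ripples
#'
#' The ripple-band (130-230 Hz) power -- the squared analytic-signal
#' envelope of the band-passed trace, smoothed over 10 ms -- is thresholded
#' at \code{cfg@ripplePowerSdThreshold} standard deviations above its mean.
#' Each supra-threshold segment is extended on both sides to where the
#' power falls back to the mean, overlapping windows are merged, and the
#' event time is the within-window power maximum.
#'
#' @param x an \linkS4class{Lfp} sampled at >= 500 Hz.
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return An \linkS4class{EventSet} of kind \code{swr} with windows.
#' @export
detectSwr <- function(x, cfg = analysisConfig()) {
  stopifnot(is(x, "Lfp"))
  rate <- samplingRate(x)
  if (rate < 500) stop("detectSwr needs a sampling rate >= 500 Hz")
  filt <- bandpassFilter(samples(x), rate, cfg@rippleBand, order = 6)
  pow <- movingAverage(hilbertEnvelope(filt)^2, round(0.010 * rate))
  mu <- mean(pow); sdv <- stats::sd(pow)
  if (sdv == 0) return(eventSet(numeric(), "swr"))
  thr <- mu + cfg@ripplePowerSdThreshold * sdv
  above <- pow > thr
  if (!any(above)) return(eventSet(numeric(), "swr"))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segS <- starts[r$values]; segE <- ends[r$values]
  belowMean <- pow <= mu
  # extend to mean crossings
  winS <- vapply(segS, function(s) {
    j <- which(belowMean[seq_len(s)])
    if (length(j)) max(j) else 1L
  }, integer(1))
  n <- length(pow)
  winE <- vapply(segE, function(e) {
    j <- which(belowMean[e:n])
    if (length(j)) e + min(j) - 1L else n
  }, integer(1))
  iv <- normalizeIntervals(asIntervals(winS, winE + 0.5))
  winS <- floor(iv[, 1L]); winE <- floor(iv[, 2L])
  t0 <- startTime(x)
  peak <- vapply(seq_len(nrow(iv)), function(i) {
    s <- winS[i]:winE[i]
    s[which.max(pow[s])]
  }, numeric(1))
  eventSet(t0 + (peak - 1) / rate, "swr",
           windowStart = t0 + (winS - 1) / rate,
           windowEnd = t0 + (winE - 1) / rate)
}

#' Detect falling zero-crossings of large-amplitude irregular activity
#'
#' The wideband trace is low-pass treated by smoothing (0.08 s moving
#' average) followed by DC removal (subtraction of a 0.2 s moving average).
#' Falling zero-crossings of the result are detected with a minimum
#' interval of 0.2 s; when two crossings conflict the earlier one is kept.
#'
#' @param x an \linkS4class{Lfp} sampled at >= 100 Hz.
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return An \linkS4class{EventSet} of kind \code{lia_falling}.
#' @export
detectLiaCycles <- function(x, cfg = analysisConfig()) {
  stopifnot(is(x, "Lfp"))
  rate <- samplingRate(x)
  if (rate < 100) stop("detectLiaCycles needs a sampling rate >= 100 Hz")
  sm <- movingAverage(samples(x), round(cfg@liaSmoothWindow * rate))
  dc <- sm - movingAverage(sm, round(cfg@liaDcWindow * rate))
  n <- length(dc)
  cross <- which(dc[-n] > 0 & dc[-1L] <= 0)
  times <- startTime(x) + (cross - 1) / rate +
    dc[cross] / (dc[cross] - dc[cross + 1L]) / rate
  keep <- numeric()
  for (tt in times) {
    if (!length(keep) || tt - keep[length(keep)] >= cfg@liaMinInterval)
      keep <- c(keep, tt)
  }
  eventSet(keep, "lia_falling")
}

#' Event cross-correlogram
#'
#' Counts of events in \code{a} falling in time bins relative to each event
#' of \code{b}, over a symmetric window.
#'
#' @param a,b \linkS4class{EventSet}s (or numeric time vectors).
#' @param window half-width of the correlogram, seconds.
#' @param binwidth bin width, seconds.
#' @return A data.frame with \code{lag} (bin centers, seconds) and
#'   \code{count}.
#' @export
eventCorrelation <- function(a, b, window = 0.3, binwidth = 0.01) {
  at <- if (is(a, "EventSet")) eventTimes(a) else as.numeric(a)
  bt <- if (is(b, "EventSet")) eventTimes(b) else as.numeric(b)
  if (!length(at) || !length(bt)) stop("both event sets must be non-empty")
  # bins centered on zero lag
  breaks <- seq(-window - binwidth / 2, window + binwidth / 2,
                by = binwidth)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  for (t0 in bt) {
    d <- at - t0
    d <- d[d >= breaks[1L] & d <= breaks[nb + 1L]]
    if (length(d))
      counts <- counts +
        tabulate(findInterval(d, breaks, rightmost.closed = TRUE), nbins = nb)
  }
  data.frame(lag = (breaks[-length(breaks)] + breaks[-1L]) / 2,
             count = counts)
}
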