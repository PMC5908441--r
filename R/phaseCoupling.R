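#' Assign oscillation phases to spikes
#'
#' Each covered spike gets the linearly interpolated phase of the reference
#' oscillation (trough-origin convention: 0 deg = trough, 180 deg = peak).
#' Spikes outside the trough span are dropped; their count is reported as
#' an attribute.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param troughs reference troughs (\linkS4class{EventSet} or times).
#' @return Numeric vector of spike phases in [0, 360) with attribute
#'   \code{nDropped}; errors if no spike is covered.
#' @export
assignPhase <- function(train, troughs) {
  stopifnot(is(train, "SpikeTrain"))
  ph <- phaseAtTimes(troughs, spikeTimes(train))
  dropped <- sum(is.na(ph))
  ph <- ph[!is.na(ph)]
  if (!length(ph)) stop("no spikes covered by the phase series")
  attr(ph, "nDropped") <- dropped
  ph
}

#' Circular statistics of a phase sample
#'
#' Mean phase (argument of the resultant vector), mean vector length r
#' (resultant length / n, the coupling strength in [0, 1]) and the Rayleigh
#' test p-value for circular uniformity using the standard approximation
#' \code{p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))} with
#' \code{R = n r}.
#'
#' @param phases phases in degrees.
#' @param weights optional non-negative weights.
#' @return A data.frame (one row) with \code{meanPhase} (degrees in
#'   [0, 360)), \code{r}, \code{p} and \code{n}.
#' @examples
#' circularStats(c(0, 90))   # mean 45, r = cos(pi/4)
#' @export
circularStats <- function(phases, weights = NULL) {
  n <- length(phases)
  if (n == 0L) stop("circularStats needs at least one phase")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  w <- weights / sum(weights)
  rad <- degToRad(phases)
  C <- sum(w * cos(rad)); S <- sum(w * sin(rad))
  r <- sqrt(C^2 + S^2)
  meanPhase <- wrapDeg(radToDeg(atan2(S, C)))
  neff <- sum(weights)^2 / sum(weights^2)  # = n for unit weights
  R <- neff * r
  p <- exp(sqrt(1 + 4 * neff + 4 * (neff^2 - R^2)) - (1 + 2 * neff))
  data.frame(meanPhase = meanPhase, r = min(r, 1), p = min(max(p, 0), 1),
             n = n)
}

#' Circular mean of phases in degrees
#' @param phases phases in degrees.
#' @return Mean direction in [0, 360).
#' @export
circularMean <- function(phases) {
  rad <- degToRad(phases)
  wrapDeg(radToDeg(atan2(mean(sin(rad)), mean(cos(rad)))))
}

#' Spike coupling to supra-threshold mid-gamma cycles
#'
#' Applies the cross-frequency gate first: the detected gamma troughs must
#' themselves be coupled to the theta cycle near its peak (circular mean of
#' their theta phases within \code{peakWindow} degrees of 180 and Rayleigh
#' p < 0.05). If the gate fails the function refuses with
#' \code{status = "refused"}. Otherwise spike phases are measured on the
#' gamma-trough clock, restricted to spikes falling inside detected
#' (supra-threshold) gamma cycles -- the cycle opened by each detected
#' trough, closed by the next trough of the full gamma trough series.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param gammaTroughs detected supra-threshold gamma troughs
#'   (\linkS4class{EventSet} from \code{\link{detectGammaTroughs}}).
#' @param allGammaTroughs all gamma-band troughs (used to close cycles and
#'   interpolate phase); defaults to the \code{allTroughs} attribute that
#'   \code{\link{detectGammaTroughs}} attaches, falling back to
#'   \code{gammaTroughs}.
#' @param thetaTroughs theta troughs for the cross-frequency gate.
#' @param halfWindowDeg half-width (degrees) of the gate window around the
#'   theta peak (default 45).
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return A list with \code{status} (\code{"ok"} or \code{"refused"}),
#'   \code{reason} and, when ok, \code{stats} (a \code{circularStats} row)
#'   and \code{nSpikesUsed}.
#' @export
gammaCoupling <- function(train, gammaTroughs, thetaTroughs,
                          allGammaTroughs = NULL,
                          halfWindowDeg = 45, cfg = analysisConfig()) {
  stopifnot(is(train, "SpikeTrain"))
  if (is.null(allGammaTroughs)) {
    allGammaTroughs <- attr(gammaTroughs, "allTroughs")
    if (is.null(allGammaTroughs)) allGammaTroughs <- gammaTroughs
  }
  gt <- if (is(gammaTroughs, "EventSet")) eventTimes(gammaTroughs) else
    as.numeric(gammaTroughs)
  allGt <- if (is(allGammaTroughs, "EventSet")) eventTimes(allGammaTroughs)
    else as.numeric(allGammaTroughs)
  if (length(gt) < 10L)
    return(list(status = "refused", reason = "too few gamma troughs"))
  # gate: gamma troughs must couple near the theta peak
  gph <- phaseAtTimes(thetaTroughs, gt)
  gph <- gph[!is.na(gph)]
  if (length(gph) < 10L)
    return(list(status = "refused",
                reason = "gamma troughs not covered by theta phase"))
  gate <- circularStats(gph)
  if (gate$p >= 0.05 || circDistDeg(gate$meanPhase, 180) > halfWindowDeg)
    return(list(status = "refused",
                reason = "no cross-frequency coupling of gamma to theta peak",
                gate = gate))
  # spike phases within detected gamma cycles only
  spikes <- spikeTimes(train)
  nxt <- vapply(gt, function(g) {
    after <- allGt[allGt > g + 1e-9]
    if (length(after)) after[1L] else NA_real_
  }, numeric(1))
  ok <- !is.na(nxt)
  cyc <- asIntervals(gt[ok], nxt[ok])
  inside <- pointsInIntervals(spikes, cyc)
  if (!any(inside))
    return(list(status = "refused",
                reason = "no spikes inside supra-threshold gamma cycles",
                gate = gate))
  ph <- phaseAtTimes(allGt, spikes[inside])
  ph <- ph[!is.na(ph)]
  list(status = "ok", gate = gate, stats = circularStats(ph),
       nSpikesUsed = length(ph))
}

#' Coupling of one LFP's theta troughs to another's theta phase
#'
#' Detects theta troughs in the target trace and measures their phases on
#' the reference trough clock; identical traces yield mean 0 deg with
#' r near 1.
#'
#' @param target an \linkS4class{Lfp} (e.g. entorhinal LFP).
#' @param referenceTroughs theta troughs of the reference LFP
#'   (\linkS4class{EventSet} or times).
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return A \code{circularStats} row for the target troughs on the
#'   reference clock.
#' @export
lfpTroughCoupling <- function(target, referenceTroughs,
                              cfg = analysisConfig()) {
  stopifnot(is(target, "Lfp"))
  if (duration(target) < 10)
    stop("lfpTroughCoupling needs at least 10 s of overlap")
  tr <- bandTroughs(samples(target), samplingRate(target), cfg@thetaBand,
                    t0 = startTime(target), order = 4)
  ph <- phaseAtTimes(referenceTroughs, tr$times)
  ph <- ph[!is.na(ph)]
  if (length(ph) < 10L) stop("fewer than 10 covered target troughs")
  circularStats(ph)
}

#' Smoothed circular phase histogram
#'
#' Bins phases on [0, 360), smooths by circular (wrap-around) convolution
#' with a Gaussian kernel and normalizes the mass to 1.
#'
#' @param phases phases in degrees.
#' @param binwidth bin width in degrees (default 20).
#' @param smoothSd Gaussian kernel s.d. in bins (default 1; 0 disables
#'   smoothing).
#' @return A data.frame with \code{phase} (bin centers, degrees) and
#'   \code{density} summing to 1.
#' @export
phaseHistogram <- function(phases, binwidth = 20, smoothSd = 1) {
  if (!length(phases)) stop("phaseHistogram needs at least one phase")
  nb <- round(360 / binwidth)
  breaks <- seq(0, 360, length.out = nb + 1L)
  counts <- tabulate(findInterval(wrapDeg(phases), breaks,
                                  rightmost.closed = TRUE), nbins = nb)
  if (smoothSd > 0) {
    half <- max(1L, ceiling(3 * smoothSd))
    k <- stats::dnorm(-half:half, sd = smoothSd)
    k <- k / sum(k)
    sm <- numeric(nb)
    for (j in -half:half)
      sm <- sm + k[j + half + 1L] *
        counts[((seq_len(nb) - 1L + j) %% nb) + 1L]
    counts <- sm
  }
  data.frame(phase = (breaks[-length(breaks)] + breaks[-1L]) / 2,
             density = counts / sum(counts))
}
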