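#' Detect spike bursts from inter-spike intervals
#'
#' A burst is a maximal run of consecutive spikes whose inter-spike
#' intervals are all below \code{cfg@isiMax} (40 ms) and that contains at
#' least \code{cfg@minBurstSpikes} spikes (default 4, i.e. a train of more
#' than 3 spikes). Bursts are non-overlapping and every spike belongs to at
#' most one burst.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return A data.frame with one row per burst: \code{start}, \code{end}
#'   (first/last spike, s), \code{n} spikes, \code{duration} (ms) and
#'   \code{intraburstFreq} (Hz, \code{(n - 1) / duration}).
#' @examples
#' tr <- spikeTrain(c(0, 0.01, 0.02, 0.03, 0.5))
#' detectBursts(tr)
#' @export
detectBursts <- function(train, cfg = analysisConfig()) {
  stopifnot(is(train, "SpikeTrain"))
  t <- spikeTimes(train)
  empty <- data.frame(start = numeric(), end = numeric(), n = integer(),
                      duration = numeric(), intraburstFreq = numeric())
  if (length(t) < cfg@minBurstSpikes) return(empty)
  short <- diff(t) < cfg@isiMax
  r <- rle(short)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= cfg@minBurstSpikes - 1L)
  if (!length(keep)) return(empty)
  first <- starts[keep]            # index of first spike of the run
  last <- ends[keep] + 1L          # ISI run of length L spans L + 1 spikes
  durMs <- (t[last] - t[first]) * 1000
  data.frame(start = t[first], end = t[last],
             n = as.integer(last - first + 1L),
             duration = durMs,
             intraburstFreq = (last - first) / (durMs / 1000))
}

#' Per-state firing rates in 1 s windows
#'
#' Each epoch of a state is tiled with non-overlapping
#' \code{cfg@rateWindow}-second windows anchored at the epoch start;
#' trailing partial windows are dropped. The rate is the spike count per
#' window; the per-state value is the mean and s.d. over windows.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param epochs an \linkS4class{EpochSet} of behavioral states.
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return A data.frame with \code{state}, \code{mean}, \code{sd} (Hz) and
#'   \code{nWindows}; states with no complete window get \code{NA}.
#' @export
firingRates <- function(train, epochs, cfg = analysisConfig()) {
  stopifnot(is(train, "SpikeTrain"), is(epochs, "EpochSet"))
  t <- spikeTimes(train)
  states <- unique(epochLabels(epochs))
  res <- lapply(states, function(st) {
    counts <- windowSpikeCounts(t, epochsWithLabel(epochs, st),
                                cfg@rateWindow)
    if (!length(counts))
      return(data.frame(state = st, mean = NA_real_, sd = NA_real_,
                        nWindows = 0L))
    ms <- meanSd(counts / cfg@rateWindow)
    data.frame(state = st, mean = ms[["mean"]], sd = ms[["sd"]],
               nWindows = length(counts))
  })
  do.call(rbind, res)
}

# spike counts in full rate windows tiling each epoch from its start
windowSpikeCounts <- function(times, epochs, win) {
  counts <- integer()
  for (i in seq_len(length(epochs))) {
    s <- epochs@start[i]; e <- epochs@end[i]
    nWin <- floor((e - s) / win + 1e-9)
    if (nWin < 1L) next
    edges <- s + win * (0:nWin)
    counts <- c(counts,
                tabulate(findInterval(times[times >= s & times < edges[nWin + 1L]],
                                      edges), nbins = nWin))
  }
  counts
}

#' Per-state burst statistics
#'
#' Bursts are assigned to a behavioral state by their first spike.
#' Durations and interburst intervals (first spike to first spike of the
#' next burst, within the same state epoch only) are summarized as median
#' and interquartile range; intraburst frequency as mean and s.d. over
#' bursts; burst incidence as the mean and s.d. of burst counts in 1 s
#' windows tiling the state's epochs.
#'
#' @param bursts a burst data.frame from \code{\link{detectBursts}}.
#' @param epochs an \linkS4class{EpochSet} of behavioral states.
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return A data.frame with one row per state: \code{nBursts},
#'   \code{durationMedian}, \code{durationIqr} (ms), \code{ibiMedian},
#'   \code{ibiIqr} (ms), \code{intraburstMean}, \code{intraburstSd} (Hz),
#'   \code{incidenceMean}, \code{incidenceSd} (Hz). States with no bursts
#'   carry \code{NA} (the unavailable sentinel).
#' @export
burstStatistics <- function(bursts, epochs, cfg = analysisConfig()) {
  stopifnot(is.data.frame(bursts), is(epochs, "EpochSet"))
  states <- unique(epochLabels(epochs))
  res <- lapply(states, function(st) {
    ep <- epochsWithLabel(epochs, st)
    iv <- epochIntervals(ep)
    inState <- pointsInIntervals(bursts$start, iv)
    b <- bursts[inState, , drop = FALSE]
    inc <- windowBurstCounts(bursts$start, ep, cfg@rateWindow)
    incMs <- meanSd(inc / cfg@rateWindow)
    if (nrow(b) == 0L)
      return(data.frame(state = st, nBursts = 0L,
                        durationMedian = NA_real_, durationIqr = NA_real_,
                        ibiMedian = NA_real_, ibiIqr = NA_real_,
                        intraburstMean = NA_real_, intraburstSd = NA_real_,
                        incidenceMean = if (length(inc)) incMs[["mean"]] else NA_real_,
                        incidenceSd = if (length(inc)) incMs[["sd"]] else NA_real_))
    # interburst intervals between consecutive bursts in the same epoch
    epIdx <- findInterval(b$start, ep@start)
    ibis <- numeric()
    for (k in unique(epIdx)) {
      bs <- sort(b$start[epIdx == k])
      if (length(bs) > 1L) ibis <- c(ibis, diff(bs) * 1000)
    }
    dur <- medianIqr(b$duration)
    ibi <- medianIqr(ibis)
    intra <- meanSd(b$intraburstFreq)
    data.frame(state = st, nBursts = nrow(b),
               durationMedian = dur[["median"]], durationIqr = dur[["iqr"]],
               ibiMedian = if (length(ibis)) ibi[["median"]] else NA_real_,
               ibiIqr = if (length(ibis)) ibi[["iqr"]] else NA_real_,
               intraburstMean = intra[["mean"]], intraburstSd = intra[["sd"]],
               incidenceMean = if (length(inc)) incMs[["mean"]] else NA_real_,
               incidenceSd = if (length(inc)) incMs[["sd"]] else NA_real_)
  })
  do.call(rbind, res)
}

windowBurstCounts <- function(burstStarts, epochs, win) {
  windowSpikeCounts(burstStarts, epochs, win)
}

#' Locomotion-immobility rate index
#'
#' \code{(LM - IM) / (LM + IM)}: positive when the unit fires faster during
#' locomotion than immobility, in [-1, 1].
#'
#' @param rateLm,rateIm mean firing rates (Hz).
#' @return The index, or \code{NA} if both rates are zero or either is
#'   missing.
#' @export
lmImIndex <- function(rateLm, rateIm) {
  if (is.na(rateLm) || is.na(rateIm)) return(NA_real_)
  if (rateLm + rateIm == 0) return(NA_real_)
  (rateLm - rateIm) / (rateLm + rateIm)
}

#' Spike-train autocorrelogram with rhythmicity peak
#'
#' Symmetric histogram of spike-pair lags (zero-lag self-pairs excluded),
#' optionally restricted to spikes inside given epochs. The rhythmicity
#' peak is the maximum of the smoothed positive-lag counts within the
#' 80-250 ms search range typical of theta-band bursting.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param binwidth bin width, seconds.
#' @param maxLag maximum lag, seconds.
#' @param epochs optional \linkS4class{EpochSet}; only spikes inside are
#'   used.
#' @param peakRange numeric(2), seconds, search range for the peak.
#' @return A list with \code{lags} (bin centers, s), \code{counts} and
#'   \code{peakLag} (s, \code{NA} when no counts fall in the range).
#' @export
autocorrelogram <- function(train, binwidth = 0.005, maxLag = 0.5,
                            epochs = NULL, peakRange = c(0.08, 0.25)) {
  stopifnot(is(train, "SpikeTrain"))
  t <- spikeTimes(train)
  if (!is.null(epochs))
    t <- t[pointsInIntervals(t, epochIntervals(epochs))]
  if (length(t) < 2L) stop("autocorrelogram needs at least 2 spikes")
  breaks <- seq(-maxLag - binwidth / 2, maxLag + binwidth / 2, by = binwidth)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  n <- length(t)
  for (i in seq_len(n - 1L)) {
    d <- t[(i + 1L):n] - t[i]
    d <- d[d <= maxLag + binwidth / 2]
    if (!length(d)) next
    counts <- counts +
      tabulate(findInterval(d, breaks, rightmost.closed = TRUE), nbins = nb)
  }
  mid <- (breaks[-length(breaks)] + breaks[-1L]) / 2
  counts <- counts + rev(counts)   # symmetric, zero-lag self-pairs excluded
  sm <- movingAverage(counts, 3L)
  inRange <- mid >= peakRange[1L] & mid <= peakRange[2L]
  peakLag <- NA_real_
  if (any(inRange) && sum(counts[inRange]) > 0) {
    smR <- sm[inRange]; rawR <- counts[inRange]
    best <- which(smR == max(smR))
    # break smoothing ties by the raw counts
    peakLag <- mid[inRange][best[which.max(rawR[best])]]
  }
  list(lags = mid, counts = counts, peakLag = peakLag)
}

#' Spikes per theta cycle
#'
#' Counts spikes in every trough-to-trough theta cycle, including cycles
#' with zero spikes.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param troughs theta troughs (\linkS4class{EventSet} or numeric times).
#' @return \code{c(mean, sd)} of spikes per cycle.
#' @export
spikesPerCycle <- function(train, troughs) {
  tt <- if (is(troughs, "EventSet")) eventTimes(troughs) else
    as.numeric(troughs)
  if (length(tt) < 2L) stop("need at least two theta troughs")
  t <- spikeTimes(train)
  counts <- tabulate(findInterval(t[t >= tt[1L] & t < tt[length(tt)]], tt),
                     nbins = length(tt) - 1L)
  ms <- meanSd(counts)
  c(mean = ms[["mean"]], sd = ms[["sd"]])
}
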