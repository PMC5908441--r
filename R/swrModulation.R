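#' Test firing-rate modulation during sharp-wave ripples
#'
#' Compares the unit's firing rate inside SWR windows to its rate outside
#' SWRs, excluding theta periods. \code{rateInside} is total spikes in SWR
#' windows over total window duration; \code{lambdaOutside} is the rate in
#' the eligible (non-theta, non-SWR) time. Two p-values are produced:
#' \describe{
#'   \item{Poisson}{the two-sided tail probability of the observed inside
#'     count under a Poisson law with expectation
#'     \code{lambdaOutside * totalSwrDuration}, doubling the smaller tail
#'     and capping at 1.}
#'   \item{shuffle}{the rank of the observed inside rate among
#'     \code{cfg@nShuffles} (1000) surrogate rates, each measured in a
#'     random set of windows matching the SWR durations placed in the
#'     eligible time, two-sided with add-one correction.}
#' }
#' Units with fewer than \code{cfg@minSwrCount} (20) SWRs are refused.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param swr an \linkS4class{EventSet} of kind \code{swr} with windows.
#' @param thetaEpochs an \linkS4class{EpochSet} containing \code{theta}
#'   epochs to exclude (may be empty).
#' @param sessionStart,sessionEnd analyzed span, seconds.
#' @param cfg an \linkS4class{AnalysisConfig}; \code{cfg@rngSeed} seeds the
#'   shuffle.
#' @param shuffle compute the shuffle p-value as well (default TRUE); the
#'   closed-form Poisson p is always computed.
#' @return A list with \code{status}, \code{nSwr}, \code{rateInside},
#'   \code{lambdaOutside} (Hz), \code{pPoisson}, \code{pShuffle} and
#'   \code{direction} (\code{"increase"}/\code{"decrease"}/\code{"none"}).
#' @export
swrRateTest <- function(train, swr, thetaEpochs, sessionStart, sessionEnd,
                        cfg = analysisConfig(), shuffle = TRUE) {
  stopifnot(is(train, "SpikeTrain"), is(swr, "EventSet"),
            identical(eventKind(swr), "swr"))
  nSwr <- length(swr)
  if (nSwr < cfg@minSwrCount)
    return(list(status = "refused", nSwr = nSwr,
                reason = sprintf("fewer than %d detected SWRs",
                                 as.integer(cfg@minSwrCount))))
  win <- asIntervals(swr@windowStart, swr@windowEnd)
  winNorm <- normalizeIntervals(win)
  totalDur <- intervalTotal(win)
  session <- asIntervals(sessionStart, sessionEnd)
  thetaIv <- if (is(thetaEpochs, "EpochSet") &&
                 "theta" %in% epochLabels(thetaEpochs))
    epochIntervals(thetaEpochs, "theta") else asIntervals(numeric(), numeric())
  eligible <- intervalSetdiff(intervalSetdiff(session, winNorm), thetaIv)
  outDur <- intervalTotal(eligible)
  if (outDur <= 0) stop("no eligible time outside SWRs and theta")
  t <- spikeTimes(train)
  kIn <- sum(pointsInIntervals(t, winNorm))
  kOut <- sum(pointsInIntervals(t, eligible))
  rateInside <- kIn / totalDur
  lambdaOutside <- kOut / outDur
  pPoisson <- poissonTwoSidedP(kIn, lambdaOutside * totalDur)
  pShuffle <- if (shuffle)
    swrShuffleP(t, win[, 2L] - win[, 1L], eligible, rateInside,
                lambdaOutside, cfg) else NA_real_
  direction <- if (rateInside > lambdaOutside) "increase"
    else if (rateInside < lambdaOutside) "decrease" else "none"
  list(status = "ok", nSwr = nSwr, rateInside = rateInside,
       lambdaOutside = lambdaOutside, pPoisson = pPoisson,
       pShuffle = pShuffle, direction = direction,
       swrDuration = totalDur, outsideDuration = outDur)
}

# two-sided Poisson tail: double the smaller of P(X <= k), P(X >= k), cap 1
poissonTwoSidedP <- function(k, mu) {
  if (mu <= 0) return(1)
  lower <- stats::ppois(k, mu)
  upper <- 1 - stats::ppois(k - 1, mu)
  min(1, 2 * min(lower, upper))
}

# surrogate windows matching the SWR durations, sampled without
# replacement from the eligible time
swrShuffleP <- function(spikes, durations, eligible, rateObs, lambdaOut,
                        cfg) {
  set.seed(cfg@rngSeed)
  nSh <- as.integer(cfg@nShuffles)
  segLen <- eligible[, 2L] - eligible[, 1L]
  totalEligible <- sum(segLen)
  rates <- numeric(nSh)
  for (s in seq_len(nSh)) {
    # place each window uniformly in eligible time, rejecting overlaps
    placed <- matrix(numeric(), ncol = 2L)
    for (d in durations) {
      for (attempt in 1:50) {
        u <- stats::runif(1, 0, totalEligible - d)
        seg <- which(cumsum(segLen) > u)[1L]
        off <- u - c(0, cumsum(segLen))[seg]
        st <- eligible[seg, 1L] + off
        en <- st + d
        if (en > eligible[seg, 2L]) next
        if (nrow(placed) &&
            any(st < placed[, 2L] & en > placed[, 1L])) next
        placed <- rbind(placed, c(st, en))
        break
      }
    }
    dur <- sum(placed[, 2L] - placed[, 1L])
    if (dur > 0) {
      cnt <- sum(findInterval(placed[, 2L], spikes) -
                 findInterval(placed[, 1L] - 1e-12, spikes))
      rates[s] <- cnt / dur
    } else rates[s] <- lambdaOut
  }
  extreme <- sum(abs(rates - lambdaOut) >= abs(rateObs - lambdaOut))
  (extreme + 1) / (nSh + 1)
}

#' Peri-SWR time histogram of spiking
#'
#' Spike counts in time bins around each SWR event time, normalized to
#' rate (Hz) per bin.
#'
#' @param train a \linkS4class{SpikeTrain}.
#' @param swr an \linkS4class{EventSet} of kind \code{swr}.
#' @param window half-width, seconds.
#' @param binwidth bin width, seconds.
#' @return A data.frame with \code{lag} (s) and \code{rate} (Hz).
#' @export
periSwrHistogram <- function(train, swr, window = 0.5, binwidth = 0.02) {
  cc <- eventCorrelation(spikeTimes(train), swr, window = window,
                         binwidth = binwidth)
  data.frame(lag = cc$lag, rate = cc$count / (length(swr) * binwidth))
}
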