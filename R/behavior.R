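#' Convert a rotary-encoder counter to speed and a movement flag
#'
#' The quadrature encoder on the treadmill axle yields
#' \code{cfg@encoderEdgesPerRev} edges per revolution of a wheel of
#' diameter \code{cfg@wheelDiameter} meters. Speed is computed every
#' \code{cfg@speedInterval} seconds (10 ms) as the distance traveled since
#' the previous step divided by the elapsed time:
#' \code{(dCounter / edgesPerRev) * pi * wheelDiameter / dt}. The movement
#' flag is raised when the counter increased by at least 2 relative to its
#' value 10 ms earlier and dropped when it increased by less than 11
#' relative to its value 50 ms earlier.
#'
#' Backward wheel motion decrements the counter; speed is reported as the
#' magnitude of the signed displacement and the sign is retained in the
#' \code{direction} column.
#'
#' @param counter integer-valued counter samples.
#' @param counterRate sampling rate of \code{counter}, Hz (>= 100).
#' @param t0 time of the first counter sample, seconds.
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return A data.frame (the speed series) with columns \code{time} (s),
#'   \code{speed} (m/s, >= 0), \code{direction} (-1/0/+1) and
#'   \code{moving} (logical movement flag).
#' @examples
#' # constant 20 ticks per 10 ms
#' cnt <- cumsum(rep(2, 500))        # sampled at 1 kHz
#' s <- encoderToSpeed(cnt, 1000)
#' mean(s$speed)                     # ~0.4587 m/s
#' @export
encoderToSpeed <- function(counter, counterRate, t0 = 0,
                           cfg = analysisConfig()) {
  if (any(counter != round(counter)))
    stop("encoder counter must be integer-valued")
  if (counterRate < 1 / cfg@speedInterval)
    stop("counter must be sampled at least every speedInterval")
  dt <- cfg@speedInterval
  stepSamp <- round(dt * counterRate)
  idx <- seq(1L, length(counter), by = stepSamp)
  cnt <- counter[idx]
  times <- t0 + (idx - 1L) / counterRate
  n <- length(cnt)
  if (n < 2L) stop("counter too short for one speed interval")
  dc <- c(0, diff(cnt))
  dist <- dc / cfg@encoderEdgesPerRev * pi * cfg@wheelDiameter
  speed <- abs(dist) / dt
  # hysteresis flag: raise on >= 2 ticks per 10 ms, drop on < 11 per 50 ms
  dc50 <- c(rep(0, min(5L, n)), cnt[-seq_len(min(5L, n))] -
              cnt[seq_len(max(0L, n - 5L))])
  moving <- logical(n)
  state <- FALSE
  for (i in seq_len(n)) {
    if (dc[i] >= 2) state <- TRUE
    else if (dc50[i] < 11) state <- FALSE
    moving[i] <- state
  }
  data.frame(time = times, speed = speed, direction = sign(dc),
             moving = moving)
}

#' Speed from the calibrated analogue voltage channel
#'
#' @param volts voltage samples of the speed channel.
#' @param cfg an \linkS4class{AnalysisConfig}; 1 V encodes
#'   \code{cfg@speedCalibration} m/s (0.6912).
#' @return Speeds in m/s.
#' @export
speedFromVoltage <- function(volts, cfg = analysisConfig()) {
  as.numeric(volts) * cfg@speedCalibration
}

#' Segment a session into the four behavioral states
#'
#' Produces a mutually exclusive, exhaustive labeling with the states
#' locomotion (LM), small movements (SM), whisking/sniffing (WS) and
#' immobility (IM). LM is a sustained movement-flag period longer than
#' \code{cfg@lmMinDuration} seconds whose mean speed exceeds
#' \code{cfg@lmSpeedThreshold} m/s; remaining movement-flag periods are SM;
#' periods where the (optional) whisking channel is active without
#' movement are WS; everything else is IM.
#'
#' @param speedSeries a data.frame from \code{\link{encoderToSpeed}}.
#' @param whisk optional logical vector, whisking active per speed sample.
#' @param sessionStart,sessionEnd session span to label; defaults to the
#'   span of the speed series.
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return An \linkS4class{EpochSet} over LM/SM/WS/IM summing to the
#'   session duration.
#' @export
segmentStates <- function(speedSeries, whisk = NULL,
                          sessionStart = NULL, sessionEnd = NULL,
                          cfg = analysisConfig()) {
  stopifnot(is.data.frame(speedSeries),
            all(c("time", "speed", "moving") %in% names(speedSeries)))
  dt <- cfg@speedInterval
  tms <- speedSeries$time
  if (is.null(sessionStart)) sessionStart <- tms[1L]
  if (is.null(sessionEnd)) sessionEnd <- tms[length(tms)] + dt
  if (!is.null(whisk) && length(whisk) != length(tms))
    stop("whisk must align with the speed series")

  runsToIntervals <- function(flag) {
    if (!any(flag)) return(asIntervals(numeric(), numeric()))
    r <- rle(flag)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values
    normalizeIntervals(asIntervals(tms[starts[keep]],
                                   tms[ends[keep]] + dt))
  }

  movIv <- runsToIntervals(speedSeries$moving)
  lmList <- list(); smList <- list()
  if (nrow(movIv)) {
    for (i in seq_len(nrow(movIv))) {
      span <- movIv[i, 2L] - movIv[i, 1L]
      inRun <- tms >= movIv[i, 1L] & tms < movIv[i, 2L]
      mspd <- mean(speedSeries$speed[inRun])
      if (span > cfg@lmMinDuration && isTRUE(mspd > cfg@lmSpeedThreshold))
        lmList[[length(lmList) + 1L]] <- movIv[i, ]
      else
        smList[[length(smList) + 1L]] <- movIv[i, ]
    }
  }
  lmIv <- if (length(lmList)) normalizeIntervals(do.call(rbind, lmList))
          else asIntervals(numeric(), numeric())
  smIv <- if (length(smList)) normalizeIntervals(do.call(rbind, smList))
          else asIntervals(numeric(), numeric())
  session <- asIntervals(sessionStart, sessionEnd)
  lmIv <- intervalIntersect(lmIv, session)
  smIv <- intervalIntersect(smIv, session)
  wsIv <- asIntervals(numeric(), numeric())
  if (!is.null(whisk)) {
    wsIv <- intervalIntersect(runsToIntervals(as.logical(whisk)), session)
    wsIv <- intervalSetdiff(wsIv, normalizeIntervals(rbind(lmIv, smIv)))
  }
  imIv <- intervalSetdiff(session,
                          normalizeIntervals(rbind(lmIv, smIv, wsIv)))
  starts <- c(lmIv[, 1L], smIv[, 1L], wsIv[, 1L], imIv[, 1L])
  ends <- c(lmIv[, 2L], smIv[, 2L], wsIv[, 2L], imIv[, 2L])
  labs <- c(rep("LM", nrow(lmIv)), rep("SM", nrow(smIv)),
            rep("WS", nrow(wsIv)), rep("IM", nrow(imIv)))
  epochSet(starts, ends, labs)
}
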