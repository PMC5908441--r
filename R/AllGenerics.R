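#' @include AllClasses.R
NULL

#' Construct an Lfp
#'
#' @param samples numeric voltage vector.
#' @param rate sampling rate, Hz.
#' @param t0 time of the first sample, seconds.
#' @return An \linkS4class{Lfp}.
#' @examples
#' x <- lfp(sin(2 * pi * 8 * seq(0, 1, by = 1e-3)), rate = 1000)
#' samplingRate(x)
#' @export
lfp <- function(samples, rate, t0 = 0) {
  new("Lfp", samples = as.numeric(samples), rate = as.numeric(rate),
      t0 = as.numeric(t0))
}

#' Construct a SpikeTrain
#'
#' @param times strictly increasing spike times, seconds.
#' @param unitId unit label.
#' @return A \linkS4class{SpikeTrain}.
#' @export
spikeTrain <- function(times, unitId = "unit") {
  new("SpikeTrain", times = as.numeric(times), unitId = as.character(unitId))
}

#' Construct an EpochSet
#'
#' @param start,end interval bounds, seconds.
#' @param label character label per interval.
#' @return An \linkS4class{EpochSet}.
#' @export
epochSet <- function(start = numeric(), end = numeric(),
                     label = character()) {
  if (length(label) == 1L && length(start) > 1L)
    label <- rep(label, length(start))
  o <- order(start)
  new("EpochSet", start = as.numeric(start)[o], end = as.numeric(end)[o],
      label = as.character(label)[o])
}

#' Construct an EventSet
#'
#' @param times increasing event times, seconds.
#' @param kind event kind (\code{"theta_trough"}, \code{"gamma_trough"},
#'   \code{"swr"} or \code{"lia_falling"}).
#' @param windowStart,windowEnd optional per-event windows.
#' @return An \linkS4class{EventSet}.
#' @export
eventSet <- function(times, kind, windowStart = numeric(),
                     windowEnd = numeric()) {
  new("EventSet", times = as.numeric(times), kind = kind,
      windowStart = as.numeric(windowStart),
      windowEnd = as.numeric(windowEnd))
}

#' Construct an AnalysisConfig
#'
#' All arguments override the documented defaults of
#' \linkS4class{AnalysisConfig}; see that class for meanings and units.
#'
#' @param ... named slot overrides, e.g. \code{minBurstSpikes = 3}.
#' @return An \linkS4class{AnalysisConfig}.
#' @examples
#' cfg <- analysisConfig(minBurstSpikes = 3)
#' cfg@isiMax
#' @export
analysisConfig <- function(...) {
  args <- list(...)
  bad <- setdiff(names(args), slotNames("AnalysisConfig"))
  if (length(bad))
    stop("unknown AnalysisConfig fields: ", paste(bad, collapse = ", "))
  do.call(new, c(list("AnalysisConfig"), args))
}

## ---- generics ----

#' @rdname lfp
#' @param object,x an object of the documented class.
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname lfp
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname lfp
#' @export
setGeneric("startTime", function(object) standardGeneric("startTime"))
#' Session-time helpers
#'
#' \code{duration} returns the spanned time in seconds; \code{sampleTimes}
#' the time stamp of every LFP sample.
#' @param object an \linkS4class{Lfp}, \linkS4class{SpikeTrain},
#'   \linkS4class{EpochSet} or \linkS4class{EventSet}.
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))
#' @rdname duration
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))
#' @rdname spikeTrain
#' @param object object to access.
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))
#' @rdname spikeTrain
#' @export
setGeneric("unitId", function(object) standardGeneric("unitId"))
#' @rdname eventSet
#' @param object object to access.
#' @export
setGeneric("eventTimes", function(object) standardGeneric("eventTimes"))
#' @rdname eventSet
#' @export
setGeneric("eventKind", function(object) standardGeneric("eventKind"))
#' @rdname eventSet
#' @export
setGeneric("eventWindows", function(object) standardGeneric("eventWindows"))
#' @rdname epochSet
#' @param object object to access.
#' @export
setGeneric("epochLabels", function(object) standardGeneric("epochLabels"))
#' Subset an EpochSet by label
#' @param object an \linkS4class{EpochSet}.
#' @param label labels to keep.
#' @return An \linkS4class{EpochSet} with only the requested labels.
#' @export
setGeneric("epochsWithLabel",
           function(object, label) standardGeneric("epochsWithLabel"))

setMethod("samples", "Lfp", function(object) object@samples)
setMethod("samplingRate", "Lfp", function(object) object@rate)
setMethod("startTime", "Lfp", function(object) object@t0)
setMethod("duration", "Lfp", function(object)
  (length(object@samples) - 1L) / object@rate)
setMethod("sampleTimes", "Lfp", function(object)
  object@t0 + (seq_along(object@samples) - 1) / object@rate)

setMethod("spikeTimes", "SpikeTrain", function(object) object@times)
setMethod("unitId", "SpikeTrain", function(object) object@unitId)
setMethod("duration", "SpikeTrain", function(object)
  if (length(object@times) < 2L) 0 else diff(range(object@times)))
setMethod("length", "SpikeTrain", function(x) length(x@times))

setMethod("eventTimes", "EventSet", function(object) object@times)
setMethod("eventKind", "EventSet", function(object) object@kind)
setMethod("eventWindows", "EventSet", function(object) {
  n <- length(object@times)
  hasWin <- length(object@windowStart) == n && n > 0L
  data.frame(start = if (hasWin) object@windowStart else rep(NA_real_, n),
             time = object@times,
             end = if (hasWin) object@windowEnd else rep(NA_real_, n))
})
setMethod("length", "EventSet", function(x) length(x@times))

setMethod("epochLabels", "EpochSet", function(object) object@label)
setMethod("length", "EpochSet", function(x) length(x@start))
setMethod("duration", "EpochSet", function(object)
  sum(object@end - object@start))
setMethod("epochsWithLabel", "EpochSet", function(object, label) {
  i <- object@label %in% label
  epochSet(object@start[i], object@end[i], object@label[i])
})

#' @export
setMethod("as.data.frame", "EpochSet", function(x, ...)
  data.frame(label = x@label, start = x@start, end = x@end))

setMethod("show", "Lfp", function(object) {
  cat(sprintf("Lfp: %d samples at %g Hz, t = [%.3f, %.3f] s\n",
              length(object@samples), object@rate, object@t0,
              object@t0 + duration(object)))
})
setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s': %d spikes", object@unitId,
              length(object@times)))
  if (length(object@times) > 1L)
    cat(sprintf(" in [%.3f, %.3f] s", min(object@times), max(object@times)))
  cat("\n")
})
setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d epochs, %.1f s total\n", length(object),
              duration(object)))
  for (lab in unique(object@label)) {
    i <- object@label == lab
    cat(sprintf("  %s: %d epochs, %.1f s\n", lab, sum(i),
                sum(object@end[i] - object@start[i])))
  }
})
setMethod("show", "EventSet", function(object) {
  cat(sprintf("EventSet '%s': %d events", object@kind, length(object)))
  if (length(object@windowStart))
    cat(sprintf(", windows totalling %.2f s",
                sum(object@windowEnd - object@windowStart)))
  cat("\n")
})
setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  for (sn in slotNames(object))
    cat(sprintf("  %-24s %s\n", sn,
                paste(format(slot(object, sn)), collapse = "-")))
})
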