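#' Polar plot of a phase histogram
#'
#' Draws a circular histogram of phases on the trough-origin convention
#' (0 deg = trough at the right, angles counter-clockwise), with the mean
#' vector drawn from the center.
#'
#' @param phases phases in degrees.
#' @param binwidth histogram bin width, degrees.
#' @param ... further arguments passed to \code{plot}.
#' @return Invisibly, the histogram data.frame.
#' @export
plotPhasePolar <- function(phases, binwidth = 20, ...) {
  h <- phaseHistogram(phases, binwidth = binwidth, smoothSd = 0)
  r <- h$density / max(h$density)
  a <- degToRad(h$phase)
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", ...)
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                    fg = "grey70")
  graphics::segments(0, 0, r * cos(a), r * sin(a), lwd = 3, col = "grey30")
  cs <- circularStats(phases)
  mu <- degToRad(cs$meanPhase)
  graphics::arrows(0, 0, cs$r * cos(mu), cs$r * sin(mu), col = "red",
                   lwd = 2, length = 0.08)
  graphics::text(c(1.08, 0, -1.08, 0), c(0, 1.08, 0, -1.08),
                 c("0°", "90°", "180°", "270°"),
                 cex = 0.8)
  invisible(h)
}

#' Thin Morlet time-frequency plot of an LFP
#'
#' Convenience wrapper computing the magnitude of a Morlet wavelet
#' transform over a frequency grid and drawing it with \code{image}.
#' Intended for quick visual checks, not quantitative analysis.
#'
#' @param x an \linkS4class{Lfp}.
#' @param freqs frequency grid, Hz.
#' @param nCycles wavelet width in cycles (default 6).
#' @param plot draw the image (default TRUE).
#' @return Invisibly, a list with \code{time}, \code{freq} and \code{power}
#'   (magnitude matrix, frequencies in rows).
#' @export
plotSpectrogram <- function(x, freqs = seq(2, 100, by = 2), nCycles = 6,
                            plot = TRUE) {
  stopifnot(is(x, "Lfp"))
  s <- samples(x) - mean(samples(x))
  rate <- samplingRate(x)
  n <- length(s)
  S <- stats::fft(s)
  fftFreq <- (seq_len(n) - 1) / n * rate
  fftFreq[fftFreq > rate / 2] <- fftFreq[fftFreq > rate / 2] - rate
  power <- matrix(0, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    f0 <- freqs[i]
    sigmaF <- f0 / nCycles
    kernel <- exp(-(fftFreq - f0)^2 / (2 * sigmaF^2))
    power[i, ] <- Mod(stats::fft(S * kernel, inverse = TRUE) / n)
  }
  tms <- sampleTimes(x)
  if (plot)
    graphics::image(tms, freqs, t(power), xlab = "time (s)",
                    ylab = "frequency (Hz)", useRaster = TRUE)
  invisible(list(time = tms, freq = freqs, power = power))
}
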