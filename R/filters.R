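# Zero-phase band-pass filtering and envelope extraction (internal).

# forward-backward Butterworth band-pass; zero-phase by construction.
# Narrow low-frequency bands at high sampling rates make the IIR
# coefficients numerically unstable, so the trace is decimated (moving
# average + subsample) to about 20x the band's upper edge before
# filtering, and the filtered signal is splined back onto the original
# grid.
bandpassFilter <- function(x, rate, band, order = 4) {
  nyq <- rate / 2
  if (band[2L] >= nyq)
    stop(sprintf("band upper edge %g Hz exceeds Nyquist (%g Hz)",
                 band[2L], nyq))
  # odd-symmetric reflection padding suppresses start/end transients so
  # that detections are invariant to constant offsets and trace edges;
  # the pad must outlast the filter ring-down (~10 / bandwidth)
  n <- length(x)
  k <- min(n - 1L,
           max(16L, round(rate * max(3 / band[1L],
                                     10 / (band[2L] - band[1L])))))
  xp <- c(2 * x[1L] - x[(k + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - k)])
  y <- bandpassCore(xp, rate, band, order)
  y[(k + 1L):(k + n)]
}

bandpassCore <- function(x, rate, band, order) {
  nyq <- rate / 2
  q <- max(1L, floor(rate / (20 * band[2L])))
  if (q > 1L) {
    sm <- movingAverage(x, q)
    idx <- seq(1L, length(x), by = q)
    xd <- sm[idx]
    rd <- rate / q
    bf <- signal::butter(order, band / (rd / 2), type = "pass")
    yd <- as.numeric(signal::filtfilt(bf, xd))
    if (length(idx) < 4L) return(rep(mean(yd), length(x)))
    stats::spline(x = idx, y = yd, xout = seq_along(x),
                  method = "fmm")$y
  } else {
    bf <- signal::butter(order, band / nyq, type = "pass")
    as.numeric(signal::filtfilt(bf, x))
  }
}

# analytic-signal magnitude via FFT (one-sided spectrum doubling)
hilbertEnvelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# indices of local minima with a minimum separation (in samples);
# on ties / closer pairs the deeper minimum wins
localMinima <- function(x, minSep) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(x[2L:(n - 1L)] <= x[1L:(n - 2L)] &
                x[2L:(n - 1L)] < x[3L:n]) + 1L
  if (!length(cand)) return(integer())
  keep <- integer()
  for (i in cand) {
    if (!length(keep) || i - keep[length(keep)] >= minSep)
      keep <- c(keep, i)
    else if (x[i] < x[keep[length(keep)]])
      keep[length(keep)] <- i
  }
  keep
}

# trough times of a band-passed trace; minimum separation is half the
# period of the band's upper edge
bandTroughs <- function(x, rate, band, t0 = 0, order = 4) {
  filt <- bandpassFilter(x, rate, band, order)
  minSep <- max(2L, floor(rate / band[2L] / 2))
  idx <- localMinima(filt, minSep)
  list(times = t0 + (idx - 1L) / rate, index = idx, filtered = filt)
}
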