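# Shared numeric conventions.

# Interquartile range, MATLAB-style midpoint quantiles (R type 5).
# This convention reproduces the published group IQRs from the per-cell
# medians for both odd and even group sizes; fixed package-wide.
iqrMidpoint <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  q <- stats::quantile(x, c(0.25, 0.75), type = 5, names = FALSE)
  q[2L] - q[1L]
}

medianIqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(median = NA_real_, iqr = NA_real_))
  c(median = stats::median(x), iqr = iqrMidpoint(x))
}

meanSd <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0)
}

# Round half away from zero (presentation only; tables print 1 decimal).
roundHalfAway <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

degToRad <- function(d) d * pi / 180
radToDeg <- function(r) r * 180 / pi

wrapDeg <- function(d) ((d %% 360) + 360) %% 360

# absolute circular distance between two angles in degrees, in [0, 180]
circDistDeg <- function(a, b) {
  d <- abs(wrapDeg(a) - wrapDeg(b))
  pmin(d, 360 - d)
}

# von Mises sampler (Best & Fisher 1979); mu degrees, returns degrees
rVonMises <- function(n, mu, kappa) {
  if (n == 0L) return(numeric())
  if (kappa < 1e-8) return(stats::runif(n, 0, 360))
  muRad <- degToRad(mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- muRad + sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrapDeg(radToDeg(out))
}

# centered moving average with edge truncation
movingAverage <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
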