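#' Classify a cell as an orchid cell
#'
#' Applies the four firing-pattern criteria that define orchid cells:
#' \enumerate{
#'   \item high burst incidence during both locomotion and immobility
#'     (mean > 3.0 Hz in LM and IM);
#'   \item long-duration bursts during locomotion and immobility
#'     (median > 50 ms in LM and IM);
#'   \item an increase in mean firing rate from immobility to locomotion;
#'   \item strong theta coupling around the CA1d theta peak: mean vector
#'     length > 0.2, Rayleigh p < 0.05 and preferred phase inside
#'     \code{cfg@peakPhaseWindow} (default 90-270 deg; the window is wide
#'     because published orchid phases span 130-264 deg).
#' }
#'
#' @param metrics a one-row data.frame in the layout of
#'   \code{\link{referenceCellMetrics}} (columns \code{burst_inc_lm_mean},
#'   \code{burst_inc_im_mean}, \code{burst_dur_median_lm},
#'   \code{burst_dur_median_im}, \code{rate_lm_mean}, \code{rate_im_mean},
#'   \code{theta_r}, \code{theta_p}, \code{theta_phase_deg}).
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return A list with \code{verdict} (\code{TRUE}, \code{FALSE} or
#'   \code{NA} when a required field is unavailable) and \code{criteria}, a
#'   named logical vector for the four criteria.
#' @export
classifyOrchid <- function(metrics, cfg = analysisConfig()) {
  stopifnot(is.data.frame(metrics), nrow(metrics) == 1L)
  g <- function(col) if (col %in% names(metrics)) metrics[[col]][1L] else NA
  crit <- c(
    burstIncidence = g("burst_inc_lm_mean") > 3.0 &
                     g("burst_inc_im_mean") > 3.0,
    burstDuration = g("burst_dur_median_lm") > 50 &
                    g("burst_dur_median_im") > 50,
    rateIncrease = g("rate_lm_mean") > g("rate_im_mean"),
    thetaPeakCoupling = g("theta_r") > 0.2 & g("theta_p") < 0.05 &
      g("theta_phase_deg") >= cfg@peakPhaseWindow[1L] &
      g("theta_phase_deg") <= cfg@peakPhaseWindow[2L])
  verdict <- if (anyNA(crit)) {
    # a criterion that is FALSE on the available data decides the verdict;
    # missing data alone never yields FALSE
    if (isTRUE(any(!crit, na.rm = TRUE))) FALSE else NA
  } else all(crit)
  list(verdict = verdict, criteria = crit)
}

#' Group-level summary of a per-cell metric
#'
#' Aggregates one column over cells, excluding unavailable entries:
#' median with midpoint-quantile IQR (the package-wide convention for
#' burst timing metrics) or mean with n-1 s.d.
#'
#' @param rows a data.frame of per-cell metrics.
#' @param field column name.
#' @param type \code{"median_iqr"} or \code{"mean_sd"}.
#' @return A list with \code{center}, \code{spread} and \code{n} (cells
#'   with data).
#' @export
groupAggregate <- function(rows, field, type = c("median_iqr", "mean_sd")) {
  type <- match.arg(type)
  x <- rows[[field]]
  if (is.null(x)) stop("unknown field: ", field)
  x <- x[!is.na(x)]
  if (!length(x)) stop("no available values for field ", field)
  if (type == "median_iqr") {
    mi <- medianIqr(x)
    list(center = mi[["median"]], spread = mi[["iqr"]], n = length(x))
  } else {
    ms <- meanSd(x)
    list(center = ms[["mean"]], spread = ms[["sd"]], n = length(x))
  }
}

#' Exact two-sided sign test
#'
#' Drops ties and unavailable pairs, then computes
#' \code{p = 2 P(X <= min(k+, k-))} under Binomial(n, 1/2), capped at 1.
#'
#' @param a,b paired numeric vectors.
#' @return A list with \code{nPositive}, \code{nNegative}, \code{n} and
#'   \code{p}.
#' @examples
#' signTest(rep(1, 16), rep(0, 16))$p  # 2 * 0.5^16
#' @export
signTest <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L) stop("sign test undefined: all pairs tied or unavailable")
  kPos <- sum(d > 0); kNeg <- n - kPos
  p <- min(1, 2 * stats::pbinom(min(kPos, kNeg), n, 0.5))
  list(nPositive = kPos, nNegative = kNeg, n = n, p = p)
}

#' Paired t test on complete pairs
#'
#' @param a,b paired numeric vectors; incomplete pairs are dropped.
#' @return A list with \code{t}, \code{df}, \code{p}, \code{meanA},
#'   \code{meanB} and \code{n}.
#' @export
pairedT <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) stop("paired t test needs at least 2 complete pairs")
  if (stats::sd(a - b) == 0)
    stop("zero variance of paired differences")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanA = mean(a), meanB = mean(b), n = length(a))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Standard two-sample KS with the asymptotic p-value.
#'
#' @param a,b numeric samples (>= 2 each).
#' @return A list with \code{D} and \code{p}.
#' @export
ksTwoSample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples need at least 2 values")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Permutation test for a difference between group circular means
#'
#' The statistic is the absolute circular distance (degrees, in [0, 180])
#' between the two group circular means. Group labels are permuted
#' \code{cfg@nPermutations} times (10000) and the p-value is
#' \code{(b + 1) / (m + 1)} where \code{b} counts permutations with a
#' statistic at least as large as observed.
#'
#' @param phasesA,phasesB phases in degrees, one group each (>= 2).
#' @param cfg an \linkS4class{AnalysisConfig}; \code{cfg@rngSeed} seeds the
#'   permutation.
#' @return A list with \code{observedDiff} (degrees), \code{p},
#'   \code{meanA}, \code{meanB}.
#' @export
circularGroupCompare <- function(phasesA, phasesB, cfg = analysisConfig()) {
  nA <- length(phasesA); nB <- length(phasesB)
  if (nA < 2L || nB < 2L) stop("both groups need at least 2 phases")
  mA <- circularMean(phasesA); mB <- circularMean(phasesB)
  obs <- circDistDeg(mA, mB)
  pool <- c(phasesA, phasesB)
  set.seed(cfg@rngSeed)
  m <- as.integer(cfg@nPermutations)
  b <- 0L
  for (i in seq_len(m)) {
    idx <- sample.int(nA + nB, nA)
    d <- circDistDeg(circularMean(pool[idx]), circularMean(pool[-idx]))
    if (d >= obs) b <- b + 1L
  }
  list(observedDiff = obs, p = (b + 1) / (m + 1), meanA = mA, meanB = mB)
}

#' Optical fractionator estimate of a total cell count
#'
#' Scales the number of counted objects by the inverse sampling fractions:
#' \code{total = counted / (ssf * asf * tsf)} where \code{ssf} is the
#' section sampling fraction (e.g. 1/3 for every third section),
#' \code{asf} the area sampling fraction (counting frame area / grid cell
#' area) and \code{tsf} the thickness sampling fraction (probe depth /
#' section thickness).
#'
#' @param counted number of counted objects (>= 0).
#' @param sectionFraction,areaFraction,thicknessFraction sampling fractions
#'   in (0, 1].
#' @return The estimated total.
#' @examples
#' # every 3rd section, 120x80 frame on a 240x160 grid, 5 of 50 um depth
#' opticalFractionator(422, 1/3, (120 * 80) / (240 * 160), 5 / 50)
#' @export
opticalFractionator <- function(counted, sectionFraction, areaFraction,
                                thicknessFraction) {
  fr <- c(sectionFraction, areaFraction, thicknessFraction)
  if (any(fr <= 0) || any(fr > 1))
    stop("sampling fractions must lie in (0, 1]")
  if (counted < 0) stop("counted must be >= 0")
  counted / prod(fr)
}

#' Gundersen-Jensen coefficient of error (smoothness class m = 1)
#'
#' The standard CE estimator for systematic sampling of section counts
#' \eqn{Q_i}: with A = sum Q_i^2, B = sum Q_i Q_{i+1}, C = sum Q_i Q_{i+2}
#' and the nugget taken as the total count, the variance of the systematic
#' sample is (3(A - sum Q) - 4B + C) / 240 and
#' CE = sqrt(sum Q + Var) / sum Q.
#'
#' @param sectionCounts counts per sampled section, in section order.
#' @return The coefficient of error.
#' @export
gundersenCE <- function(sectionCounts) {
  q <- as.numeric(sectionCounts)
  if (length(q) < 3L) stop("need at least 3 section counts")
  total <- sum(q)
  if (total <= 0) stop("total count must be positive")
  A <- sum(q^2)
  B <- sum(q[-length(q)] * q[-1L])
  C <- sum(q[seq_len(length(q) - 2L)] * q[-(1:2)])
  varSys <- (3 * (A - total) - 4 * B + C) / 240
  sqrt(total + max(varSys, 0)) / total
}
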