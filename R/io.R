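#' Write a session directory
#'
#' Writes the tab-separated session layout: \code{lfp.tsv} (metadata lines
#' \code{# rate:} and \code{# t0:} followed by one voltage per line),
#' \code{spikes.tsv} (columns \code{unit}, \code{time}),
#' \code{epochs.tsv} (\code{label}, \code{start}, \code{end}) and, when
#' behavior channels are present, \code{behavior.tsv} (\code{time},
#' \code{counter}, \code{whisk}). Ground-truth event sets (from the
#' synthetic generator) are written as \code{truth_<kind>.tsv}.
#'
#' @param dir output directory (created if missing).
#' @param lfp an \linkS4class{Lfp}.
#' @param trains a list of \linkS4class{SpikeTrain}s (or a single train).
#' @param epochs optional \linkS4class{EpochSet}.
#' @param behavior optional data.frame with \code{time}, \code{counter},
#'   \code{whisk}.
#' @param truth optional named list of \linkS4class{EventSet}s.
#' @param digits decimal digits for times (default 6, microsecond
#'   precision).
#' @return \code{dir}, invisibly.
#' @export
writeSession <- function(dir, lfp, trains, epochs = NULL, behavior = NULL,
                         truth = NULL, digits = 6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is(trains, "SpikeTrain")) trains <- list(trains)
  con <- file.path(dir, "lfp.tsv")
  writeLines(c(sprintf("# rate: %.10g", samplingRate(lfp)),
               sprintf("# t0: %.10g", startTime(lfp)),
               formatC(samples(lfp), format = "g", digits = 9)), con)
  spk <- do.call(rbind, lapply(trains, function(tr)
    data.frame(unit = unitId(tr),
               time = formatC(spikeTimes(tr), format = "f",
                              digits = digits))))
  if (is.null(spk)) spk <- data.frame(unit = character(), time = character())
  utils::write.table(spk, file.path(dir, "spikes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(epochs))
    utils::write.table(
      data.frame(label = epochs@label,
                 start = formatC(epochs@start, format = "f", digits = digits),
                 end = formatC(epochs@end, format = "f", digits = digits)),
      file.path(dir, "epochs.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  if (!is.null(behavior))
    utils::write.table(behavior, file.path(dir, "behavior.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(truth))
    for (nm in names(truth)) {
      ev <- truth[[nm]]
      df <- eventWindows(ev)
      utils::write.table(df, file.path(dir, sprintf("truth_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  invisible(dir)
}

#' Read a session directory
#'
#' Reads the layout written by \code{\link{writeSession}}. Malformed rows
#' raise an error naming the file and line; non-monotonic spike times raise
#' an error naming the unit. Spike times outside the LFP span are clipped,
#' and the number clipped is reported via a message and the
#' \code{nClipped} attribute of each train.
#'
#' @param dir session directory.
#' @param cfg an \linkS4class{AnalysisConfig}.
#' @return A list with \code{lfp}, \code{trains} (named list of
#'   \linkS4class{SpikeTrain}s), \code{epochs} (or \code{NULL}) and
#'   \code{behavior} (or \code{NULL}).
#' @export
readSession <- function(dir, cfg = analysisConfig()) {
  lfpPath <- file.path(dir, "lfp.tsv")
  if (!file.exists(lfpPath)) stop("missing lfp.tsv in ", dir)
  lines <- readLines(lfpPath)
  meta <- grep("^#", lines, value = TRUE)
  rate <- as.numeric(sub(".*rate:\\s*", "", meta[grepl("rate:", meta)]))
  t0 <- as.numeric(sub(".*t0:\\s*", "", meta[grepl("t0:", meta)]))
  if (!length(rate) || is.na(rate) || rate <= 0)
    stop("lfp.tsv: missing or invalid '# rate:' header")
  if (!length(t0) || is.na(t0)) t0 <- 0
  body <- lines[!grepl("^#", lines)]
  vals <- suppressWarnings(as.numeric(body))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L] + sum(grepl("^#", lines))
    stop(sprintf("lfp.tsv: malformed value at line %d", bad))
  }
  x <- lfp(vals, rate = rate, t0 = t0)
  span <- c(t0, t0 + duration(x))

  spkPath <- file.path(dir, "spikes.tsv")
  trains <- list()
  if (file.exists(spkPath)) {
    tab <- readDelimChecked(spkPath, c("unit", "time"))
    tab$time <- parseNumericColumn(tab$time, spkPath, "time")
    for (u in unique(tab$unit)) {
      tt <- tab$time[tab$unit == u]
      if (length(tt) > 1L && any(diff(tt) <= 0))
        stop(sprintf("spikes.tsv: non-monotonic spike times for unit '%s'",
                     u))
      inSpan <- tt >= span[1L] & tt <= span[2L]
      nClipped <- sum(!inSpan)
      if (nClipped > 0L)
        message(sprintf("unit '%s': %d spike(s) outside the LFP span clipped",
                        u, nClipped))
      tr <- spikeTrain(tt[inSpan], u)
      attr(tr, "nClipped") <- nClipped
      trains[[u]] <- tr
    }
  }

  epochs <- NULL
  epPath <- file.path(dir, "epochs.tsv")
  if (file.exists(epPath)) {
    tab <- readDelimChecked(epPath, c("label", "start", "end"))
    epochs <- epochSet(parseNumericColumn(tab$start, epPath, "start"),
                       parseNumericColumn(tab$end, epPath, "end"),
                       tab$label)
  }

  behavior <- NULL
  bePath <- file.path(dir, "behavior.tsv")
  if (file.exists(bePath))
    behavior <- utils::read.delim(bePath)

  list(lfp = x, trains = trains, epochs = epochs, behavior = behavior)
}

readDelimChecked <- function(path, cols) {
  tab <- tryCatch(utils::read.delim(path, colClasses = "character"),
                  error = function(e)
                    stop(sprintf("%s: %s", basename(path),
                                 conditionMessage(e))))
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", basename(path),
                 paste(miss, collapse = ", ")))
  nf <- utils::count.fields(path, sep = "\t")
  if (any(nf != nf[1L]))
    stop(sprintf("%s: malformed row at line %d", basename(path),
                 which(nf != nf[1L])[1L]))
  tab
}

parseNumericColumn <- function(x, path, col) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v))
    stop(sprintf("%s: malformed %s at line %d", basename(path), col,
                 which(is.na(v))[1L] + 1L))
  v
}

#' Reference per-cell firing-pattern metrics
#'
#' Loads the packaged table of published summary metrics for 18 medial
#' septal neurons recorded in awake head-fixed mice: 8 identified orchid
#' cells (juxtacellularly labeled, entorhinal-projecting), 8 putative
#' orchid cells and 2 identified septo-hippocampal cells. Columns cover
#' per-state firing rate (mean, s.d.), burst incidence (mean, s.d.),
#' median and IQR of burst duration and interburst interval, intraburst
#' frequency (mean, s.d.), LM-vs-IM Kolmogorov-Smirnov p-values, theta and
#' mid-gamma coupling (preferred phase, mean vector length, Rayleigh p,
#' spike count), spikes per theta cycle and SWR modulation (count, rates,
#' p). Unavailable entries are \code{NA}; p-values censored at the printed
#' bound are stored as that bound (1e-4).
#'
#' @return A data.frame with 18 rows and a \code{group} column
#'   (\code{identified_orchid}, \code{putative_orchid},
#'   \code{septohippocampal}).
#' @examples
#' m <- referenceCellMetrics()
#' subset(m, group == "identified_orchid")$cell
#' @export
referenceCellMetrics <- function() {
  path <- system.file("extdata", "reference_cells.tsv",
                      package = "septorhythm", mustWork = TRUE)
  tab <- utils::read.delim(path, na.strings = "u",
                           check.names = FALSE)
  # integrity check against transcription anchors
  if (nrow(tab) != 18L)
    stop("reference_cells.tsv corrupted: expected 18 rows")
  anchor <- tab[tab$cell == "TV58g", ]
  if (nrow(anchor) != 1L || abs(anchor$rate_lm_mean - 48.4) > 1e-9 ||
      abs(anchor$theta_phase_deg - 159) > 1e-9 ||
      sum(tab$group == "identified_orchid") != 8L ||
      sum(tab$group == "putative_orchid") != 8L ||
      sum(tab$group == "septohippocampal") != 2L)
    stop("reference_cells.tsv failed its integrity check")
  tab
}
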