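# Real-valued interval algebra on matrices with columns start, end.
# All helpers expect and return normalized (sorted, disjoint) sets.

asIntervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  cbind(start = as.numeric(start), end = as.numeric(end))
}

# sort and merge overlapping / touching intervals
normalizeIntervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[iv[, 2L] > iv[, 1L], , drop = FALSE]
  if (nrow(iv) <= 1L) return(iv)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    k <- nrow(out)
    if (iv[i, 1L] <= out[k, 2L] + 1e-12)
      out[k, 2L] <- max(out[k, 2L], iv[i, 2L])
    else out <- rbind(out, iv[i, , drop = FALSE])
  }
  out
}

intervalIntersect <- function(a, b) {
  a <- normalizeIntervals(a); b <- normalizeIntervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(asIntervals(numeric(), numeric()))
  res <- list()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1L], b[, 1L]); e <- pmin(a[i, 2L], b[, 2L])
    keep <- e > s
    if (any(keep)) res[[length(res) + 1L]] <- cbind(s[keep], e[keep])
  }
  if (!length(res)) return(asIntervals(numeric(), numeric()))
  m <- do.call(rbind, res)
  normalizeIntervals(asIntervals(m[, 1L], m[, 2L]))
}

# a \ b
intervalSetdiff <- function(a, b) {
  a <- normalizeIntervals(a); b <- normalizeIntervals(b)
  if (nrow(a) == 0L) return(a)
  if (nrow(b) == 0L) return(a)
  res <- list()
  for (i in seq_len(nrow(a))) {
    cur <- a[i, 1L]; aEnd <- a[i, 2L]
    ov <- b[b[, 2L] > a[i, 1L] & b[, 1L] < aEnd, , drop = FALSE]
    if (nrow(ov)) {
      for (j in seq_len(nrow(ov))) {
        if (ov[j, 1L] > cur)
          res[[length(res) + 1L]] <- c(cur, min(ov[j, 1L], aEnd))
        cur <- max(cur, ov[j, 2L])
        if (cur >= aEnd) break
      }
    }
    if (cur < aEnd) res[[length(res) + 1L]] <- c(cur, aEnd)
  }
  if (!length(res)) return(asIntervals(numeric(), numeric()))
  m <- do.call(rbind, res)
  normalizeIntervals(asIntervals(m[, 1L], m[, 2L]))
}

intervalTotal <- function(iv) if (nrow(iv) == 0L) 0 else sum(iv[, 2L] - iv[, 1L])

# Jaccard overlap of two interval sets
intervalJaccard <- function(a, b) {
  inter <- intervalTotal(intervalIntersect(a, b))
  uni <- intervalTotal(normalizeIntervals(rbind(a, b)))
  if (uni == 0) return(NA_real_)
  inter / uni
}

epochIntervals <- function(epochs, label = NULL) {
  if (!is.null(label)) epochs <- epochsWithLabel(epochs, label)
  asIntervals(epochs@start, epochs@end)
}

pointsInIntervals <- function(x, iv) {
  if (nrow(iv) == 0L || length(x) == 0L)
    return(logical(length(x)))
  inside <- logical(length(x))
  for (i in seq_len(nrow(iv)))
    inside <- inside | (x >= iv[i, 1L] & x <= iv[i, 2L])
  inside
}
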