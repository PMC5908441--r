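# Shared synthetic sessions, built once per test run.

.sessionCache <- new.env(parent = emptyenv())

cachedSession <- function(key, builder) {
  if (is.null(.sessionCache[[key]])) .sessionCache[[key]] <- builder()
  .sessionCache[[key]]
}

# default-condition session with behavior channels
defaultSession <- function() {
  cachedSession("default", function()
    generateSession(sessionSpec(duration = 120, rngSeed = 42)))
}

# locomotion/immobility-only schedule (for theta-epoch recovery)
lmImSession <- function() {
  cachedSession("lmim", function() {
    sch <- epochSet(c(0, 40, 80), c(40, 80, 120), c("LM", "IM", "LM"))
    generateLfp(sessionSpec(duration = 120, schedule = sch, rngSeed = 11))
  })
}

# brute-force burst scanner: walks the train spike by spike
oracleBursts <- function(times, isiMax = 0.040, minSpikes = 4) {
  res <- list()
  i <- 1L
  n <- length(times)
  while (i <= n) {
    j <- i
    while (j < n && times[j + 1L] - times[j] < isiMax) j <- j + 1L
    if (j - i + 1L >= minSpikes)
      res[[length(res) + 1L]] <- c(start = times[i], end = times[j],
                                   n = j - i + 1L)
    i <- j + 1L
  }
  if (!length(res))
    return(data.frame(start = numeric(), end = numeric(), n = numeric()))
  as.data.frame(do.call(rbind, res))
}

randomTrain <- function(n, span = 3) {
  sort(runif(n, 0, span))
}
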