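## Internal event detection on long, uniformly sampled traces.
##
## Detection runs on a decimated (~50 Hz) and additionally smoothed copy of
## the trace so that noise-scale local maxima disappear; peak locations are
## then refined on the full-resolution smoothed trace. Prominence is the
## usual topographic definition: peak height minus the higher of the lowest
## points separating the peak from higher terrain on either side.

.movingAverage <- function(x, win) {
  # centered moving average with shrinking (truncated) windows at the edges
  n <- length(x)
  win <- as.integer(win)
  if (win <= 1L) return(x)
  if (win > n) stop("smoothing window longer than the trace")
  left <- (win - 1L) %/% 2L
  right <- win - 1L - left
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

.localMaxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

.prominence <- function(x, i) {
  v <- x[i]
  leftHigher <- which(x[seq_len(i - 1L)] > v)
  lo <- if (length(leftHigher)) max(leftHigher) else 1L
  minLeft <- min(x[lo:i])
  rightHigher <- which(x[(i + 1L):length(x)] > v)
  hi <- if (length(rightHigher)) i + min(rightHigher) else length(x)
  minRight <- min(x[i:hi])
  v - max(minLeft, minRight)
}

## Returns a data.frame(index, time, prominence) of peaks on the detection
## grid, ordered by time, honoring minimum prominence and separation.
.findPeaks <- function(x, fs, minProminence, minIntervalS,
                       detectRate = 50) {
  step <- max(1L, floor(fs / detectRate))
  xi <- x[seq(1L, length(x), by = step)]
  fsD <- fs / step
  # extra smoothing at the detection scale (1 s) to kill noise maxima
  xi <- .movingAverage(xi, max(1L, as.integer(round(fsD))))
  cand <- .localMaxima(xi)
  if (!length(cand)) return(data.frame(index = integer(0), time = numeric(0),
                                       prominence = numeric(0)))
  prom <- vapply(cand, function(i) .prominence(xi, i), numeric(1))
  keepMask <- prom >= minProminence
  cand <- cand[keepMask]; prom <- prom[keepMask]
  if (!length(cand)) return(data.frame(index = integer(0), time = numeric(0),
                                       prominence = numeric(0)))
  # enforce separation, keeping higher peaks first
  ord <- order(xi[cand], decreasing = TRUE)
  keep <- logical(length(cand))
  tCand <- (cand - 1L) / fsD
  for (j in ord) {
    if (!any(keep & abs(tCand - tCand[j]) < minIntervalS)) keep[j] <- TRUE
  }
  cand <- cand[keep]; prom <- prom[keep]; tCand <- tCand[keep]
  ord <- order(tCand)
  cand <- cand[ord]; prom <- prom[ord]; tCand <- tCand[ord]
  # refine each peak on the full-resolution trace within +/- minInterval/2
  half <- as.integer(round(minIntervalS / 2 * fs))
  idxFull <- vapply(tCand, function(tc) {
    c0 <- as.integer(round(tc * fs)) + 1L
    lo <- max(1L, c0 - half); hi <- min(length(x), c0 + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  data.frame(index = idxFull, time = (idxFull - 1L) / fs, prominence = prom)
}
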