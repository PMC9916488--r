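## Empirical mode decomposition and analytic-signal utilities.
##
## No EMD implementation ships with the imported packages, so the sifting
## algorithm is authored here: cubic-spline upper/lower envelopes through the
## local extrema (mirror-extended at the boundaries), iterated until the
## normalized squared change between consecutive sifts falls below a
## threshold (default 0.2) or a sift cap is reached. IMFs are subtracted
## successively, so IMFs + residual reconstruct the input to machine
## precision by construction.

.maximaIdx <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

.minimaIdx <- function(x) .maximaIdx(-x)

## Cubic-spline envelope through (idx, x[idx]) with mirror extension of up to
## two extrema beyond each boundary, evaluated on 1..n.
.splineEnvelope <- function(x, idx, n) {
  px <- as.numeric(idx)
  py <- x[idx]
  k <- length(idx)
  nl <- min(2L, k)
  left <- 2 - px[seq_len(nl)]            # mirrored about sample 1
  right <- 2 * n - px[seq(k, by = -1L, length.out = nl)]  # about sample n
  xs <- c(rev(left), px, rev(right))
  ys <- c(py[seq_len(nl)][seq(nl, 1L)], py,
          py[seq(k, by = -1L, length.out = nl)][seq(nl, 1L)])
  ord <- order(xs)
  xs <- xs[ord]; ys <- ys[ord]
  keep <- !duplicated(xs)
  stats::spline(xs[keep], ys[keep], xout = seq_len(n), method = "fmm")$y
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by standard
#' sifting: the mean of the spline envelopes through the maxima and minima is
#' subtracted until the normalized squared change between sifts drops below
#' `sdThresh` or `maxSifts` is reached; extraction stops when the remainder
#' has fewer than two maxima or minima, or after `maxImfs` IMFs.
#'
#' @param x numeric signal (length >= 16).
#' @param maxImfs maximum number of IMFs (default 10).
#' @param sdThresh sift stopping threshold on the normalized squared change
#'   (default 0.2).
#' @param maxSifts cap on sifting iterations per IMF (default 10).
#' @return A list with `imfs` (samples x IMFs matrix, possibly 0 columns) and
#'   `residual`; `rowSums(imfs) + residual` equals `x`.
#' @examples
#' x <- sin(2 * pi * 5 * seq(0, 1, length.out = 200))
#' dec <- emd(x)
#' ncol(dec$imfs)
#' @export
emd <- function(x, maxImfs = 10, sdThresh = 0.2, maxSifts = 10) {
  if (length(x) < 16L) stop("signal too short for decomposition (< 16 samples)")
  n <- length(x)
  residual <- as.numeric(x)
  imfList <- list()
  for (k in seq_len(maxImfs)) {
    h <- residual
    mx <- .maximaIdx(h); mn <- .minimaIdx(h)
    if (length(mx) < 2L || length(mn) < 2L) break
    for (s in seq_len(maxSifts)) {
      upper <- .splineEnvelope(h, mx, n)
      lower <- .splineEnvelope(h, mn, n)
      m <- (upper + lower) / 2
      h1 <- h - m
      if (any(!is.finite(h1)))
        stop("sifting diverged: normalized squared change (SD < ", sdThresh,
             ") criterion could not be evaluated")
      sdv <- sum((h - h1)^2) / max(sum(h^2), .Machine$double.eps)
      h <- h1
      mx <- .maximaIdx(h); mn <- .minimaIdx(h)
      if (length(mx) < 2L || length(mn) < 2L) break
      if (sdv < sdThresh) break
    }
    imfList[[k]] <- h
    residual <- residual - h
  }
  imfs <- if (length(imfList)) do.call(cbind, imfList) else
    matrix(numeric(0), nrow = n, ncol = 0)
  list(imfs = imfs, residual = residual)
}

## Analytic signal via the frequency-domain Hilbert transform. The signal is
## reflection-padded to a 2-3-5-smooth length so the FFT stays O(n log n)
## for arbitrary window lengths; the padding is discarded afterwards.
.analyticSignal <- function(x) {
  n <- length(x)
  m <- stats::nextn(n, c(2L, 3L, 5L))
  xp <- if (m > n) c(x, rev(x)[seq_len(m - n)]) else x
  X <- fft(xp)
  h <- numeric(m)
  if (m %% 2L == 0L) {
    h[1L] <- 1; h[m / 2L + 1L] <- 1; h[2:(m / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2:((m + 1L) / 2L)] <- 2
  }
  (fft(X * h, inverse = TRUE) / m)[seq_len(n)]
}

.instFrequency <- function(phase, fs) {
  n <- length(phase)
  ph <- signal::unwrap(phase)
  d <- numeric(n)
  d[1L] <- ph[2L] - ph[1L]
  d[n] <- ph[n] - ph[n - 1L]
  if (n > 2L) d[2:(n - 1L)] <- (ph[3:n] - ph[1:(n - 2L)]) / 2
  d * fs / (2 * pi)
}

#' Hilbert-Huang spectrum of a signal
#'
#' Runs [emd()] and computes, per IMF, the instantaneous amplitude and
#' frequency from the analytic signal (frequency-domain Hilbert transform;
#' frequency is the central-difference derivative of the unwrapped phase).
#'
#' @param x numeric signal (length >= 16).
#' @param samplingRate sampling rate, Hz.
#' @param startTimeS time of the first sample (s); the spectrum's time base
#'   is `startTimeS + (0:(n-1)) / samplingRate`.
#' @inheritParams emd
#' @return A [HilbertSpectrum-class].
#' @examples
#' fs <- 2000
#' x <- sin(2 * pi * 100 * seq(0, 1 - 1 / fs, by = 1 / fs))
#' hs <- hilbertHuang(x, fs)
#' median(instFrequency(hs)[, 1])  # ~100 Hz
#' @export
hilbertHuang <- function(x, samplingRate, startTimeS = 0,
                         maxImfs = 10, sdThresh = 0.2, maxSifts = 10) {
  dec <- emd(x, maxImfs = maxImfs, sdThresh = sdThresh, maxSifts = maxSifts)
  n <- length(x)
  nImf <- ncol(dec$imfs)
  amp <- matrix(0, n, nImf)
  freq <- matrix(0, n, nImf)
  for (j in seq_len(nImf)) {
    a <- .analyticSignal(dec$imfs[, j])
    amp[, j] <- Mod(a)
    freq[, j] <- .instFrequency(Arg(a), samplingRate)
  }
  new("HilbertSpectrum",
      imfs = dec$imfs, residual = dec$residual,
      instAmplitude = amp, instFrequency = freq,
      time = startTimeS + (seq_len(n) - 1) / samplingRate,
      samplingRate = samplingRate)
}
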