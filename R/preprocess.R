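## Signal preprocessing: antialias downsampling, zero-phase Butterworth
## filtering, Hilbert envelograms and the 5 x 15000 CNN input matrix.

#' Default envelogram bands
#'
#' The four bandpass bands feeding the envelogram rows, covering
#' beta/low/high gamma (20-100 Hz), ripples (80-250 Hz), fast ripples
#' (200-600 Hz) and very fast ripples (500-900 Hz).
#'
#' @return list of `c(low, high)` pairs in Hz.
#' @export
defaultBands <- function() {
  list(c(20, 100), c(80, 250), c(200, 600), c(500, 900))
}

featureRowNames <- function(bands = defaultBands()) {
  c("raw_lowpass",
    vapply(bands, function(b) sprintf("env_%g_%g", b[1], b[2]), character(1)))
}

## Bartlett-Hanning window of length n (symmetric).
barthannWindow <- function(n) {
  x <- seq(0, 1, length.out = n) - 0.5
  0.62 - 0.48 * abs(x) + 0.38 * cos(2 * pi * x)
}

#' Antialias filter and downsample
#'
#' Low-passes the input with a zero-phase Bartlett-Hanning-windowed sinc
#' FIR filter (default cutoff 1 kHz) and resamples to the target rate.
#' Integer decimation picks exact samples; rational ratios are handled by
#' interpolation on the antialiased (band-limited) signal.  Output length
#' is `round(length(x) * targetRate / sourceRate)`.
#'
#' @param x numeric signal at `sourceRate`.
#' @param sourceRate source sampling rate in Hz.
#' @param targetRate target sampling rate in Hz (must not exceed source).
#' @param cutoff FIR cutoff frequency in Hz.
#' @param taps number of FIR taps (odd); NULL picks a length giving a
#'   narrow transition band relative to the source rate.
#' @return numeric signal at `targetRate`.
#' @export
antialiasDownsample <- function(x, sourceRate, targetRate, cutoff = 1000,
                                taps = NULL) {
  if (targetRate > sourceRate)
    stopValidation("targetRate (", targetRate,
                   ") must not exceed sourceRate (", sourceRate, ")")
  if (sourceRate == targetRate) return(x)
  if (cutoff >= sourceRate / 2)
    stopValidation("cutoff must be below the source Nyquist frequency")
  n <- length(x)
  if (is.null(taps)) taps <- 2L * floor(6 * sourceRate / cutoff / 2) + 1L
  taps <- as.integer(taps)
  if (taps %% 2 == 0) taps <- taps + 1L
  hw <- (taps - 1L) %/% 2L
  k <- seq(-hw, hw)
  fc <- cutoff / sourceRate
  h <- 2 * fc * sinc(2 * fc * k) * barthannWindow(taps)
  h <- h / sum(h)
  ## zero-phase FIR: symmetric kernel applied centred, reflective edges
  if (hw >= n) stopValidation("signal too short for the FIR length")
  xp <- c(rev(x[2:(hw + 1)]), x, rev(x[(n - hw):(n - 1)]))
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  y <- as.numeric(y[(hw + 1):(hw + n)])
  m <- round(n * targetRate / sourceRate)
  ratio <- sourceRate / targetRate
  if (abs(ratio - round(ratio)) < 1e-9) {
    y[seq(1, by = round(ratio), length.out = m)]
  } else {
    idx <- (seq_len(m) - 1) * ratio + 1
    stats::approx(seq_len(n), y, xout = idx, rule = 2)$y
  }
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Zero-phase Butterworth filter
#'
#' Forward-backward application of a 3rd-order Butterworth design (zero
#' net phase shift, effectively 6th-order magnitude).  Edges are handled
#' by odd-reflection padding long enough to absorb the filter's transient
#' at the lowest band edge; output length equals input length.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param kind "lowpass" or "bandpass".
#' @param band for bandpass, `c(low, high)` in Hz; for lowpass, the cutoff
#'   as a single number.
#' @param order Butterworth order of each pass (default 3).
#' @return filtered signal, same length as `x`.
#' @export
zeroPhaseFilter <- function(x, fs, kind = c("lowpass", "bandpass"), band,
                            order = 3) {
  kind <- match.arg(kind)
  nyq <- fs / 2
  if (kind == "lowpass") {
    if (length(band) != 1 || band <= 0 || band >= nyq)
      stopValidation("lowpass cutoff must lie in (0, fs/2)")
    flt <- signal::butter(order, band / nyq, type = "low")
    lowEdge <- band
  } else {
    if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
        band[2] >= nyq)
      stopValidation("bandpass band must satisfy 0 < low < high < fs/2")
    flt <- signal::butter(order, band / nyq, type = "pass")
    lowEdge <- band[1]
  }
  n <- length(x)
  if (n < 2) stopValidation("signal too short to filter")
  pad <- min(n - 1, max(3 * order, ceiling(3 * fs / lowEdge)))
  ## odd reflection: continuous value and slope at the edges
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(flt, c(left, x, right))
  y[(pad + 1):(pad + n)]
}

## Analytic signal via the frequency-domain Hilbert construction.
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Bandpass power envelope (envelogram)
#'
#' Bandpass-filters the signal with a zero-phase 3rd-order Butterworth
#' design, then takes the squared magnitude of the analytic signal
#' (signal + i Hilbert transform).  The result is a non-negative
#' instantaneous band-power trace of the same length.
#'
#' @param x numeric signal.
#' @param band `c(low, high)` band edges in Hz.
#' @param fs sampling rate in Hz.
#' @return non-negative numeric vector, same length as `x`.
#' @export
envelogram <- function(x, band, fs) {
  xf <- zeroPhaseFilter(x, fs, "bandpass", band)
  Mod(analyticSignal(xf))^2
}

#' Z-score a feature row
#'
#' Subtracts the mean and divides by the population standard deviation.
#' A degenerate constant row (zero variance) maps to all zeros.
#'
#' @param x non-empty numeric vector.
#' @return z-scored vector.
#' @export
zscoreRow <- function(x) {
  if (length(x) == 0) stopValidation("cannot z-score an empty vector")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s < 1e-12 * (abs(m) + 1)) return(rep(0, length(x)))
  (x - m) / s
}

#' Build the CNN input feature matrix
#'
#' Transforms a 3-s segment into the 5 x 15000 classifier input: row 1 is
#' the z-scored 900 Hz low-passed raw trace; rows 2-5 are z-scored
#' envelograms of the four default bands, in band order.
#'
#' @param segment a [SegmentRecord-class], or a numeric vector with `fs`
#'   supplied.
#' @param fs sampling rate in Hz (taken from the segment if given).
#' @param segmentSeconds expected duration in seconds.
#' @param bands list of band edge pairs (default [defaultBands()]).
#' @param lowpassCutoff cutoff for the raw row's lowpass, Hz.
#' @return numeric matrix `(1 + length(bands)) x samples` with semantic
#'   row names; every row has mean 0 and unit population standard
#'   deviation (constant rows map to zero).
#' @export
#' @examples
#' cfg <- synthConfig(seed = 7)
#' fm <- buildFeatureMatrix(genPhysiological(cfg))
#' dim(fm)  # 5 15000
buildFeatureMatrix <- function(segment, fs = NULL, segmentSeconds = 3,
                               bands = defaultBands(), lowpassCutoff = 900) {
  if (is(segment, "SegmentRecord")) {
    x <- segment@signal
    fs <- segment@samplingRate
  } else if (is.numeric(segment)) {
    if (is.null(fs)) stopValidation("fs must be supplied for a raw vector")
    x <- as.numeric(segment)
  } else stopValidation("segment must be a SegmentRecord or numeric vector")
  expected <- round(fs * segmentSeconds)
  if (length(x) != expected)
    stopValidation("segment has ", length(x), " samples; expected ",
                   expected, " (", segmentSeconds, " s at ", fs, " Hz)")
  out <- matrix(0, nrow = 1 + length(bands), ncol = length(x),
                dimnames = list(featureRowNames(bands), NULL))
  out[1, ] <- zscoreRow(zeroPhaseFilter(x, fs, "lowpass", lowpassCutoff))
  for (i in seq_along(bands))
    out[i + 1, ] <- zscoreRow(envelogram(x, bands[[i]], fs))
  out
}

## Batch feature extraction for a SegmentSet -> array (rows, samples, n).
featureTensor <- function(set, bands = defaultBands(), lowpassCutoff = 900,
                          verbose = FALSE) {
  stopifnot(is(set, "SegmentSet"))
  n <- nSegments(set)
  rows <- 1 + length(bands)
  len <- nrow(set@signals)
  out <- array(0, dim = c(rows, len, n))
  for (i in seq_len(n)) {
    out[, , i] <- buildFeatureMatrix(set@signals[, i], fs = set@samplingRate,
                                     segmentSeconds = len / set@samplingRate,
                                     bands = bands,
                                     lowpassCutoff = lowpassCutoff)
    if (verbose && i %% 200 == 0)
      message("  features: ", i, "/", n)
  }
  out
}
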