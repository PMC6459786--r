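## Synthetic iEEG generator: seeded, four segment classes.

#' Create a synthetic-generator configuration
#'
#' Defaults encode the pipeline's acquisition constants: 5 kHz sampling and
#' 3-s segments (15,000 samples).  The background is 1/f ("pink") noise;
#' transient events are scaled by `artifactSNR` relative to the background
#' standard deviation.
#'
#' @param samplingRate sampling rate in Hz.
#' @param segmentSeconds segment duration in seconds.
#' @param lineFreq power-line frequency, 50 or 60 Hz.
#' @param backgroundAmplitude background standard deviation (arbitrary
#'   microvolt-scale units; downstream z-scoring removes absolute scale).
#' @param artifactSNR event-to-background amplitude ratio for spikes,
#'   bursts and line interference.
#' @param seed integer RNG seed; NA draws from the current stream.
#' @return a validated [SynthConfig-class].
#' @export
#' @examples
#' cfg <- synthConfig(seed = 1)
#' seg <- genPhysiological(cfg)
#' length(segmentSignal(seg))  # 15000
synthConfig <- function(samplingRate = 5000, segmentSeconds = 3,
                        lineFreq = 50, backgroundAmplitude = 25,
                        artifactSNR = 2.5, seed = NA) {
  obj <- tryCatch(
    new("SynthConfig", samplingRate = samplingRate,
        segmentSeconds = segmentSeconds, lineFreq = lineFreq,
        backgroundAmplitude = backgroundAmplitude,
        artifactSNR = artifactSNR, seed = as.numeric(seed)),
    error = function(e) stopValidation(conditionMessage(e)))
  obj
}

cfgSamples <- function(cfg) as.integer(round(cfg@samplingRate * cfg@segmentSeconds))

## 1/f^alpha *amplitude* noise via spectral shaping (power falls as
## f^(-2*alpha)), unit standard deviation.  Frequencies below 1 Hz are
## flattened, mimicking AC coupling.
pinkNoise <- function(n, fs, alpha = 1) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)          # two-sided frequency axis
  shape <- 1 / pmax(f, 1)^alpha
  shape[1] <- 0                 # remove DC
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x <- x / s
  x
}

## Background common to all classes: pink noise with slow amplitude
## modulation (iEEG is not stationary over 3 s) plus a small white
## sensor-noise floor, scaled to cfg@backgroundAmplitude.
synthBackground <- function(cfg) {
  n <- cfgSamples(cfg)
  t <- seq_len(n) / cfg@samplingRate
  am <- 1 + 0.3 * sin(2 * pi * stats::runif(1, 0.1, 0.5) * t +
                        stats::runif(1, 0, 2 * pi))
  alpha <- stats::runif(1, 0.8, 1.4)      # spectral slope varies by site
  floorSd <- if (stats::runif(1) < 0.3)
    stats::runif(1, 0.1, 0.25) else 0.05  # occasional noisier contacts
  x <- pinkNoise(n, cfg@samplingRate, alpha) * am + floorSd * stats::rnorm(n)
  cfg@backgroundAmplitude * x / stats::sd(x)
}

## Blunt biphasic transient without an HFO: benign sharp activity that
## physiological iEEG may legitimately contain.  Keeps the physiological
## and pathological classes from being trivially separable by amplitude.
addBenignTransient <- function(x, fs, sdbg, centre = NULL) {
  n <- length(x)
  width <- stats::runif(1, 0.08, 0.15)
  sigma <- width / 4
  if (is.null(centre)) centre <- stats::runif(1, 0.2, n / fs - 0.2)
  t <- (seq_len(n) / fs) - centre
  wave <- exp(-t^2 / (2 * sigma^2)) -
    0.5 * exp(-(t - 1.5 * sigma)^2 / (2 * (2 * sigma)^2))
  x + stats::runif(1, 0.8, 1.8) * sdbg * wave / max(abs(wave))
}

## Seed resolution for the public generators: an explicit seed wins,
## NA falls back to cfg@seed, NULL (used internally by genDataset) keeps
## drawing from the current stream so successive segments differ.
resolveSeed <- function(cfg, seed) {
  if (is.null(seed)) NULL
  else if (is.na(seed)) cfg@seed
  else seed
}

newSegment <- function(cfg, x, label) {
  new("SegmentRecord", signal = x, samplingRate = cfg@samplingRate,
      label = label)
}

#' Generate a physiological iEEG segment
#'
#' Pink-noise background plus two to four low-amplitude band-limited
#' oscillations in the 8-30 Hz range (alpha/beta rhythms).  Contains no
#' spectral line at the mains frequency and no broadband high-frequency
#' activity beyond the 1/f background.
#'
#' @param cfg a [SynthConfig-class].
#' @param seed RNG seed overriding `cfg@seed` (NA: use `cfg@seed`).
#' @return a labelled [SegmentRecord-class].
#' @export
genPhysiological <- function(cfg, seed = NA) {
  validObject(cfg)
  withSeed(resolveSeed(cfg, seed), {
    n <- cfgSamples(cfg)
    t <- seq_len(n) / cfg@samplingRate
    x <- synthBackground(cfg)
    sdbg <- stats::sd(x)
    for (k in seq_len(sample(2:4, 1))) {
      f <- stats::runif(1, 8, 30)
      a <- stats::runif(1, 0.2, 0.5) * sdbg
      x <- x + a * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    }
    ## occasional benign sharp transients (no superimposed HFO), and
    ## occasional gamma/low-ripple bursts; sometimes a burst is centred
    ## on a transient (spindle-on-vertex-wave-like), which spectrally
    ## and morphologically abuts a weak spike-with-HFO
    transientCentres <- numeric(0)
    for (k in seq_len(stats::rbinom(1, 3, 0.4))) {
      centre <- stats::runif(1, 0.2, cfg@segmentSeconds - 0.2)
      transientCentres <- c(transientCentres, centre)
      x <- addBenignTransient(x, cfg@samplingRate, sdbg, centre)
    }
    for (k in seq_len(stats::rbinom(1, 2, 0.4))) {
      fg <- stats::runif(1, 60, 140)
      dur <- stats::runif(1, 0.05, 0.3)
      centre <- if (length(transientCentres) && stats::runif(1) < 0.35)
        sample(transientCentres, 1)
      else stats::runif(1, 0.3, cfg@segmentSeconds - 0.3)
      gwin <- exp(-(t - centre)^2 / (2 * (dur / 4)^2))
      x <- x + stats::runif(1, 0.3, 0.8) * sdbg * gwin *
        sin(2 * pi * fg * t)
    }
    newSegment(cfg, x, "physiological")
  })
}

## Biphasic sharp transient (difference of two offset Gaussians) with a
## Gaussian-windowed ripple-band burst centred on the spike peak.
addSpikeHFO <- function(x, fs, snr, sdbg, hampMin = 0.15) {
  n <- length(x)
  width <- stats::runif(1, 0.04, 0.12)         # spike duration, s
  sigma <- width / 6
  centre <- stats::runif(1, 0.15, n / fs - 0.15)
  t <- (seq_len(n) / fs) - centre
  spike <- exp(-t^2 / (2 * sigma^2)) -
    0.6 * exp(-(t - 1.2 * sigma)^2 / (2 * (1.8 * sigma)^2))
  spike <- spike / max(abs(spike))
  amp <- sign(stats::runif(1) - 0.2) * stats::runif(1, 0.1, 1.5) *
    snr * sdbg                                  # variable size and polarity
  ## HFO riding on the spike peak; amplitudes have a weak tail so many
  ## spikes carry only a subtle ripple
  fhfo <- stats::runif(1, 100, 240)
  hdur <- stats::runif(1, 0.04, 0.1)
  hwin <- exp(-t^2 / (2 * (hdur / 4)^2))
  hamp <- stats::runif(1, hampMin, 2.0) * sdbg
  x + amp * spike + hamp * hwin * sin(2 * pi * fhfo * t)
}

#' Generate a pathological iEEG segment
#'
#' Physiological background plus 1-5 interictal spike transients
#' (biphasic sharp waves, 50-100 ms) each carrying a superimposed
#' high-frequency oscillation burst in the ripple band, centred on the
#' spike peak.
#'
#' @param cfg a [SynthConfig-class].
#' @param nSpikes number of spikes; NULL draws 1-5 at random.  0 reduces
#'   to the physiological contract.
#' @param seed RNG seed overriding `cfg@seed`.
#' @return a labelled [SegmentRecord-class].
#' @export
genPathological <- function(cfg, nSpikes = NULL, seed = NA) {
  validObject(cfg)
  withSeed(resolveSeed(cfg, seed), {
    n <- cfgSamples(cfg)
    t <- seq_len(n) / cfg@samplingRate
    x <- synthBackground(cfg)
    sdbg <- stats::sd(x)
    for (k in seq_len(sample(2:4, 1))) {
      f <- stats::runif(1, 8, 30)
      a <- stats::runif(1, 0.2, 0.5) * sdbg
      x <- x + a * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    }
    k <- if (is.null(nSpikes)) sample(1:5, 1) else as.integer(nSpikes)
    if (k < 0) stopValidation("nSpikes must be non-negative")
    for (i in seq_len(k))
      x <- addSpikeHFO(x, cfg@samplingRate, cfg@artifactSNR, sdbg,
                       hampMin = if (i == 1) 0.25 else 0.15)
    newSegment(cfg, x, if (k == 0) "physiological" else "pathological")
  })
}

#' Generate a power-line noise segment
#'
#' Physiological background plus a sinusoid at the mains frequency with
#' smaller odd harmonics; the spectral line dominates the periodogram.
#'
#' @param cfg a [SynthConfig-class]; `cfg@lineFreq` must be 50 or 60.
#' @param lineFreq mains frequency override (50 or 60 Hz).
#' @param amplitude line amplitude; NULL uses `artifactSNR` x background
#'   standard deviation.  0 returns pure background.
#' @param seed RNG seed overriding `cfg@seed`.
#' @return a labelled [SegmentRecord-class].
#' @export
genLineNoise <- function(cfg, lineFreq = NULL, amplitude = NULL, seed = NA) {
  validObject(cfg)
  lf <- if (is.null(lineFreq)) cfg@lineFreq else lineFreq
  if (!lf %in% c(50, 60))
    stopValidation("line frequency must be 50 or 60 Hz, got ", lf)
  withSeed(resolveSeed(cfg, seed), {
    n <- cfgSamples(cfg)
    t <- seq_len(n) / cfg@samplingRate
    x <- synthBackground(cfg)
    sdbg <- stats::sd(x)
    ## the floor keeps the spectral line dominant over the 1/f background
    ## peak for every draw (class contract)
    a <- if (is.null(amplitude)) stats::runif(1, 0.7, 1.5) *
      cfg@artifactSNR * sdbg else amplitude
    phi <- stats::runif(1, 0, 2 * pi)
    line <- a * (sin(2 * pi * lf * t + phi) +
                   0.25 * sin(2 * pi * 3 * lf * t + 3 * phi) +
                   0.10 * sin(2 * pi * 5 * lf * t + 5 * phi))
    label <- if (lf == 50) "line_noise_50" else "line_noise_60"
    newSegment(cfg, x + line, label)
  })
}

#' Generate a non-cerebral artifact segment
#'
#' One of three waveform families on a physiological background:
#' `muscle` -- a broadband high-frequency noise burst of at least 0.5 s;
#' `step` -- a baseline jump exceeding ten background standard deviations
#' (movement/discontinuity); `clip` -- a high-amplitude transient saturated
#' at a clipping level (machine artifact).
#'
#' @param cfg a [SynthConfig-class].
#' @param variant "muscle", "step", "clip" or "random".
#' @param seed RNG seed overriding `cfg@seed`.
#' @return a labelled [SegmentRecord-class].
#' @export
genArtifact <- function(cfg, variant = c("random", "muscle", "step", "clip"),
                        seed = NA) {
  validObject(cfg)
  variant <- match.arg(variant)
  withSeed(resolveSeed(cfg, seed), {
    if (variant == "random")
      variant <- sample(c("muscle", "step", "clip"), 1)
    n <- cfgSamples(cfg)
    fs <- cfg@samplingRate
    x <- synthBackground(cfg)
    sdbg <- stats::sd(x)
    if (variant == "muscle") {
      ## bursts may fill the whole segment: muscle artifact can span
      ## several seconds, which motivated the 3-s segment length
      dur <- stats::runif(1, 0.5, cfg@segmentSeconds)
      start <- stats::runif(1, 0, n / fs - dur)
      idx <- seq(floor(start * fs) + 1, floor((start + dur) * fs))
      burst <- stats::rnorm(length(idx))
      flt <- signal::butter(3, 100 / (fs / 2), type = "high")
      burst <- signal::filtfilt(flt, burst)
      ## sustained EMG envelope: flat middle with short cosine ramps
      m <- length(idx)
      ramp <- max(2L, min(round(0.2 * cfg@samplingRate), m %/% 4))
      win <- rep(1, m)
      win[1:ramp] <- 0.5 - 0.5 * cos(pi * (1:ramp) / ramp)
      win[(m - ramp + 1):m] <- rev(win[1:ramp])
      x[idx] <- x[idx] + stats::runif(1, 0.4, 1.5) * cfg@artifactSNR * sdbg *
        win * burst / stats::sd(burst)
    } else if (variant == "step") {
      at <- sample.int(n - 1, 1)
      jump <- sample(c(-1, 1), 1) * stats::runif(1, 12, 20) * sdbg
      x[(at + 1):n] <- x[(at + 1):n] + jump
    } else {                                   # clip
      dur <- stats::runif(1, 0.2, 0.8)
      centre <- stats::runif(1, dur, n / fs - dur)
      t <- (seq_len(n) / fs) - centre
      pulse <- stats::runif(1, 3, 5) * cfg@artifactSNR * sdbg *
        exp(-t^2 / (2 * (dur / 4)^2))
      clipAt <- 1.5 * cfg@artifactSNR * sdbg
      x <- pmin(pmax(x + pulse, -clipAt), clipAt)
    }
    newSegment(cfg, x, "artifact")
  })
}

#' Generate a labelled synthetic dataset
#'
#' Draws the requested number of segments per class from a single seeded
#' stream and shuffles them.  Count names must be canonical class labels;
#' see [classLabels()].
#'
#' @param cfg a [SynthConfig-class].
#' @param counts named integer vector, e.g.
#'   `c(physiological = 40, pathological = 10, line_noise_50 = 20, artifact = 20)`.
#' @param seed RNG seed overriding `cfg@seed`.
#' @return a [SegmentSet-class] with one column per segment.
#' @export
genDataset <- function(cfg, counts, seed = NA) {
  validObject(cfg)
  if (length(counts) == 0)
    stopValidation("counts must name at least one class")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stopValidation("counts must be a named vector of class labels")
  checkLabels(names(counts))
  if (any(counts < 0)) stopValidation("counts must be non-negative")
  withSeed(resolveSeed(cfg, seed), {
    n <- cfgSamples(cfg)
    total <- sum(counts)
    sig <- matrix(0, nrow = n, ncol = total)
    lab <- character(total)
    j <- 0L
    for (cls in names(counts)) {
      for (i in seq_len(counts[[cls]])) {
        seg <- switch(cls,
          physiological = genPhysiological(cfg, seed = NULL),
          pathological  = genPathological(cfg, seed = NULL),
          line_noise_50 = genLineNoise(cfg, lineFreq = 50, seed = NULL),
          line_noise_60 = genLineNoise(cfg, lineFreq = 60, seed = NULL),
          artifact      = genArtifact(cfg, seed = NULL))
        j <- j + 1L
        sig[, j] <- seg@signal
        lab[j] <- cls
      }
    }
    ord <- sample.int(total)
    new("SegmentSet", signals = sig[, ord, drop = FALSE],
        samplingRate = cfg@samplingRate, labels = lab[ord])
  })
}

#' Concatenate a SegmentSet into a continuous recording
#'
#' Lays the segments of a set end to end across `nChannels` channels
#' (round-robin) and returns both the resulting [RecordingBundle-class]
#' and an annotation table marking each segment's interval and label.
#' Used by the `simulate` pipeline stage to produce file-backed synthetic
#' recordings.
#'
#' @param set a labelled [SegmentSet-class].
#' @param nChannels number of output channels.
#' @param channelPrefix prefix for generated channel names.
#' @return list with elements `bundle` and `annotations` (data.frame with
#'   columns channel, start_sample, end_sample, label; 0-based half-open).
#' @export
datasetToRecording <- function(set, nChannels = 1, channelPrefix = "ch") {
  stopifnot(is(set, "SegmentSet"))
  ns <- nSegments(set)
  if (ns == 0) stopValidation("empty SegmentSet")
  perChan <- ceiling(ns / nChannels)
  len <- nrow(set@signals)
  sig <- matrix(0, nrow = nChannels, ncol = perChan * len)
  ann <- vector("list", ns)
  for (i in seq_len(ns)) {
    ch <- ((i - 1) %% nChannels) + 1
    slot <- (i - 1) %/% nChannels
    sig[ch, (slot * len + 1):((slot + 1) * len)] <- set@signals[, i]
    ann[[i]] <- data.frame(
      channel = paste0(channelPrefix, ch),
      start_sample = slot * len, end_sample = (slot + 1) * len,
      label = set@labels[i], stringsAsFactors = FALSE)
  }
  bundle <- new("RecordingBundle", signal = sig,
                samplingRate = set@samplingRate,
                channelNames = paste0(channelPrefix, seq_len(nChannels)))
  list(bundle = bundle, annotations = do.call(rbind, ann))
}
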