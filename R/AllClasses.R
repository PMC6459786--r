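## S4 classes for the central containers.

#' Configuration of the synthetic iEEG generator
#'
#' Holds the acquisition constants (5 kHz sampling, 3-s segments) and the
#' generator's amplitude model.  `backgroundAmplitude` is the standard
#' deviation of the pink-noise background in arbitrary (microvolt-scale)
#' units; `artifactSNR` scales transient events (spikes, bursts, line
#' noise) relative to that background standard deviation.
#'
#' @slot samplingRate sampling rate in Hz (default 5000).
#' @slot segmentSeconds segment duration in seconds (default 3).
#' @slot lineFreq power-line frequency in Hz, 50 or 60.
#' @slot backgroundAmplitude background standard deviation, arbitrary units.
#' @slot artifactSNR event-to-background amplitude ratio.
#' @slot seed integer RNG seed, or NA to draw from the current stream.
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(samplingRate = "numeric", segmentSeconds = "numeric",
                 lineFreq = "numeric", backgroundAmplitude = "numeric",
                 artifactSNR = "numeric", seed = "numeric"),
  prototype(samplingRate = 5000, segmentSeconds = 3, lineFreq = 50,
            backgroundAmplitude = 25, artifactSNR = 2.5, seed = NA_real_))

setValidity("SynthConfig", function(object) {
  msgs <- character()
  if (length(object@samplingRate) != 1 || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msgs <- c(msgs, "samplingRate must be a positive number")
  if (length(object@segmentSeconds) != 1 ||
      !is.finite(object@segmentSeconds) || object@segmentSeconds <= 0)
    msgs <- c(msgs, "segmentSeconds must be a positive number")
  if (length(msgs) == 0) {
    n <- object@samplingRate * object@segmentSeconds
    if (abs(n - round(n)) > 1e-8)
      msgs <- c(msgs, "samplingRate * segmentSeconds must be a whole number of samples")
  }
  if (!object@lineFreq %in% c(50, 60))
    msgs <- c(msgs, "lineFreq must be 50 or 60")
  if (object@backgroundAmplitude <= 0)
    msgs <- c(msgs, "backgroundAmplitude must be positive")
  if (object@artifactSNR <= 0)
    msgs <- c(msgs, "artifactSNR must be positive")
  if (length(msgs)) msgs else TRUE
})

#' A single labelled iEEG segment
#'
#' One channel, a fixed duration of signal at a known sampling rate, with
#' an optional gold-standard class label.
#'
#' @slot signal numeric vector of samples.
#' @slot samplingRate sampling rate in Hz.
#' @slot label one of [classLabels()] or NA when unlabelled.
#' @exportClass SegmentRecord
setClass("SegmentRecord",
  representation(signal = "numeric", samplingRate = "numeric",
                 label = "character"),
  prototype(label = NA_character_))

setValidity("SegmentRecord", function(object) {
  if (length(object@signal) == 0) return("signal must be non-empty")
  if (object@samplingRate <= 0) return("samplingRate must be positive")
  if (length(object@label) != 1) return("label must be length 1")
  if (!is.na(object@label) && !object@label %in% classLabels())
    return(paste0("unknown label: ", object@label))
  TRUE
})

#' A collection of equally sized labelled segments
#'
#' Segments are stored as the columns of a samples-by-segments matrix for
#' efficient batch feature extraction; labels align with columns.
#'
#' @slot signals numeric matrix, samples in rows, one column per segment.
#' @slot samplingRate sampling rate in Hz.
#' @slot labels character vector of per-segment labels (NA allowed).
#' @exportClass SegmentSet
setClass("SegmentSet",
  representation(signals = "matrix", samplingRate = "numeric",
                 labels = "character"))

setValidity("SegmentSet", function(object) {
  if (ncol(object@signals) != length(object@labels))
    return("labels length must equal the number of segments")
  if (object@samplingRate <= 0) return("samplingRate must be positive")
  bad <- setdiff(unique(object@labels[!is.na(object@labels)]), classLabels())
  if (length(bad)) return(paste0("unknown label(s): ",
                                 paste(bad, collapse = ", ")))
  TRUE
})

#' A multichannel continuous recording
#'
#' @slot signal numeric matrix, channels in rows, samples in columns.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelNames unique channel names, one per row.
#' @exportClass RecordingBundle
setClass("RecordingBundle",
  representation(signal = "matrix", samplingRate = "numeric",
                 channelNames = "character"))

setValidity("RecordingBundle", function(object) {
  if (nrow(object@signal) != length(object@channelNames))
    return("channelNames length must equal the number of signal rows")
  if (anyDuplicated(object@channelNames))
    return("channelNames must be unique")
  if (object@samplingRate <= 0) return("samplingRate must be positive")
  TRUE
})

#' Channel-by-second class probability grid
#'
#' The source object for artifact and pathology probability matrices
#' (APM/PPM): for every channel and every 1-s epoch, a class probability
#' vector summing to one.  Seconds are 0-based: column j covers the epoch
#' \[j, j+1) seconds.
#'
#' @slot values 3-D numeric array, channels x seconds x classes.
#' @slot channelNames channel names, one per array row.
#' @slot classOrder class labels, one per array slice.
#' @exportClass ProbabilityMatrix
setClass("ProbabilityMatrix",
  representation(values = "array", channelNames = "character",
                 classOrder = "character"))

setValidity("ProbabilityMatrix", function(object) {
  d <- dim(object@values)
  if (length(d) != 3) return("values must be a 3-D array")
  if (d[1] != length(object@channelNames))
    return("channelNames length must equal dim 1")
  if (d[3] != length(object@classOrder))
    return("classOrder length must equal dim 3")
  if (d[1] > 0 && d[2] > 0) {
    sums <- apply(object@values, c(1, 2), sum)
    if (any(abs(sums - 1) > 1e-6))
      return("class probabilities must sum to 1 per (channel, second) cell")
  }
  TRUE
})

#' Confusion matrix of gold-standard versus automated classification
#'
#' Rows are gold-standard classes, columns the automated classification.
#'
#' @slot counts K x K non-negative integer matrix with class dimnames.
#' @slot classOrder class labels in row/column order.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(counts = "matrix", classOrder = "character"))

setValidity("ConfusionMatrix", function(object) {
  k <- length(object@classOrder)
  if (!all(dim(object@counts) == c(k, k)))
    return("counts must be K x K with K = length(classOrder)")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (any(object@counts != round(object@counts)))
    return("counts must be integers")
  TRUE
})

#' One-dimensional convolutional segment classifier
#'
#' Stacked conv -> batch-norm -> ReLU -> max-pool blocks over the 5-row
#' feature matrix (rows treated as input channels of a 1-D convolution),
#' followed by dropout, a hidden dense layer and a softmax output.
#'
#' @slot config list of architecture hyperparameters (see [modelConfig()]).
#' @slot classOrder output class labels, one per softmax unit.
#' @slot params named list of weight arrays.
#' @slot bnState running batch-norm means/variances used in evaluation mode.
#' @exportClass CNNClassifier
setClass("CNNClassifier",
  representation(config = "list", classOrder = "character",
                 params = "list", bnState = "list"))

setValidity("CNNClassifier", function(object) {
  if (length(object@classOrder) != object@config$nClasses)
    return("classOrder length must equal config$nClasses")
  TRUE
})
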