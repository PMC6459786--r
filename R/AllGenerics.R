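## Generics and accessors.

#' @rdname SegmentSet-class
#' @param object a SegmentSet, ProbabilityMatrix or ConfusionMatrix.
#' @export
setGeneric("nSegments", function(object) standardGeneric("nSegments"))

#' @rdname SegmentSet-class
#' @export
setGeneric("segmentLabels", function(object) standardGeneric("segmentLabels"))

#' @rdname RecordingBundle-class
#' @param object object with channels.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname ProbabilityMatrix-class
#' @param object object with a class ordering.
#' @export
setGeneric("classOrder", function(object) standardGeneric("classOrder"))

#' @rdname RecordingBundle-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @describeIn SegmentSet-class number of segments.
#' @export
setMethod("nSegments", "SegmentSet", function(object) ncol(object@signals))

#' @describeIn SegmentSet-class per-segment labels.
#' @export
setMethod("segmentLabels", "SegmentSet", function(object) object@labels)

#' @describeIn RecordingBundle-class channel names.
#' @export
setMethod("channelNames", "RecordingBundle",
          function(object) object@channelNames)

#' @describeIn ProbabilityMatrix-class channel names.
#' @export
setMethod("channelNames", "ProbabilityMatrix",
          function(object) object@channelNames)

#' @describeIn ProbabilityMatrix-class class labels in slice order.
#' @export
setMethod("classOrder", "ProbabilityMatrix",
          function(object) object@classOrder)

#' @describeIn ConfusionMatrix-class class labels in row/column order.
#' @export
setMethod("classOrder", "ConfusionMatrix", function(object) object@classOrder)

#' @describeIn CNNClassifier-class output class labels.
#' @export
setMethod("classOrder", "CNNClassifier", function(object) object@classOrder)

#' @describeIn RecordingBundle-class sampling rate in Hz.
#' @export
setMethod("samplingRate", "RecordingBundle",
          function(object) object@samplingRate)

#' @describeIn SegmentSet-class sampling rate in Hz.
#' @export
setMethod("samplingRate", "SegmentSet", function(object) object@samplingRate)

#' @describeIn SegmentRecord-class sampling rate in Hz.
#' @export
setMethod("samplingRate", "SegmentRecord",
          function(object) object@samplingRate)

#' Extract one segment from a SegmentSet
#'
#' @param object a [SegmentSet-class].
#' @param i segment index.
#' @return a [SegmentRecord-class].
#' @export
getSegment <- function(object, i) {
  stopifnot(is(object, "SegmentSet"))
  if (i < 1 || i > nSegments(object))
    stopValidation("segment index out of range")
  new("SegmentRecord", signal = object@signals[, i],
      samplingRate = object@samplingRate, label = object@labels[i])
}

#' Signal matrix of a SegmentSet
#'
#' @param object a [SegmentSet-class].
#' @return numeric matrix, samples x segments.
#' @export
segmentSignals <- function(object) {
  stopifnot(is(object, "SegmentSet"))
  object@signals
}

#' Signal vector of a SegmentRecord
#'
#' @param object a [SegmentRecord-class].
#' @return numeric vector of samples.
#' @export
segmentSignal <- function(object) {
  stopifnot(is(object, "SegmentRecord"))
  object@signal
}

#' @describeIn SegmentRecord-class label accessor.
#' @export
setMethod("segmentLabels", "SegmentRecord", function(object) object@label)

#' Signal matrix of a RecordingBundle
#'
#' @param object a [RecordingBundle-class].
#' @return numeric matrix, channels x samples.
#' @export
recordingSignal <- function(object) {
  stopifnot(is(object, "RecordingBundle"))
  object@signal
}

#' Probability array of a ProbabilityMatrix
#'
#' @param object a [ProbabilityMatrix-class].
#' @param class optional class label; if given, returns the channels x
#'   seconds probability slice for that class.
#' @return 3-D array, or a matrix when `class` is given.
#' @export
probValues <- function(object, class = NULL) {
  stopifnot(is(object, "ProbabilityMatrix"))
  if (is.null(class)) return(object@values)
  j <- match(class, object@classOrder)
  if (is.na(j))
    stopValidation("class '", class, "' not in classOrder")
  slice <- object@values[, , j, drop = FALSE]
  dim(slice) <- dim(object@values)[1:2]
  dimnames(slice) <- list(object@channelNames, NULL)
  slice
}

#' Counts of a ConfusionMatrix
#'
#' @param object a [ConfusionMatrix-class].
#' @return K x K integer matrix, gold rows x predicted columns.
#' @export
confusionCounts <- function(object) {
  stopifnot(is(object, "ConfusionMatrix"))
  object@counts
}

setMethod("show", "SegmentRecord", function(object) {
  cat(sprintf("SegmentRecord: %d samples at %g Hz (%.3g s), label: %s\n",
              length(object@signal), object@samplingRate,
              length(object@signal) / object@samplingRate,
              ifelse(is.na(object@label), "<none>", object@label)))
})

setMethod("show", "SegmentSet", function(object) {
  cat(sprintf("SegmentSet: %d segments of %d samples at %g Hz\n",
              ncol(object@signals), nrow(object@signals),
              object@samplingRate))
  tab <- table(object@labels, useNA = "ifany")
  if (length(tab))
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab),
                           collapse = ", "), "\n")
})

setMethod("show", "RecordingBundle", function(object) {
  cat(sprintf("RecordingBundle: %d channel(s) x %d samples at %g Hz (%.3g s)\n",
              nrow(object@signal), ncol(object@signal), object@samplingRate,
              ncol(object@signal) / object@samplingRate))
  cat("  channels:", paste(head(object@channelNames, 8), collapse = ", "),
      if (length(object@channelNames) > 8) "..." else "", "\n")
})

setMethod("show", "ProbabilityMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("ProbabilityMatrix: %d channel(s) x %d second(s) x %d class(es)\n",
              d[1], d[2], d[3]))
  cat("  classes:", paste(object@classOrder, collapse = ", "), "\n")
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (gold rows x automated columns):\n")
  print(object@counts)
})

setMethod("show", "CNNClassifier", function(object) {
  cfg <- object@config
  blocks <- vapply(cfg$convBlocks, function(b)
    sprintf("%df/k%d/p%d", b[1], b[2], b[3]), character(1))
  cat(sprintf("CNNClassifier: input %d x %d -> [%s] -> dense %d -> softmax %d\n",
              cfg$inputRows, cfg$inputLength,
              paste(blocks, collapse = " -> "), cfg$denseUnits, cfg$nClasses))
  cat("  classes:", paste(object@classOrder, collapse = ", "), "\n")
  cat(sprintf("  parameters: %d\n", parameterCount(object)))
})
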