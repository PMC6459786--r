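## Sliding-window detection over continuous recordings and the
## artifact / pathology probability matrices (APM / PPM).

#' Classify a continuous recording into a probability matrix
#'
#' Slides the classifier over each channel independently with 3-s windows
#' and a 1-s stride (2-s overlap); the probability vector of the window
#' starting at second t is assigned to its centre second t+1.  The first
#' and last seconds have no centred window and replicate the nearest
#' centred column so the matrix spans the full record.  A trailing
#' fraction of a second is dropped.
#'
#' @param model a trained [CNNClassifier-class].
#' @param bundle a [RecordingBundle-class] at the pipeline rate (the rate
#'   implied by the model input length / 3 s).
#' @param batchSize windows per forward batch.
#' @return a [ProbabilityMatrix-class], channels x floor(duration) seconds
#'   x classes.
#' @export
classifyRecord <- function(model, bundle, batchSize = 64) {
  stopifnot(is(model, "CNNClassifier"), is(bundle, "RecordingBundle"))
  cfg <- model@config
  winSec <- 3
  fs <- cfg$inputLength / winSec
  if (abs(bundle@samplingRate - fs) > 1e-6)
    stopValidation("recording rate ", bundle@samplingRate,
                   " Hz does not match the model's pipeline rate ", fs, " Hz")
  nSamp <- ncol(bundle@signal)
  nSec <- floor(nSamp / fs)
  if (nSec < winSec)
    stopValidation("recording must be at least ", winSec, " s long")
  nWin <- nSec - winSec + 1            # windows start at 0, 1, ... s
  nCh <- nrow(bundle@signal)
  k <- cfg$nClasses
  vals <- array(NA_real_, dim = c(nCh, nSec, k))
  winLen <- cfg$inputLength
  for (ch in seq_len(nCh)) {
    X <- array(0, dim = c(cfg$inputRows, winLen, nWin))
    for (w in seq_len(nWin)) {
      seg <- bundle@signal[ch, ((w - 1) * fs + 1):((w - 1) * fs + winLen)]
      X[, , w] <- buildFeatureMatrix(seg, fs = fs)
    }
    for (s in seq(1, nWin, by = batchSize)) {
      e <- min(s + batchSize - 1, nWin)
      probs <- predictProba(model, X[, , s:e, drop = FALSE])
      ## window starting at second w-1 centres on second w (0-based),
      ## i.e. column w + 1 in 1-based indexing
      vals[ch, (s:e) + 1, ] <- probs
    }
  }
  vals[, 1, ] <- vals[, 2, ]                     # leading edge
  if (nSec > nWin + 1)
    for (j in (nWin + 2):nSec) vals[, j, ] <- vals[, nWin + 1, ]
  new("ProbabilityMatrix", values = vals,
      channelNames = bundle@channelNames, classOrder = model@classOrder)
}

#' Binarise a probability matrix for one target class
#'
#' A cell is 1 iff the target class probability strictly exceeds the
#' threshold (default 0.95, the "probability higher than 95%" display
#' rule of the APM/PPM).
#'
#' @param pm a [ProbabilityMatrix-class].
#' @param targetClass class label to threshold (e.g. "artifact" for an
#'   APM, "pathological" for a PPM).
#' @param threshold probability threshold in (0, 1).
#' @return integer matrix channels x seconds of 0/1, channel rownames.
#' @export
binarizeMatrix <- function(pm, targetClass, threshold = 0.95) {
  stopifnot(is(pm, "ProbabilityMatrix"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stopValidation("threshold must lie strictly inside (0, 1)")
  slice <- probValues(pm, targetClass)
  out <- (slice > threshold) + 0L
  dimnames(out) <- list(pm@channelNames, NULL)
  out
}

#' Extract detection events from a binarised matrix
#'
#' Connected-component labelling along time: per channel, maximal runs of
#' supra-threshold seconds become events; runs shorter than
#' `minDurationS` are discarded.  Intervals are 0-based half-open seconds.
#'
#' @param binMat channels x seconds 0/1 matrix (see [binarizeMatrix()]).
#' @param pm optional source [ProbabilityMatrix-class] to record each
#'   event's peak probability.
#' @param targetClass class label of the events (needed for
#'   peak-probability lookup, recorded in the output).
#' @param minDurationS minimum run length in seconds.
#' @return data.frame with columns `channel`, `start_second`,
#'   `end_second`, `class`, `peak_probability` (NA without `pm`).
#' @export
extractEvents <- function(binMat, pm = NULL, targetClass = NA_character_,
                          minDurationS = 1) {
  if (minDurationS < 1) stopValidation("minDurationS must be >= 1")
  chNames <- rownames(binMat)
  if (is.null(chNames)) chNames <- paste0("ch", seq_len(nrow(binMat)))
  slice <- if (!is.null(pm)) probValues(pm, targetClass) else NULL
  out <- list()
  for (ch in seq_len(nrow(binMat))) {
    r <- rle(as.integer(binMat[ch, ]) > 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths           # 0-based start seconds
    keep <- r$values & r$lengths >= minDurationS
    for (j in which(keep)) {
      peak <- if (!is.null(slice))
        max(slice[ch, (starts[j] + 1):ends[j]]) else NA_real_
      out[[length(out) + 1]] <- data.frame(
        channel = chNames[ch], start_second = starts[j],
        end_second = ends[j], class = targetClass,
        peak_probability = peak, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(channel = character(), start_second = integer(),
                      end_second = integer(), class = character(),
                      peak_probability = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Render a probability or binary matrix as a raster image
#'
#' One pixel row per channel and one pixel column per second.  Binary
#' matrices use a two-colour map (blue background, yellow detections);
#' probability matrices use a blue-to-yellow ramp.
#'
#' @param m channels x seconds matrix (binary 0/1 or probabilities in
#'   \[0, 1\]), or a [ProbabilityMatrix-class] with `targetClass`.
#' @param path output PNG path.
#' @param targetClass class slice when `m` is a ProbabilityMatrix.
#' @param scale integer pixel scaling factor per cell.
#' @return `path`, invisibly.
#' @export
renderMatrix <- function(m, path, targetClass = NULL, scale = 1) {
  if (is(m, "ProbabilityMatrix")) {
    if (is.null(targetClass))
      stopValidation("targetClass required for a ProbabilityMatrix")
    m <- probValues(m, targetClass)
  }
  if (!is.matrix(m) || nrow(m) == 0 || ncol(m) == 0)
    stopValidation("matrix to render must be non-empty")
  binary <- all(m %in% c(0, 1))
  pal <- grDevices::colorRampPalette(c("#15306e", "#ffd500"))(256)
  idx <- if (binary) ifelse(m > 0, 256, 1)
  else pmin(256, pmax(1, floor(m * 255) + 1))
  cols <- matrix(pal[idx], nrow = nrow(m))
  ok <- tryCatch({
    grDevices::png(path, width = ncol(m) * scale, height = nrow(m) * scale)
    graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1))
    graphics::rasterImage(grDevices::as.raster(cols), 0, 0, 1, 1,
                          interpolate = FALSE)
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    stop(errorCondition(paste0("failed to write image: ",
                               conditionMessage(e)),
                        class = c("ieegnoise_io_error", "error")))
  })
  invisible(path)
}
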