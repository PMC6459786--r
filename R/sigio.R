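## Signal, annotation, probability-matrix and checkpoint I/O.
##
## Native signal storage is a flat little-endian float64 array plus a YAML
## sidecar header (<path>.hdr); EDF is supported for interoperability.
## All sample coordinates are 0-based half-open [start, end).

#' Write a recording in the native array format
#'
#' Writes the signal as little-endian float64, channel-major (all samples
#' of channel 1, then channel 2, ...), with a YAML sidecar header
#' `<path>.hdr` describing sampling rate, channel names and layout.
#'
#' @param bundle a [RecordingBundle-class].
#' @param path output data-file path.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(bundle, path) {
  stopifnot(is(bundle, "RecordingBundle"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(bundle@signal)), con, size = 8, endian = "little")
  hdr <- list(format = "ieegnoise-array", version = 1L,
              sampling_rate_hz = bundle@samplingRate,
              n_channels = nrow(bundle@signal),
              n_samples = ncol(bundle@signal),
              channel_names = as.list(bundle@channelNames),
              dtype = "float64", byte_order = "little",
              layout = "channel_major")
  yaml::write_yaml(hdr, paste0(path, ".hdr"))
  invisible(path)
}

readArrayRecording <- function(path) {
  hdrPath <- paste0(path, ".hdr")
  if (!file.exists(hdrPath))
    stopFormat("missing sidecar header: ", hdrPath)
  hdr <- tryCatch(yaml::read_yaml(hdrPath),
                  error = function(e) stopFormat("unparseable header: ",
                                                 conditionMessage(e)))
  for (field in c("sampling_rate_hz", "n_channels", "n_samples",
                  "channel_names"))
    if (is.null(hdr[[field]]))
      stopFormat("header missing required field '", field, "'")
  nch <- as.integer(hdr$n_channels)
  ns <- as.integer(hdr$n_samples)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = nch * ns, size = 8,
               endian = "little")
  if (length(x) != nch * ns)
    stopFormat("data file holds ", length(x), " samples; header says ",
               nch * ns)
  new("RecordingBundle",
      signal = matrix(x, nrow = nch, byrow = TRUE),
      samplingRate = hdr$sampling_rate_hz,
      channelNames = unlist(hdr$channel_names))
}

readAscii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

readEDFRecording <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readAscii(con, 8)                       # version
  readAscii(con, 80); readAscii(con, 80)  # patient / recording id
  readAscii(con, 8); readAscii(con, 8)    # start date / time
  headerBytes <- suppressWarnings(as.integer(readAscii(con, 8)))
  readAscii(con, 44)                      # reserved
  nRecords <- suppressWarnings(as.integer(readAscii(con, 8)))
  recDur <- suppressWarnings(as.numeric(readAscii(con, 8)))
  ns <- suppressWarnings(as.integer(readAscii(con, 4)))
  if (is.na(ns) || ns < 1)
    stopFormat("EDF header field 'number of signals' is invalid")
  if (is.na(nRecords) || nRecords < 0)
    stopFormat("EDF header field 'number of data records' is invalid")
  if (is.na(recDur) || recDur <= 0)
    stopFormat("EDF header field 'record duration' is invalid")
  labels <- vapply(seq_len(ns), function(i) readAscii(con, 16), character(1))
  for (i in seq_len(ns)) readAscii(con, 80)     # transducer
  for (i in seq_len(ns)) readAscii(con, 8)      # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i)
    suppressWarnings(as.numeric(readAscii(con, 8))), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i)
    suppressWarnings(as.numeric(readAscii(con, 8))), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i)
    suppressWarnings(as.numeric(readAscii(con, 8))), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i)
    suppressWarnings(as.numeric(readAscii(con, 8))), numeric(1))
  for (i in seq_len(ns)) readAscii(con, 80)     # prefiltering
  spr <- vapply(seq_len(ns), function(i)
    suppressWarnings(as.integer(readAscii(con, 8))), integer(1))
  for (i in seq_len(ns)) readAscii(con, 32)     # reserved
  if (any(is.na(pmin_) | is.na(pmax_) | is.na(dmin_) | is.na(dmax_)))
    stopFormat("EDF header has invalid physical/digital min/max fields")
  if (any(is.na(spr) | spr < 1))
    stopFormat("EDF header field 'samples per record' is invalid")
  if (length(unique(spr)) != 1)
    stop(errorCondition(
      "mixed per-channel sampling rates in EDF are unsupported",
      class = c("ieegnoise_unsupported_error", "error")))
  if (any(dmax_ == dmin_))
    stopFormat("EDF header has equal digital min and max")
  fs <- spr[1] / recDur
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  sig <- matrix(0, nrow = ns, ncol = nRecords * spr[1])
  for (r in seq_len(nRecords)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                   endian = "little")
      if (length(d) != spr[i])
        stopFormat("EDF data truncated in record ", r)
      sig[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (d - dmin_[i]) * gain[i] + pmin_[i]
    }
  }
  nm <- make.unique(ifelse(nzchar(labels), labels,
                           paste0("ch", seq_len(ns))))
  new("RecordingBundle", signal = sig, samplingRate = fs,
      channelNames = nm)
}

#' Read a multichannel recording
#'
#' @param path file path (for the array format, the data file; the header
#'   is expected at `<path>.hdr`).
#' @param format "array" (native flat array + YAML header) or "edf"
#'   (European Data Format; all channels must share one sampling rate).
#' @return a [RecordingBundle-class].
#' @export
readRecording <- function(path, format = c("array", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopFormat("file not found: ", path)
  switch(format, array = readArrayRecording(path),
         edf = readEDFRecording(path))
}

## Minimal EDF writer (16-bit), used to build interoperability fixtures.
padField <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

writeEDFRecording <- function(bundle, path, recordSeconds = 1) {
  stopifnot(is(bundle, "RecordingBundle"))
  ns <- nrow(bundle@signal)
  spr <- as.integer(round(bundle@samplingRate * recordSeconds))
  nRec <- ncol(bundle@signal) %/% spr
  pmax_ <- apply(bundle@signal, 1, function(x) max(abs(x), 1))
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, w) writeBin(charToRaw(padField(x, w)), con)
  put("0", 8); put("synthetic", 80); put("synthetic", 80)
  put("01.01.26", 8); put("00.00.00", 8)
  put(256 + ns * 256, 8); put("", 44)
  put(nRec, 8); put(format(recordSeconds), 8); put(ns, 4)
  for (i in seq_len(ns)) put(bundle@channelNames[i], 16)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (i in seq_len(ns)) put(format(-pmax_[i], digits = 6), 8)
  for (i in seq_len(ns)) put(format(pmax_[i], digits = 6), 8)
  for (i in seq_len(ns)) put(-32768, 8)
  for (i in seq_len(ns)) put(32767, 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(spr, 8)
  for (i in seq_len(ns)) put("", 32)
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      x <- bundle@signal[i, ((r - 1) * spr + 1):(r * spr)]
      d <- round((x - (-pmax_[i])) / (2 * pmax_[i] / 65535)) - 32768
      writeBin(as.integer(pmin(pmax(d, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read / write per-channel annotation tables
#'
#' Tab-delimited tables with columns `channel`, `start_sample`,
#' `end_sample`, `label`; sample coordinates are 0-based half-open.
#' Labels must be canonical class labels ([classLabels()]); unknown
#' labels are rejected.
#'
#' @param path file path.
#' @return data.frame of validated annotations.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stopFormat("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("channel", "start_sample", "end_sample", "label")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stopFormat("annotation table missing column(s): ",
               paste(miss, collapse = ", "))
  validateAnnotations(tab)
}

#' @rdname readAnnotations
#' @param annotations annotation data.frame.
#' @export
writeAnnotations <- function(annotations, path) {
  validateAnnotations(annotations)
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validateAnnotations <- function(tab, bundle = NULL) {
  if (any(tab$start_sample < 0))
    stopValidation("start_sample must be non-negative")
  if (any(tab$end_sample <= tab$start_sample))
    stopValidation("annotations must satisfy start_sample < end_sample")
  checkLabels(tab$label)
  if (!is.null(bundle)) {
    bad <- setdiff(unique(tab$channel), bundle@channelNames)
    if (length(bad))
      stopValidation("annotation references unknown channel(s): ",
                     paste(bad, collapse = ", "))
    if (any(tab$end_sample > ncol(bundle@signal)))
      stopValidation("annotation extends past the end of the recording")
  }
  tab
}

#' Cut annotated intervals into fixed-length labelled segments
#'
#' Each annotated interval is tiled into non-overlapping segments of
#' `segmentSeconds`; a trailing remainder shorter than one segment is
#' dropped.  Every segment inherits its interval's label.
#'
#' @param bundle a [RecordingBundle-class].
#' @param annotations annotation data.frame (see [readAnnotations()]).
#' @param segmentSeconds segment duration in seconds (default 3).
#' @return a labelled [SegmentSet-class].
#' @export
segmentRecording <- function(bundle, annotations, segmentSeconds = 3) {
  stopifnot(is(bundle, "RecordingBundle"))
  validateAnnotations(annotations, bundle)
  segLen <- as.integer(round(bundle@samplingRate * segmentSeconds))
  sigs <- list()
  labs <- character(0)
  for (r in seq_len(nrow(annotations))) {
    a <- annotations[r, ]
    ch <- match(a$channel, bundle@channelNames)
    nSeg <- (a$end_sample - a$start_sample) %/% segLen
    for (j in seq_len(nSeg)) {
      s0 <- a$start_sample + (j - 1) * segLen
      sigs[[length(sigs) + 1]] <- bundle@signal[ch, (s0 + 1):(s0 + segLen)]
      labs <- c(labs, a$label)
    }
  }
  signals <- if (length(sigs)) do.call(cbind, sigs)
  else matrix(numeric(0), nrow = segLen, ncol = 0)
  new("SegmentSet", signals = signals, samplingRate = bundle@samplingRate,
      labels = labs)
}

#' Write / read a probability matrix as delimited text
#'
#' Long-by-class wide-by-time layout: one row per (channel, class) pair
#' with columns `channel`, `class`, then one column per 1-s epoch
#' (`s0`, `s1`, ...).  Round-trips preserve values to at least six
#' significant digits.
#'
#' @param pm a [ProbabilityMatrix-class].
#' @param path file path.
#' @return `path` (write) or a [ProbabilityMatrix-class] (read).
#' @export
writeProbabilityMatrix <- function(pm, path) {
  stopifnot(is(pm, "ProbabilityMatrix"))
  d <- dim(pm@values)
  if (d[1] == 0 || d[2] == 0)
    stopValidation("cannot write an empty probability matrix")
  rows <- list()
  for (k in seq_along(pm@classOrder)) {
    m <- probValues(pm, pm@classOrder[k])
    df <- data.frame(channel = pm@channelNames,
                     class = pm@classOrder[k], stringsAsFactors = FALSE)
    vals <- as.data.frame(signif(m, 9))
    names(vals) <- paste0("s", seq_len(d[2]) - 1)
    rows[[k]] <- cbind(df, vals)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProbabilityMatrix
#' @export
readProbabilityMatrix <- function(path) {
  if (!file.exists(path)) stopFormat("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "class") %in% names(tab)))
    stopFormat("probability matrix file missing channel/class columns")
  classes <- unique(tab$class)
  channels <- unique(tab$channel)
  secCols <- grep("^s[0-9]+$", names(tab), value = TRUE)
  nSec <- length(secCols)
  vals <- array(NA_real_, dim = c(length(channels), nSec, length(classes)))
  for (k in seq_along(classes)) {
    sub <- tab[tab$class == classes[k], ]
    sub <- sub[match(channels, sub$channel), ]
    vals[, , k] <- as.matrix(sub[, secCols])
  }
  ## renormalise away text-precision loss
  sums <- apply(vals, c(1, 2), sum)
  vals <- vals / array(rep(sums, length(classes)), dim = dim(vals))
  new("ProbabilityMatrix", values = vals, channelNames = channels,
      classOrder = classes)
}

#' Save / load a classifier checkpoint
#'
#' Checkpoints store the architecture hyperparameters, all weights, the
#' batch-norm running statistics and the class-label ordering; loading
#' reconstructs a model whose outputs match the saved model exactly.
#' Structural mismatches (e.g. a class list inconsistent with the output
#' layer) raise a version error.
#'
#' @param model a [CNNClassifier-class].
#' @param path checkpoint path.
#' @return `path` (save) or the restored [CNNClassifier-class] (load).
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "CNNClassifier"))
  saveRDS(list(format = "ieegnoise-checkpoint", version = 1L,
               config = model@config, classOrder = model@classOrder,
               params = model@params, bnState = model@bnState),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stopFormat("file not found: ", path)
  ck <- tryCatch(readRDS(path),
                 error = function(e) stopFormat("unreadable checkpoint: ",
                                                conditionMessage(e)))
  if (!identical(ck$format, "ieegnoise-checkpoint"))
    stopVersion("not an ieegnoise checkpoint")
  if (!identical(ck$version, 1L))
    stopVersion("unsupported checkpoint version: ", ck$version)
  if (length(ck$classOrder) != ck$config$nClasses ||
      nrow(ck$params$out_W) != ck$config$nClasses)
    stopVersion("checkpoint class list does not match the output layer")
  new("CNNClassifier", config = ck$config, classOrder = ck$classOrder,
      params = ck$params, bnState = ck$bnState)
}
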