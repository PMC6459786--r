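makeBundle <- function(nch = 2, seconds = 10, fs = 5000, seed = 1) {
  set.seed(seed)
  new("RecordingBundle",
      signal = matrix(rnorm(nch * seconds * fs), nrow = nch),
      samplingRate = fs,
      channelNames = paste0("ch", seq_len(nch)))
}

test_that("array recordings round-trip bit-identically", {
  b <- makeBundle()
  path <- tempfile(fileext = ".dat")
  writeRecording(b, path)
  b2 <- readRecording(path, "array")
  expect_identical(recordingSignal(b2), recordingSignal(b))
  expect_equal(samplingRate(b2), 5000)
  expect_equal(channelNames(b2), c("ch1", "ch2"))
  ## missing header is a format error
  file.remove(paste0(path, ".hdr"))
  expect_error(readRecording(path, "array"), class = "ieegnoise_format_error")
  expect_error(readRecording(tempfile(), "array"),
               class = "ieegnoise_format_error")
})

test_that("EDF recordings are read with header-derived shape and scaling", {
  b <- makeBundle(nch = 2, seconds = 10, fs = 5000)
  path <- tempfile(fileext = ".edf")
  ieegnoise:::writeEDFRecording(b, path)
  r <- readRecording(path, "edf")
  expect_equal(dim(recordingSignal(r)), c(2, 50000))
  expect_equal(samplingRate(r), 5000)
  expect_equal(channelNames(r), c("ch1", "ch2"))
  ## 16-bit quantisation: relative error bounded by one quantisation step
  q <- 2 * max(abs(recordingSignal(b))) / 65535
  expect_lt(max(abs(recordingSignal(r) - recordingSignal(b))), q)
})

test_that("a byte-level hand-built EDF parses to the expected samples", {
  ## single channel, 1 record of 4 samples at 4 Hz, phys range -100..100
  path <- tempfile(fileext = ".edf")
  con <- file(path, "wb")
  pad <- function(x, w) writeBin(charToRaw(sprintf(paste0("%-", w, "s"), x)), con)
  pad("0", 8); pad("pt", 80); pad("rec", 80); pad("01.01.26", 8)
  pad("00.00.00", 8); pad(256 + 256, 8); pad("", 44); pad("1", 8)
  pad("1", 8); pad("1", 4)
  pad("sig1", 16); pad("", 80); pad("uV", 8)
  pad("-100", 8); pad("100", 8); pad("-32768", 8); pad("32767", 8)
  pad("", 80); pad("4", 8); pad("", 32)
  writeBin(as.integer(c(-32768, 0, 32767, 16384)), con, size = 2,
           endian = "little")
  close(con)
  r <- readRecording(path, "edf")
  expect_equal(samplingRate(r), 4)
  expect_equal(channelNames(r), "sig1")
  got <- as.numeric(recordingSignal(r))
  gain <- 200 / 65535
  expect_equal(got, (c(-32768, 0, 32767, 16384) + 32768) * gain - 100,
               tolerance = 1e-9)
})

test_that("annotated intervals tile into floor-division many labelled segments", {
  fs <- 5000
  b <- makeBundle(nch = 2, seconds = 20, fs = fs)
  ann <- data.frame(
    channel = c("ch1", "ch2", "ch1"),
    start_sample = c(0L, 10000L, 55000L),
    end_sample = c(45000L, 50000L, 65000L),    # 9 s, 8 s, 2 s
    label = c("artifact", "physiological", "pathological"),
    stringsAsFactors = FALSE)
  segs <- segmentRecording(b, ann, segmentSeconds = 3)
  expect_equal(nSegments(segs), 3 + 2 + 0)
  expect_equal(segmentLabels(segs),
               c(rep("artifact", 3), rep("physiological", 2)))
  expect_equal(nrow(segmentSignals(segs)), 15000)
  ## first segment equals the raw slice, 0-based half-open
  expect_identical(segmentSignals(segs)[, 1],
                   recordingSignal(b)[1, 1:15000])
  ## unknown channel rejected
  bad <- ann
  bad$channel[1] <- "nope"
  expect_error(segmentRecording(b, bad), class = "ieegnoise_validation_error")
  ## annotation tables round-trip with label validation
  path <- tempfile(fileext = ".tsv")
  writeAnnotations(ann, path)
  back <- readAnnotations(path)
  expect_equal(back, ann)
  bad2 <- ann
  bad2$label[1] <- "mystery"
  expect_error(writeAnnotations(bad2, path),
               class = "ieegnoise_validation_error")
})

test_that("probability matrices round-trip through delimited text", {
  set.seed(4)
  raw <- array(runif(3 * 10 * 2), dim = c(3, 10, 2))
  sums <- apply(raw, c(1, 2), sum)
  vals <- raw / array(rep(sums, 2), dim = dim(raw))
  pm <- new("ProbabilityMatrix", values = vals,
            channelNames = c("A1", "A2", "B1"),
            classOrder = c("artifact", "physiological"))
  path <- tempfile(fileext = ".tsv")
  writeProbabilityMatrix(pm, path)
  lines <- readLines(path)
  expect_length(lines, 1 + 3 * 2)          # header + channels x classes
  expect_length(strsplit(lines[2], "\t")[[1]], 2 + 10)
  pm2 <- readProbabilityMatrix(path)
  expect_equal(probValues(pm2), probValues(pm), tolerance = 1e-6)
  expect_equal(channelNames(pm2), channelNames(pm))
  ## empty matrix rejected
  empty <- new("ProbabilityMatrix",
               values = array(numeric(0), dim = c(0, 0, 2)),
               channelNames = character(0),
               classOrder = c("a", "b"))
  expect_error(writeProbabilityMatrix(empty, path),
               class = "ieegnoise_validation_error")
})

test_that("model checkpoints restore identical forward outputs", {
  model <- buildModel(modelConfig(nClasses = 3,
                                  convBlocks = list(c(4, 5, 4), c(8, 5, 4)),
                                  denseUnits = 16, inputLength = 240),
                      seed = 5, classOrder = c("physiological",
                                               "pathological", "artifact"))
  path <- tempfile(fileext = ".rds")
  saveModel(model, path)
  model2 <- loadModel(path)
  set.seed(2)
  x <- matrix(rnorm(5 * 240), 5, 240)
  expect_identical(predictProba(model, x), predictProba(model2, x))
  expect_equal(classOrder(model2), classOrder(model))
  ## tampering with the class list is a version error
  ck <- readRDS(path)
  ck$classOrder <- ck$classOrder[1:2]
  tampered <- tempfile(fileext = ".rds")
  saveRDS(ck, tampered)
  expect_error(loadModel(tampered), class = "ieegnoise_version_error")
  expect_error(loadModel(tempfile()), class = "ieegnoise_format_error")
  ## a 3-class checkpoint is loadable and transfer-compatible (contract)
  gm <- loadModel(path)
  expect_length(classOrder(gm), 3)
})
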