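## Geometry tests run with an untrained (but deterministic) classifier:
## window placement, edge replication and thresholding do not depend on
## the weights.

freshModel <- function(k = 4, seed = 1) {
  labs <- c("physiological", "pathological", "line_noise_60", "artifact")
  buildModel(modelConfig(nClasses = k), seed = seed,
             classOrder = labs[seq_len(k)])
}

recordingOf <- function(nch, seconds, fs = 5000, seed = 1) {
  set.seed(seed)
  new("RecordingBundle",
      signal = matrix(rnorm(nch * round(seconds * fs)), nrow = nch),
      samplingRate = fs, channelNames = paste0("ch", seq_len(nch)))
}

test_that("classifyRecord builds a floor(T)-second matrix with centred windows and edge replication", {
  m <- freshModel()
  b <- recordingOf(2, 10)
  pm <- classifyRecord(m, b)
  v <- probValues(pm)
  expect_equal(dim(v), c(2, 10, 4))
  ## per-cell probabilities sum to one
  expect_true(all(abs(apply(v, c(1, 2), sum) - 1) < 1e-6))
  ## edge replication: column 0 copies column 1, last copies second-last
  expect_equal(v[, 1, ], v[, 2, ])
  expect_equal(v[, 10, ], v[, 9, ])
  ## interior columns come from 8 distinct centred windows
  expect_equal(length(unique(round(v[1, 2:9, 1], 10))), 8)
  ## exactly 3 s record: one window, three identical columns
  b3 <- recordingOf(1, 3)
  v3 <- probValues(classifyRecord(m, b3))
  expect_equal(dim(v3), c(1, 3, 4))
  expect_equal(v3[, 1, ], v3[, 2, ])
  expect_equal(v3[, 3, ], v3[, 2, ])
  ## trailing fraction of a second is dropped
  bfrac <- recordingOf(1, 4.6)
  expect_equal(dim(probValues(classifyRecord(m, bfrac)))[2], 4)
  ## too-short or wrong-rate input
  expect_error(classifyRecord(m, recordingOf(1, 2.5)),
               class = "ieegnoise_validation_error")
  bad <- recordingOf(1, 4, fs = 1000)
  expect_error(classifyRecord(m, bad), class = "ieegnoise_validation_error")
})

test_that("channels are classified independently: permuting rows permutes the matrix", {
  m <- freshModel()
  b <- recordingOf(3, 6, seed = 7)
  pm <- classifyRecord(m, b)
  perm <- c(3, 1, 2)
  bPerm <- new("RecordingBundle", signal = recordingSignal(b)[perm, ],
               samplingRate = samplingRate(b),
               channelNames = channelNames(b)[perm])
  pmPerm <- classifyRecord(m, bPerm)
  expect_equal(probValues(pmPerm), probValues(pm)[perm, , ])
  expect_equal(channelNames(pmPerm), channelNames(b)[perm])
})

test_that("a matrix column depends only on its 3-s source window", {
  m <- freshModel()
  b <- recordingOf(1, 8, seed = 3)
  pm <- classifyRecord(m, b)
  ## perturb samples outside [2, 5) s; column 3 (0-based) must not move
  sig <- recordingSignal(b)
  sig[1, c(1:(2 * 5000), (5 * 5000 + 1):(8 * 5000))] <-
    sig[1, c(1:(2 * 5000), (5 * 5000 + 1):(8 * 5000))] + 50
  b2 <- new("RecordingBundle", signal = sig, samplingRate = 5000,
            channelNames = "ch1")
  pm2 <- classifyRecord(m, b2)
  expect_equal(probValues(pm2)[1, 4, ], probValues(pm)[1, 4, ],
               tolerance = 1e-7)
})

test_that("binarisation is strict and APM/PPM sum to at most one detection per cell", {
  vals <- array(0, dim = c(1, 4, 2))
  vals[1, , 1] <- c(0.96, 0.95, 0.4, 0.951)
  vals[1, , 2] <- 1 - vals[1, , 1]
  pm <- new("ProbabilityMatrix", values = vals, channelNames = "ch1",
            classOrder = c("artifact", "physiological"))
  bm <- binarizeMatrix(pm, "artifact", 0.95)
  expect_equal(as.integer(bm), c(1L, 0L, 0L, 1L))     # strictly > 0.95
  expect_error(binarizeMatrix(pm, "artifact", 1.5),
               class = "ieegnoise_validation_error")
  expect_error(binarizeMatrix(pm, "bogus"), class = "ieegnoise_validation_error")
  ## all-physiological record -> all-zero artifact matrix
  expect_true(all(binarizeMatrix(pm, "physiological", 0.95)[, 1:2] == 0))
  ## 2-class vector (0.6, 0.4) at threshold 0.5 -> first class detected
  expect_equal(unname(binarizeMatrix(pm, "physiological", 0.5)[1, 3]), 1L)
  ## above 0.5, APM + PPM can never overlap
  set.seed(8)
  raw <- array(runif(3 * 20 * 3), dim = c(3, 20, 3))
  raw <- raw / array(rep(apply(raw, c(1, 2), sum), 3), dim = dim(raw))
  pm3 <- new("ProbabilityMatrix", values = raw,
             channelNames = paste0("c", 1:3),
             classOrder = c("artifact", "pathological", "physiological"))
  total <- binarizeMatrix(pm3, "artifact", 0.51) +
    binarizeMatrix(pm3, "pathological", 0.51)
  expect_true(all(total <= 1))
})

test_that("event extraction equals brute-force run enumeration", {
  row <- matrix(c(0, 1, 1, 1, 0, 1, 0), nrow = 1,
                dimnames = list("ch1", NULL))
  ev <- extractEvents(row, minDurationS = 1)
  expect_equal(ev$start_second, c(1, 5))
  expect_equal(ev$end_second, c(4, 6))
  ev2 <- extractEvents(row, minDurationS = 2)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$start_second, 1)
  ## empty input
  expect_equal(nrow(extractEvents(matrix(0, 2, 5))), 0)
  ## brute force over random binary rows
  set.seed(99)
  for (trial in 1:50) {
    bm <- matrix(rbinom(2 * 15, 1, 0.4), nrow = 2,
                 dimnames = list(c("a", "b"), NULL))
    minDur <- sample(1:3, 1)
    ev <- extractEvents(bm, minDurationS = minDur)
    ## enumerate runs directly
    brute <- list()
    for (ch in 1:2) {
      run <- 0
      for (t in 1:16) {
        on <- t <= 15 && bm[ch, t] == 1
        if (on) run <- run + 1
        else if (run > 0) {
          if (run >= minDur)
            brute[[length(brute) + 1]] <- c(ch, t - 1 - run, t - 1)
          run <- 0
        }
      }
    }
    expect_equal(nrow(ev), length(brute))
    if (length(brute)) {
      bmat <- do.call(rbind, brute)
      ord <- order(bmat[, 1], bmat[, 2])
      bmat <- bmat[ord, , drop = FALSE]
      expect_equal(ev$channel, c("a", "b")[bmat[, 1]])
      expect_equal(ev$start_second, bmat[, 2])
      expect_equal(ev$end_second, bmat[, 3])
    }
  }
})

test_that("rendered rasters have one pixel per channel-second", {
  skip_if_not_installed("png")
  bm <- matrix(rbinom(5 * 60, 1, 0.2), nrow = 5)
  path <- tempfile(fileext = ".png")
  renderMatrix(bm, path)
  img <- png::readPNG(path)
  expect_equal(dim(img)[1:2], c(5, 60))
  ## all-zero matrix renders a uniform background
  path0 <- tempfile(fileext = ".png")
  renderMatrix(matrix(0, 3, 10), path0)
  img0 <- png::readPNG(path0)
  expect_equal(length(unique(as.vector(img0[, , 1]))), 1)
  ## probability rendering shares dimensions with the binary one
  pathP <- tempfile(fileext = ".png")
  renderMatrix(matrix(runif(5 * 60), 5), pathP)
  expect_equal(dim(png::readPNG(pathP))[1:2], dim(img)[1:2])
})
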