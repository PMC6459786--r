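## Shared fixtures: small configs, an independent envelope oracle, and a
## lazily trained classifier reused across tests that need one.

fastSynthCfg <- function(seed = NA) synthConfig(seed = seed)

## Independent analytic-envelope oracle (squared magnitude of the
## analytic signal), written directly against the FFT so it does not
## share code with the package implementation.
oracleEnvelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  w <- rep(0, n)
  w[1] <- 1
  if (n %% 2 == 0) { w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2 }
  else w[2:((n + 1) / 2)] <- 2
  Mod(fft(X * w, inverse = TRUE) / n)^2
}

## Band power from a raw periodogram (oracle, no package code).
oracleBandPower <- function(x, fs, low, high) {
  n <- length(x)
  P <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sum(P[f >= low & f <= high & f <= fs / 2])
}

## Tiny model configuration for fast trainer unit tests on synthetic
## feature tensors (not real segments).
tinyModelConfig <- function(nClasses = 3, inputLength = 240) {
  modelConfig(nClasses = nClasses,
              convBlocks = list(c(4, 5, 4), c(8, 5, 4)),
              dropoutRate = 0, l2Lambda = 0, denseUnits = 16,
              inputRows = 5, inputLength = inputLength)
}

## Random, linearly separable feature tensors for trainer mechanics tests.
tinyTaskData <- function(n, nClasses = 3, inputLength = 240, seed = 1) {
  set.seed(seed)
  X <- array(rnorm(5 * inputLength * n), dim = c(5, inputLength, n))
  y <- paste0("class_", rep_len(seq_len(nClasses), n))
  for (i in seq_len(n)) {
    k <- as.integer(sub("class_", "", y[i]))
    X[k, , i] <- X[k, , i] + 3          # class-specific row offset
  }
  list(X = X, y = y)
}

## One trained 4-class classifier on a small synthetic set, cached for
## the whole test session.
.trainedModelCache <- new.env(parent = emptyenv())
trainedSynthModel <- function() {
  if (!is.null(.trainedModelCache$fit)) return(.trainedModelCache$fit)
  cfg <- fastSynthCfg()
  counts <- c(physiological = 60, pathological = 60, line_noise_60 = 60,
              artifact = 60)
  train <- genDataset(cfg, counts, seed = 2001)
  val <- genDataset(cfg, counts / 3, seed = 2002)
  model <- buildModel(modelConfig(nClasses = 4), seed = 2001)
  fit <- trainModel(model, train, val,
                    trainConfig(seed = 2001, maxEpochs = 10))
  .trainedModelCache$fit <- fit
  fit
}
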