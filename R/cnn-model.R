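## 1-D convolutional classifier: architecture, forward/backward pass.
## Convolution and pooling kernels live in src/conv1d.cpp; batch
## normalization, dense layers, softmax and the optimizer are plain R
## matrix code.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Create a model configuration
#'
#' Each conv block is `c(filters, kernel_length, pool_length)` and expands
#' to 1-D convolution (the 5 feature rows act as input channels) ->
#' batch normalization -> ReLU -> non-overlapping max pooling.  Blocks are
#' followed by dropout on the flattened features, one hidden dense layer
#' and a softmax output.  The defaults keep the network small enough to
#' train on a single CPU in minutes while reducing the 15,000 time steps
#' to a compact dense input.
#'
#' @param nClasses number of output classes (3 generalized / 4 specialized).
#' @param convBlocks list of `c(filters, kernel, pool)` triples.
#' @param dropoutRate dropout fraction on the flattened features, in \[0,1).
#' @param l2Lambda L2 penalty weight on convolution and dense weights.
#' @param denseUnits hidden dense layer width.
#' @param inputRows feature-matrix rows (raw + envelogram bands).
#' @param inputLength feature-matrix columns (samples per segment).
#' @return validated configuration list of class "modelConfig".
#' @export
modelConfig <- function(nClasses = 4,
                        convBlocks = list(c(8, 9, 6), c(16, 9, 6),
                                          c(32, 9, 6), c(32, 9, 6)),
                        dropoutRate = 0.5, l2Lambda = 1e-4,
                        denseUnits = 128, inputRows = 5,
                        inputLength = 15000) {
  if (nClasses < 2) stopValidation("nClasses must be >= 2")
  if (dropoutRate < 0 || dropoutRate >= 1)
    stopValidation("dropoutRate must be in [0, 1)")
  if (l2Lambda < 0) stopValidation("l2Lambda must be non-negative")
  for (b in convBlocks) {
    if (length(b) != 3 || any(b < 1))
      stopValidation("each conv block must be c(filters, kernel, pool) with values >= 1")
    if (b[2] %% 2 == 0)
      stopValidation("kernel lengths must be odd (centred same-padding)")
  }
  cfg <- list(nClasses = as.integer(nClasses),
              convBlocks = lapply(convBlocks, as.integer),
              dropoutRate = dropoutRate, l2Lambda = l2Lambda,
              denseUnits = as.integer(denseUnits),
              inputRows = as.integer(inputRows),
              inputLength = as.integer(inputLength))
  ## time length after each pooling stage; final flatten must be non-empty
  t <- cfg$inputLength
  for (b in cfg$convBlocks) {
    t <- t %/% b[3]
    if (t < 1) stopValidation("pooling reduces the time axis below 1 sample")
  }
  cfg$flatDim <- cfg$convBlocks[[length(cfg$convBlocks)]][1] * t
  class(cfg) <- "modelConfig"
  cfg
}

#' Build a seeded, randomly initialised classifier
#'
#' Weight initialisation is He-scaled normal, drawn from a local seeded
#' stream so identical `(cfg, seed)` give bit-identical models.
#'
#' @param cfg a [modelConfig()].
#' @param seed integer RNG seed for the initial weights.
#' @param classOrder optional class labels (length `nClasses`); defaults
#'   to placeholders until training assigns real labels.
#' @return a [CNNClassifier-class].
#' @export
buildModel <- function(cfg, seed = 1, classOrder = NULL) {
  if (!inherits(cfg, "modelConfig")) stopValidation("cfg must be a modelConfig")
  if (is.null(classOrder))
    classOrder <- paste0("class_", seq_len(cfg$nClasses))
  if (length(classOrder) != cfg$nClasses)
    stopValidation("classOrder length must equal nClasses")
  params <- list()
  bn <- list()
  withSeed(seed, {
    cin <- cfg$inputRows
    for (i in seq_along(cfg$convBlocks)) {
      b <- cfg$convBlocks[[i]]
      fanIn <- cin * b[2]
      params[[paste0("conv", i, "_W")]] <-
        matrix(stats::rnorm(b[1] * fanIn, sd = sqrt(2 / fanIn)),
               nrow = b[1], ncol = fanIn)
      params[[paste0("conv", i, "_b")]] <- numeric(b[1])
      params[[paste0("bn", i, "_gamma")]] <- rep(1, b[1])
      params[[paste0("bn", i, "_beta")]] <- numeric(b[1])
      bn[[paste0("bn", i, "_mean")]] <- numeric(b[1])
      bn[[paste0("bn", i, "_var")]] <- rep(1, b[1])
      cin <- b[1]
    }
    params$dense_W <- matrix(
      stats::rnorm(cfg$denseUnits * cfg$flatDim, sd = sqrt(2 / cfg$flatDim)),
      nrow = cfg$denseUnits, ncol = cfg$flatDim)
    params$dense_b <- numeric(cfg$denseUnits)
    params$out_W <- matrix(
      stats::rnorm(cfg$nClasses * cfg$denseUnits,
                   sd = sqrt(2 / cfg$denseUnits)),
      nrow = cfg$nClasses, ncol = cfg$denseUnits)
    params$out_b <- numeric(cfg$nClasses)
  })
  new("CNNClassifier", config = unclass(cfg), classOrder = classOrder,
      params = params, bnState = bn)
}

#' Number of trainable parameters
#'
#' @param model a [CNNClassifier-class].
#' @return integer parameter count.
#' @export
parameterCount <- function(model) {
  sum(vapply(model@params, length, integer(1)))
}

blocksMatrix <- function(cfg) {
  do.call(rbind, cfg$convBlocks)
}

bnMeanList <- function(model) {
  lapply(seq_along(model@config$convBlocks),
         function(i) model@bnState[[paste0("bn", i, "_mean")]])
}

bnVarList <- function(model) {
  lapply(seq_along(model@config$convBlocks),
         function(i) model@bnState[[paste0("bn", i, "_var")]])
}

checkInputDims <- function(model, X) {
  cfg <- model@config
  d <- dim(X)
  if (length(d) != 3 || d[1] != cfg$inputRows || d[2] != cfg$inputLength)
    stopShape("input must be ", cfg$inputRows, " x ", cfg$inputLength,
              " (x batch); got ", paste(d, collapse = " x "))
  invisible(d)
}

## Evaluation-mode class probabilities, K x B.
cnnPredict <- function(model, X) {
  checkInputDims(model, X)
  cnn_eval(model@params, bnMeanList(model), bnVarList(model), X,
           blocksMatrix(model@config))
}

## One fused training step (forward with batch statistics, cross-entropy,
## backward).  Returns loss (CE, without the L2 penalty), probabilities,
## gradients, and updated running batch-norm statistics.  The dropout
## mask is drawn here, from the caller's RNG stream, so training remains
## seeded on the R side.
cnnTrainStep <- function(model, X, targets, weights = NULL,
                         momentum = BN_MOMENTUM) {
  checkInputDims(model, X)
  cfg <- model@config
  B <- dim(X)[3]
  dropMask <- if (cfg$dropoutRate > 0)
    matrix(stats::rbinom(cfg$flatDim * B, 1, 1 - cfg$dropoutRate),
           nrow = cfg$flatDim) / (1 - cfg$dropoutRate)
  else matrix(numeric(0), 0, 0)
  if (is.null(weights)) weights <- numeric(0)
  st <- cnn_step(model@params, bnMeanList(model), bnVarList(model), X,
                 as.integer(targets), blocksMatrix(cfg), momentum,
                 dropMask, weights)
  ## L2 penalty on conv/dense weights: add the term and its gradient here
  wNames <- grep("(^conv[0-9]+_W$)|(^dense_W$)|(^out_W$)",
                 names(model@params), value = TRUE)
  l2 <- 0
  for (nm in wNames) {
    l2 <- l2 + sum(model@params[[nm]]^2)
    st$grads[[nm]] <- st$grads[[nm]] +
      2 * cfg$l2Lambda * model@params[[nm]]
  }
  st$loss <- st$loss + cfg$l2Lambda * l2
  bn <- model@bnState
  for (i in seq_along(cfg$convBlocks)) {
    bn[[paste0("bn", i, "_mean")]] <- st$bnMean[[i]]
    bn[[paste0("bn", i, "_var")]] <- st$bnVar[[i]]
  }
  st$bn <- bn
  st
}

coerceInput <- function(model, x) {
  cfg <- model@config
  if (is.matrix(x)) {
    if (!all(dim(x) == c(cfg$inputRows, cfg$inputLength)))
      stopShape("feature matrix must be ", cfg$inputRows, " x ",
                cfg$inputLength, "; got ", paste(dim(x), collapse = " x "))
    array(x, dim = c(dim(x), 1))
  } else if (is.array(x) && length(dim(x)) == 3) {
    x
  } else stopShape("input must be a feature matrix or a 3-D array")
}

#' Class probabilities for one or more feature matrices
#'
#' Deterministic evaluation-mode forward pass (dropout disabled, batch
#' normalization using running statistics).
#'
#' @param model a [CNNClassifier-class].
#' @param x a `rows x length` feature matrix, or a `rows x length x B`
#'   array for a batch.
#' @return for a single matrix, a named probability vector (names are the
#'   model's class order); for a batch, a `B x nClasses` matrix with one
#'   row per input, order preserved.  Probabilities sum to 1.
#' @export
predictProba <- function(model, x) {
  stopifnot(is(model, "CNNClassifier"))
  single <- is.matrix(x)
  X <- coerceInput(model, x)
  probs <- t(cnnPredict(model, X))
  colnames(probs) <- model@classOrder
  if (single) probs[1, ] else probs
}

#' Predicted class labels
#'
#' @param model a [CNNClassifier-class].
#' @param x feature matrix or batch array (see [predictProba()]).
#' @return character vector of predicted labels (argmax of the
#'   probability vector).
#' @export
predictClass <- function(model, x) {
  probs <- predictProba(model, x)
  if (is.null(dim(probs))) return(names(probs)[which.max(probs)])
  model@classOrder[max.col(probs, ties.method = "first")]
}
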