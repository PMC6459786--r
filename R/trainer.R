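## Dataset splitting, supervised training with validation-based early
## stopping, and transfer learning.

#' Create a training configuration
#'
#' Training minimises cross-entropy plus the model's L2 penalty with
#' adaptive-moment gradient descent (Adam).  After every epoch the
#' validation loss is evaluated in a forward-only pass (weights untouched);
#' training stops once validation loss has failed to improve for
#' `earlyStopPatience` consecutive epochs, or at `maxEpochs`, whichever
#' comes first, and the weights from the best validation epoch are
#' restored.
#'
#' @param maxEpochs epoch cap (default 25).
#' @param baseLearningRate Adam step size.
#' @param batchSize minibatch size.
#' @param earlyStopPatience epochs without validation improvement before
#'   stopping (default 1: stop on first decline).
#' @param earlyStopMinDelta minimum decrease in validation loss that
#'   counts as an improvement (standard min-delta refinement; avoids
#'   chasing sub-noise gains to the epoch cap).
#' @param transferLrFraction learning-rate fraction for transferred layers
#'   during [transferRetrain()] (default 0.10).
#' @param balanceClasses if TRUE, weight the loss by inverse class
#'   frequency (off by default).
#' @param seed RNG seed for shuffling, dropout and transfer re-initialisation.
#' @return configuration list of class "trainConfig".
#' @export
trainConfig <- function(maxEpochs = 25, baseLearningRate = 1e-3,
                        batchSize = 32, earlyStopPatience = 1,
                        earlyStopMinDelta = 1e-3,
                        transferLrFraction = 0.10, balanceClasses = FALSE,
                        seed = 1) {
  if (maxEpochs < 1) stopValidation("maxEpochs must be >= 1")
  if (baseLearningRate <= 0) stopValidation("baseLearningRate must be positive")
  if (batchSize < 1) stopValidation("batchSize must be >= 1")
  if (earlyStopPatience < 1) stopValidation("earlyStopPatience must be >= 1")
  if (earlyStopMinDelta < 0) stopValidation("earlyStopMinDelta must be >= 0")
  if (transferLrFraction <= 0 || transferLrFraction > 1)
    stopValidation("transferLrFraction must be in (0, 1]")
  structure(list(maxEpochs = as.integer(maxEpochs),
                 baseLearningRate = baseLearningRate,
                 batchSize = as.integer(batchSize),
                 earlyStopPatience = as.integer(earlyStopPatience),
                 earlyStopMinDelta = earlyStopMinDelta,
                 transferLrFraction = transferLrFraction,
                 balanceClasses = balanceClasses,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

subsetSegments <- function(set, idx) {
  new("SegmentSet", signals = set@signals[, idx, drop = FALSE],
      samplingRate = set@samplingRate, labels = set@labels[idx])
}

#' Stratified train/validation/test split
#'
#' Splits a labelled segment collection per class: validation and test
#' sizes are floored, the remainder goes to train, and assignment uses a
#' seeded shuffle.  Partitions are disjoint and cover the input.
#'
#' @param set a labelled [SegmentSet-class].
#' @param fractions named vector with entries among `train`, `validation`,
#'   `test`, summing to 1.
#' @param seed RNG seed for the shuffle.
#' @return list with elements `train`, `validation`, `test`
#'   ([SegmentSet-class] each).
#' @export
#' @examples
#' cfg <- synthConfig(seed = 3)
#' ds <- genDataset(cfg, c(physiological = 10, artifact = 10))
#' sp <- splitDataset(ds, c(train = 0.7, validation = 0.3), seed = 1)
#' nSegments(sp$train)  # 14
splitDataset <- function(set, fractions = c(train = 0.7, validation = 0.3),
                         seed = 1) {
  stopifnot(is(set, "SegmentSet"))
  allowed <- c("train", "validation", "test")
  if (is.null(names(fractions)) ||
      !all(names(fractions) %in% allowed))
    stopValidation("fractions must be named among train/validation/test")
  f <- c(train = 0, validation = 0, test = 0)
  f[names(fractions)] <- fractions
  if (abs(sum(f) - 1) > 1e-6)
    stopValidation("fractions must sum to 1 (got ", sum(f), ")")
  if (any(is.na(set@labels)))
    stopValidation("every segment must be labelled before splitting")
  idxTrain <- idxVal <- idxTest <- integer(0)
  withSeed(seed, {
    for (cls in unique(set@labels)) {
      ci <- which(set@labels == cls)
      n <- length(ci)
      nVal <- floor(f[["validation"]] * n)
      nTest <- floor(f[["test"]] * n)
      nTrain <- n - nVal - nTest
      for (part in allowed) {
        need <- switch(part, train = nTrain, validation = nVal, test = nTest)
        if (f[[part]] > 0 && need == 0)
          stopValidation("class '", cls, "' too small (", n,
                         " segments) for the requested ", part, " fraction")
      }
      ci <- ci[sample.int(n)]
      idxTrain <- c(idxTrain, ci[seq_len(nTrain)])
      if (nVal > 0) idxVal <- c(idxVal, ci[nTrain + seq_len(nVal)])
      if (nTest > 0) idxTest <- c(idxTest, ci[nTrain + nVal + seq_len(nTest)])
    }
  })
  list(train = subsetSegments(set, idxTrain),
       validation = subsetSegments(set, idxVal),
       test = subsetSegments(set, idxTest))
}

## Accepts a labelled SegmentSet or a precomputed list(features, labels)
## and returns list(X = rows x length x n array, y = labels).
asTrainingData <- function(data, what = "data") {
  if (is(data, "SegmentSet")) {
    if (nSegments(data) == 0) stopValidation("empty ", what, " set")
    if (any(is.na(data@labels)))
      stopValidation(what, " set contains unlabelled segments")
    list(X = featureTensor(data), y = data@labels)
  } else if (is.list(data) && !is.null(data$X) && !is.null(data$y)) {
    if (length(data$y) == 0) stopValidation("empty ", what, " set")
    if (dim(data$X)[3] != length(data$y))
      stopValidation(what, ": feature batch size must match labels")
    data
  } else stopValidation(what, " must be a SegmentSet or list(X, y)")
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, lrMult,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- lr * lrMult[[nm]] * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

## Mean cross-entropy of a model on a feature tensor, evaluation mode.
evalLoss <- function(model, X, targets, weights = NULL, batch = 128) {
  n <- dim(X)[3]
  tot <- 0
  wtot <- 0
  for (s in seq(1, n, by = batch)) {
    e <- min(s + batch - 1, n)
    probs <- cnnPredict(model, X[, , s:e, drop = FALSE])
    pr <- probs[cbind(targets[s:e], seq_len(e - s + 1))]
    w <- if (is.null(weights)) rep(1, e - s + 1) else weights[s:e]
    tot <- tot + sum(-w * log(pmax(pr, 1e-12)))
    wtot <- wtot + sum(w)
  }
  tot / wtot
}

## Canonical labels first, any other labels (e.g. bespoke tasks) after,
## alphabetically -- deterministic regardless of input order.
canonicalClassOrder <- function(labels) {
  u <- unique(labels)
  c(intersect(classLabels(), u), sort(setdiff(u, classLabels())))
}

trainModelCore <- function(model, train, validation, cfg, lrMult = NULL,
                           verbose = FALSE) {
  tr <- asTrainingData(train, "train")
  va <- asTrainingData(validation, "validation")
  classOrd <- model@classOrder
  if (all(grepl("^class_[0-9]+$", classOrd))) {
    classOrd <- canonicalClassOrder(c(tr$y, va$y))
    if (length(classOrd) != model@config$nClasses)
      stopValidation("data contain ", length(classOrd),
                     " classes but the model has ", model@config$nClasses,
                     " outputs")
    model@classOrder <- classOrd
  }
  yTr <- match(tr$y, classOrd)
  yVa <- match(va$y, classOrd)
  if (any(is.na(yTr)) || any(is.na(yVa)))
    stopValidation("labels outside the model's class order")
  wTr <- NULL
  if (isTRUE(cfg$balanceClasses)) {
    freq <- table(factor(tr$y, levels = classOrd))
    wcls <- as.numeric(sum(freq) / (length(freq) * pmax(freq, 1)))
    wTr <- wcls[yTr]
  }
  if (is.null(lrMult)) {
    lrMult <- as.list(rep(1, length(model@params)))
    names(lrMult) <- names(model@params)
  }
  nTr <- dim(tr$X)[3]
  state <- adamInit(model@params)
  best <- list(loss = Inf, params = model@params, bn = model@bnState,
               epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  badEpochs <- 0L
  withSeed(cfg$seed, {
    for (epoch in seq_len(cfg$maxEpochs)) {
      ord <- sample.int(nTr)
      epochLoss <- 0
      nb <- 0L
      for (s in seq(1, nTr, by = cfg$batchSize)) {
        e <- min(s + cfg$batchSize - 1, nTr)
        bi <- ord[s:e]
        st <- cnnTrainStep(model, tr$X[, , bi, drop = FALSE], yTr[bi],
                           weights = if (is.null(wTr)) NULL else wTr[bi])
        if (!is.finite(st$loss))
          stop(errorCondition(
            paste0("non-finite training loss at epoch ", epoch),
            class = c("ieegnoise_numerical_error", "error")))
        model@bnState <- st$bn
        upd <- adamStep(model@params, st$grads, state,
                        cfg$baseLearningRate, lrMult)
        model@params <- upd$params
        state <- upd$state
        epochLoss <- epochLoss + st$loss
        nb <- nb + 1L
      }
      valLoss <- evalLoss(model, va$X, yVa)
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = epochLoss / nb,
                                  val_loss = valLoss))
      if (verbose)
        message(sprintf("epoch %d: train %.4f  val %.4f", epoch,
                        epochLoss / nb, valLoss))
      if (valLoss < best$loss - cfg$earlyStopMinDelta) {
        best <- list(loss = valLoss, params = model@params,
                     bn = model@bnState, epoch = epoch)
        badEpochs <- 0L
      } else {
        badEpochs <- badEpochs + 1L
        if (badEpochs >= cfg$earlyStopPatience) break
      }
    }
  })
  model@params <- best$params
  model@bnState <- best$bn
  attr(history, "best_epoch") <- best$epoch
  attr(history, "lr_multipliers") <- unlist(lrMult)
  list(model = model, history = history)
}

#' Train a classifier
#'
#' Minimises cross-entropy plus the L2 penalty on the training set;
#' validation loss is evaluated after every epoch in a forward-only pass
#' and drives early stopping (see [trainConfig()]).  The returned model
#' carries the weights of the best validation epoch.
#'
#' @param model a [CNNClassifier-class] (untrained or pre-trained).
#' @param train labelled [SegmentSet-class] (or `list(X, y)` of a
#'   precomputed feature tensor and labels).
#' @param validation held-out labelled data, same format, disjoint from
#'   `train`.
#' @param cfg a [trainConfig()].
#' @param verbose print per-epoch losses.
#' @return list with `model` (best-epoch weights) and `history`
#'   (data.frame of per-epoch train/validation loss; attributes
#'   `best_epoch` and `lr_multipliers`).
#' @export
trainModel <- function(model, train, validation, cfg = trainConfig(),
                       verbose = FALSE) {
  stopifnot(is(model, "CNNClassifier"), inherits(cfg, "trainConfig"))
  trainModelCore(model, train, validation, cfg, lrMult = NULL,
                 verbose = verbose)
}

#' Adapt a trained model to a new site/class set by transfer learning
#'
#' Replaces the final softmax layer with a freshly initialised layer
#' (normal, mean 0, sd 0.01) sized to the new class set, then retrains on
#' the new site's data with the transferred layers' learning rate set to
#' `transferLrFraction` (default 10%) of the final layer's rate.
#'
#' @param gmModel a trained [CNNClassifier-class] (e.g. a generalized
#'   3-class model).
#' @param train new-site labelled [SegmentSet-class] (or `list(X, y)`).
#' @param validation new-site validation data, same format.
#' @param newClassOrder class labels of the new task (may differ in number
#'   from the source model, e.g. 3 -> 4 when adding a 60 Hz line class).
#' @param cfg a [trainConfig()].
#' @param verbose print per-epoch losses.
#' @return list with `model` and `history` as in [trainModel()].
#' @export
transferRetrain <- function(gmModel, train, validation, newClassOrder,
                            cfg = trainConfig(), verbose = FALSE) {
  stopifnot(is(gmModel, "CNNClassifier"), inherits(cfg, "trainConfig"))
  if (!is.character(newClassOrder) || length(newClassOrder) < 2)
    stopValidation("newClassOrder must name at least 2 classes")
  tr <- asTrainingData(train, "train")
  if (dim(tr$X)[1] != gmModel@config$inputRows ||
      dim(tr$X)[2] != gmModel@config$inputLength)
    stopVersion("feature dimensionality ",
                paste(dim(tr$X)[1:2], collapse = " x "),
                " incompatible with the source model (",
                gmModel@config$inputRows, " x ",
                gmModel@config$inputLength, ")")
  model <- gmModel
  k <- length(newClassOrder)
  model@config$nClasses <- as.integer(k)
  withSeed(cfg$seed, {
    model@params$out_W <- matrix(
      stats::rnorm(k * model@config$denseUnits, sd = 0.01),
      nrow = k, ncol = model@config$denseUnits)
    model@params$out_b <- numeric(k)
  })
  model@classOrder <- newClassOrder
  lrMult <- as.list(rep(cfg$transferLrFraction, length(model@params)))
  names(lrMult) <- names(model@params)
  lrMult$out_W <- 1
  lrMult$out_b <- 1
  trainModelCore(model, tr, validation, cfg, lrMult = lrMult,
                 verbose = verbose)
}

#' Evaluate a classifier on labelled segments
#'
#' @param model a trained [CNNClassifier-class].
#' @param test labelled [SegmentSet-class] or `list(X, y)`.
#' @return a [ConfusionMatrix-class] (gold rows x predicted columns) over
#'   the model's class order.
#' @export
evaluateModel <- function(model, test) {
  te <- asTrainingData(test, "test")
  n <- dim(te$X)[3]
  pred <- character(n)
  for (s in seq(1, n, by = 128)) {
    e <- min(s + 127, n)
    probs <- predictProba(model, te$X[, , s:e, drop = FALSE])
    pred[s:e] <- model@classOrder[max.col(probs, ties.method = "first")]
  }
  confusionMatrix(te$y, pred, classOrder = model@classOrder)
}
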