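test_that("stratified splits honour per-class fractions with remainder to train", {
  cfg <- synthConfig()
  ds <- genDataset(cfg, c(physiological = 100), seed = 1)
  sp <- splitDataset(ds, c(train = 0.7, validation = 0.3), seed = 2)
  expect_equal(nSegments(sp$train), 70)
  expect_equal(nSegments(sp$validation), 30)
  expect_equal(nSegments(sp$test), 0)
  sp2 <- splitDataset(ds, c(train = 0.04, validation = 0.04, test = 0.92),
                      seed = 2)
  expect_equal(nSegments(sp2$train), 4)
  expect_equal(nSegments(sp2$validation), 4)
  expect_equal(nSegments(sp2$test), 92)
  expect_error(splitDataset(ds, c(train = 0.6, validation = 0.3)),
               class = "ieegnoise_validation_error")
})

test_that("splits are disjoint, covering, stratified and seeded", {
  cfg <- synthConfig()
  ds <- genDataset(cfg, c(physiological = 20, pathological = 10,
                          artifact = 15), seed = 3)
  ## tag segments via their first sample to track identity
  key <- function(set) round(segmentSignals(set)[1, ], 9)
  sp <- splitDataset(ds, c(train = 0.6, validation = 0.2, test = 0.2),
                     seed = 5)
  keys <- c(key(sp$train), key(sp$validation), key(sp$test))
  expect_equal(sort(keys), sort(key(ds)))
  expect_equal(anyDuplicated(keys), anyDuplicated(key(ds)))
  ## per-class proportions in every part
  tabTrain <- table(segmentLabels(sp$train))
  expect_equal(as.numeric(tabTrain[c("physiological", "pathological",
                                     "artifact")]), c(12, 6, 9))
  ## seeded reproducibility
  spB <- splitDataset(ds, c(train = 0.6, validation = 0.2, test = 0.2),
                      seed = 5)
  expect_identical(segmentSignals(sp$train), segmentSignals(spB$train))
  ## too-small class
  tiny <- genDataset(cfg, c(physiological = 3), seed = 4)
  expect_error(splitDataset(tiny, c(train = 0.7, validation = 0.2,
                                    test = 0.1)),
               class = "ieegnoise_validation_error")
})

test_that("training stops when validation stalls and restores the best epoch", {
  ## rig a run whose validation never improves (the improvement bar is
  ## unreachably high) with frozen weights: patience 1 stops at epoch 2
  ## and returns the epoch-1 weights
  td <- tinyTaskData(30, seed = 21)
  vd <- tinyTaskData(12, seed = 22)
  m <- buildModel(tinyModelConfig(), seed = 1,
                  classOrder = c("class_1", "class_2", "class_3"))
  fit <- trainModel(m, td, vd,
                    trainConfig(maxEpochs = 25, baseLearningRate = 1e-12,
                                earlyStopPatience = 1,
                                earlyStopMinDelta = 100, seed = 1))
  expect_equal(nrow(fit$history), 2)
  expect_equal(attr(fit$history, "best_epoch"), 1)
  ## weights of the returned model are the (frozen) originals
  expect_equal(fit$model@params$out_W, m@params$out_W, tolerance = 1e-9)
  ## patience 2 with the same bar runs one epoch longer
  fit2 <- trainModel(m, td, vd,
                     trainConfig(maxEpochs = 25, baseLearningRate = 1e-12,
                                 earlyStopPatience = 2,
                                 earlyStopMinDelta = 100, seed = 1))
  expect_equal(nrow(fit2$history), 3)
})

test_that("training loss decreases on an overfit smoke test and is reproducible", {
  td <- tinyTaskData(10, seed = 31)
  m <- buildModel(tinyModelConfig(), seed = 2,
                  classOrder = c("class_1", "class_2", "class_3"))
  cfg <- trainConfig(maxEpochs = 5, earlyStopPatience = 5,
                     earlyStopMinDelta = 0, seed = 3)
  fit <- trainModel(m, td, td, cfg)
  expect_equal(nrow(fit$history), 5)
  expect_true(all(diff(fit$history$train_loss) <= 1e-3))
  ## end-to-end seeded reproducibility
  fit2 <- trainModel(m, td, td, cfg)
  expect_equal(fit$history$val_loss, fit2$history$val_loss,
               tolerance = 1e-6)
  ## evaluation leaves weights untouched
  before <- fit$model@params
  invisible(evaluateModel(fit$model, td))
  expect_identical(fit$model@params, before)
  ## empty training set errors
  expect_error(trainModel(m, list(X = array(0, c(5, 240, 0)),
                                  y = character(0)), td, cfg),
               class = "ieegnoise_validation_error")
})

test_that("transfer learning resets the softmax layer and scales transferred learning rates", {
  td3 <- tinyTaskData(30, nClasses = 3, seed = 41)
  gm <- trainModel(buildModel(tinyModelConfig(3), seed = 4,
                              classOrder = paste0("class_", 1:3)),
                   td3, td3, trainConfig(maxEpochs = 2, seed = 4))$model
  td4 <- tinyTaskData(40, nClasses = 4, seed = 42)
  vd4 <- tinyTaskData(16, nClasses = 4, seed = 43)
  fit <- transferRetrain(gm, td4, vd4, paste0("class_", 1:4),
                         trainConfig(maxEpochs = 2, seed = 5))
  ## 3 -> 4 classes
  expect_length(classOrder(fit$model), 4)
  expect_length(predictProba(fit$model, td4$X[, , 1]), 4)
  ## transferred groups learn at 10% of the final layer's rate
  lrm <- attr(fit$history, "lr_multipliers")
  expect_equal(unname(lrm["out_W"]), 1)
  expect_equal(unname(lrm["out_b"]), 1)
  expect_true(all(lrm[setdiff(names(lrm), c("out_W", "out_b"))] == 0.10))
  ## the final layer was reset to a fresh small-variance normal state:
  ## freeze training (vanishing lr) and inspect the resulting layer
  frozen <- transferRetrain(gm, td4, vd4, paste0("class_", 1:4),
                            trainConfig(maxEpochs = 1,
                                        baseLearningRate = 1e-12,
                                        seed = 5))$model
  expect_equal(dim(frozen@params$out_W), c(4, 16))
  expect_lt(sd(frozen@params$out_W), 0.05)        # fresh N(0, 0.01) draw
  x <- td3$X[, , 1]
  p0 <- predictProba(gm, x)
  pf <- predictProba(frozen, x)
  expect_false(isTRUE(all.equal(unname(p0), unname(pf[1:3]),
                                tolerance = 1e-4)))
  ## feature-dimension mismatch is a version error
  bad <- tinyTaskData(8, nClasses = 4, inputLength = 120, seed = 44)
  expect_error(transferRetrain(gm, bad, bad, paste0("class_", 1:4),
                               trainConfig(seed = 1)),
               class = "ieegnoise_version_error")
})
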