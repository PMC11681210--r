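test_that("random splits are exhaustive, disjoint and size-exact", {
  cfg <- trainConfig(seed = 7)
  sp <- splitDataset(100, cfg)
  expect_length(sp$train, 80)
  expect_length(sp$val, 10)
  expect_length(sp$test, 10)
  all_idx <- sort(c(sp$train, sp$val, sp$test))
  expect_identical(all_idx, 1:100)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_identical(splitDataset(100, cfg), sp)
  # rounding preserves the total for awkward sizes
  sp17 <- splitDataset(17, cfg)
  expect_equal(sum(lengths(sp17)), 17)
  expect_error(splitDataset(5, cfg), class = "ts_validation_error")
})

test_that("training configuration validates the protocol bounds", {
  expect_error(trainConfig(splitFractions = c(0.5, 0.5, 0.2)),
               class = "ts_parameter_error")
  expect_error(trainConfig(patience = 60, epochs = 50),
               class = "ts_parameter_error")
  cfg <- trainConfig()
  expect_equal(cfg@splitFractions, c(0.8, 0.1, 0.1))
  expect_equal(cfg@learningRate, 0.001)
  expect_equal(cfg@batchSize, 16L)
  expect_equal(cfg@epochs, 50L)
  expect_equal(cfg@patience, 10L)
  expect_equal(cfg@dropoutRate, 0.25)
})

test_that("early stopping halts at patience and restores the best weights", {
  samples <- tiny_training_set(12)
  net <- thrombusNet(modelConfig(depth = 2, baseFilters = 4,
                                 inputSize = 32), seed = 8)
  cfg <- trainConfig(epochs = 10L, batchSize = 4L, patience = 2L,
                     seed = 8L)
  snaps <- list()
  riggedLoss <- c(1.0, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0, 1.0, 1.0, 1.0)
  fit <- trainModel(net, samples, cfg,
                    splits = list(train = 1:10, val = 11:12,
                                  test = integer(0)),
                    .valLoss = function(epoch, model) {
                      snaps[[epoch]] <<- model@params$head.w$value
                      riggedLoss[epoch]
                    })
  # best at epoch 2; patience 2 exhausted after epochs 3 and 4
  expect_identical(bestEpoch(fit$log), 2L)
  expect_true(fit$log@stoppedEarly)
  expect_equal(nrow(trainHistory(fit$log)), 4)
  expect_identical(fit$model@params$head.w$value, snaps[[2]])
  expect_false(identical(snaps[[2]], snaps[[4]]))
  # log invariant: best epoch has the minimal recorded validation loss
  h <- trainHistory(fit$log)
  expect_equal(which.min(h$valLoss), bestEpoch(fit$log))
})

test_that("a short seeded run is reproducible and evaluable", {
  samples <- tiny_training_set(12)
  cfg <- trainConfig(epochs = 2L, batchSize = 4L, patience = 2L, seed = 9L)
  net1 <- thrombusNet(modelConfig(depth = 2, baseFilters = 4,
                                  inputSize = 32), seed = 9)
  fit1 <- trainModel(net1, samples, cfg)
  net2 <- thrombusNet(modelConfig(depth = 2, baseFilters = 4,
                                  inputSize = 32), seed = 9)
  fit2 <- trainModel(net2, samples, cfg)
  expect_equal(trainHistory(fit1$log)$trainLoss,
               trainHistory(fit2$log)$trainLoss, tolerance = 1e-12)
  expect_equal(trainHistory(fit1$log)$valLoss,
               trainHistory(fit2$log)$valLoss, tolerance = 1e-12)
  expect_true(all(is.finite(trainHistory(fit1$log)$trainLoss)))
  # evaluation is side-effect free and bounded
  sp <- splitDataset(samples, cfg)
  r1 <- evaluateSplit(fit1$model, samples[sp$val])
  r2 <- evaluateSplit(fit1$model, samples[sp$val])
  expect_identical(metricsAsDataFrame(r1), metricsAsDataFrame(r2))
  df <- metricsAsDataFrame(r1)
  ratios <- unlist(df[1, 1:6])
  expect_true(all(is.na(ratios) | (ratios >= 0 & ratios <= 1)))
  expect_gte(df$loss, 0)
  expect_error(evaluateSplit(fit1$model, list()),
               class = "ts_validation_error")
})

test_that("the training log serializes to tsv and json", {
  samples <- tiny_training_set(12)
  cfg <- trainConfig(epochs = 1L, batchSize = 4L, patience = 1L, seed = 10L)
  net <- thrombusNet(modelConfig(depth = 2, baseFilters = 4,
                                 inputSize = 32), seed = 10)
  fit <- trainModel(net, samples, cfg)
  paths <- writeTrainLog(fit$log, file.path(tempdir(), "tl"))
  expect_true(all(file.exists(paths)))
  tab <- read.delim(paths[1])
  expect_equal(nrow(tab), 1)
  expect_true(all(c("trainLoss", "valLoss", "valDice") %in% names(tab)))
})
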