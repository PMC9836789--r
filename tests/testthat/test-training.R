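trainToy <- function(n = 8L, size = 32L, seedBase = 300L) {
  s <- smallImageSet(n, classes = c("Mel", "Nv"), size = size,
                     seedBase = seedBase)
  list(x = batchFromImages(s$images), y = s$labels, boxes = s$boxes,
       images = s$images)
}

test_that("zero epochs returns the initial weights and an empty log", {
  m <- tinyClassifier(seed = 21, cache = FALSE)
  w0 <- DermaFusion:::netGetWeights(m)
  d <- trainToy(4)
  fit <- trainModel(m, d$x, d$y, cfg = trainConfig(maxEpochs = 0L))
  expect_identical(nrow(fit$log), 0L)
  expect_identical(DermaFusion:::netGetWeights(fit$model), w0)
  expect_identical(fit$stopReason, "max_epochs")
})

test_that("training is reproducible under a fixed seed", {
  d <- trainToy(6)
  run <- function() {
    m <- tinyClassifier(seed = 5, cache = FALSE)
    trainModel(m, d$x, d$y, cfg = trainConfig(batchSize = 3L, maxEpochs = 4L,
                                              initialLr = 1e-3, seed = 2))$log
  }
  expect_identical(run(), run())
})

test_that("a small model memorises a tiny two-class set", {
  d <- trainToy(8)
  m <- tinyClassifier(nClasses = 7L, seed = 31, cache = FALSE)
  fit <- trainModel(m, d$x, d$y,
                    cfg = trainConfig(batchSize = 4L, initialLr = 3e-3,
                                      maxEpochs = 200L,
                                      earlyStopPatience = Inf,
                                      lrPatience = 1e9, seed = 4,
                                      stopAtTrainAccuracy = 1))
  expect_identical(fit$stopReason, "train_accuracy_target")
  expect_lte(nrow(fit$log), 200L)
  expect_identical(tail(fit$log$train_acc, 1), 1)
})

test_that("plateau decay multiplies the rate by exactly 0.1 and stops at patience", {
  d <- trainToy(4)
  m <- tinyClassifier(seed = 41, cache = FALSE)
  # a vanishing learning rate cannot improve the loss: pure plateau regime
  cfg <- trainConfig(batchSize = 4L, initialLr = 1e-12, lrPatience = 2,
                     earlyStopPatience = 5, maxEpochs = 28L, seed = 3)
  fit <- trainModel(m, d$x, d$y, d$x, d$y, cfg)
  lr <- fit$log$lr
  expect_true(all(diff(lr) <= 0))                       # non-increasing
  drops <- lr[-1][diff(lr) < 0] / lr[-length(lr)][diff(lr) < 0]
  expect_true(all(abs(drops - 0.1) < 1e-12))            # exactly x0.1
  expect_identical(fit$stopReason, "early_stop")
  # first epoch sets the best; then exactly patience non-improving epochs
  expect_identical(nrow(fit$log), 1L + 5L)
})

test_that("best-validation weights are restored on return", {
  set.seed(10)
  d <- trainToy(8)
  v <- trainToy(4, seedBase = 900L)
  m <- tinyClassifier(seed = 51, cache = FALSE)
  cfg <- trainConfig(batchSize = 4L, initialLr = 3e-3, maxEpochs = 10L,
                     earlyStopPatience = Inf, lrPatience = 1e9, seed = 6)
  fit <- trainModel(m, d$x, d$y, v$x, v$y, cfg)
  ev <- DermaFusion:::evalOnSet(fit$model, v$x, v$y)
  expect_equal(ev$loss, min(fit$log$val_loss), tolerance = 1e-6)
})

test_that("invalid training inputs are rejected", {
  m <- tinyClassifier(cache = FALSE)
  expect_error(trainModel(m, array(0, c(32L, 32L, 3L, 0L)), integer(0)),
               "empty training set")
  d <- trainToy(4)
  expect_error(trainModel(m, d$x, d$y[1:2]), "label mismatch")
})

test_that("ablation grids produce one fully populated row per variant", {
  d <- trainToy(6, size = 32L)
  data <- list(trainX = d$x, trainY = d$y, testX = d$x, testY = d$y)
  grid <- data.frame(variant = c("vgg16", "vgg16"), gemP = c(1, 4),
                     mrf = c(TRUE, TRUE))
  cfg <- trainConfig(batchSize = 3L, initialLr = 1e-3, maxEpochs = 1L,
                     earlyStopPatience = Inf, lrPatience = 1e9, seed = 8)
  tab <- runAblation(grid, data, cfg, inputSize = 32L)
  expect_identical(nrow(tab), 2L)
  expect_true(all(is.finite(tab$precision)))
  expect_true(all(is.finite(tab$recall)))
  expect_true(all(is.finite(tab$f1)))
  expect_true(all(is.finite(tab$accuracy)))
  expect_identical(tab$gem_p, c(1, 4))
  expect_error(runAblation(grid[0, ], data, cfg), "empty")
})
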