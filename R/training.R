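# Training loop: Adam on softmax cross-entropy, reduce-on-plateau learning
# rate (factor 0.1), early stopping on the validation loss, best-weights
# restoration. Fully seeded: shuffling and initialisation are deterministic,
# and the native kernels are deterministic on a fixed thread count.

labelsToIndex <- function(y) {
  if (is.character(y) || is.factor(y)) classIndex(as.character(y))
  else as.integer(y)
}

asBatchArray <- function(x) {
  if (is.list(x)) batchFromImages(x) else x
}

evalOnSet <- function(model, x, y, batchSize = 16L) {
  n <- dim(x)[4]
  loss <- 0; correct <- 0
  probs <- NULL
  for (start in seq(1L, n, by = batchSize)) {
    sel <- start:min(start + batchSize - 1L, n)
    ev <- eng_eval(model@ptr, x[, , , sel, drop = FALSE], y[sel])
    loss <- loss + ev$loss * length(sel)
    correct <- correct + sum(max.col(ev$probs) - 1L == y[sel])
    probs <- rbind(probs, ev$probs)
  }
  list(loss = loss / n, acc = correct / n, probs = probs)
}

#' Train a lesion classifier
#'
#' Minimises softmax cross-entropy with Adam. The learning rate starts at
#' `cfg@initialLr` and is multiplied by `cfg@lrDecayFactor` whenever the
#' monitored loss fails to improve for `cfg@lrPatience` epochs; training
#' stops at `cfg@maxEpochs` or after `cfg@earlyStopPatience` non-improving
#' epochs. When a validation set is supplied the validation loss is
#' monitored and the best-validation weights (including batch-norm running
#' statistics) are restored on return; without one the training loss is
#' monitored and the final weights are kept (the overfitting regime).
#'
#' @param model a classifier [LesionNet-class] (modified in place).
#' @param trainX images (list or H x W x 3 x N array in `[0,1]`).
#' @param trainY labels: 0-based indices, class names, or a factor.
#' @param valX,valY optional validation set.
#' @param cfg a [TrainConfig-class]; see [trainConfig()].
#' @return list with `model`, `log` (data.frame: epoch, train_loss,
#'   train_acc, val_loss, val_acc, lr) and `stopReason`.
#' @export
trainModel <- function(model, trainX, trainY, valX = NULL, valY = NULL,
                       cfg = trainConfig()) {
  validObject(cfg)
  x <- asBatchArray(trainX)
  y <- labelsToIndex(trainY)
  n <- dim(x)[4]
  if (n == 0L || length(y) != n) stop("empty training set or label mismatch")
  hasVal <- !is.null(valX)
  if (hasVal) { vx <- asBatchArray(valX); vy <- labelsToIndex(valY) }

  lr <- cfg@initialLr
  best <- Inf; bestW <- NULL
  stopWait <- 0; lrWait <- 0
  rows <- list()
  stopReason <- "max_epochs"

  for (epoch in seq_len(cfg@maxEpochs)) {
    ord <- withSeed(cfg@seed + epoch, sample.int(n))
    eLoss <- 0; eCorrect <- 0
    for (start in seq(1L, n, by = cfg@batchSize)) {
      sel <- ord[start:min(start + cfg@batchSize - 1L, n)]
      st <- eng_train_step(model@ptr, x[, , , sel, drop = FALSE], y[sel], lr)
      eLoss <- eLoss + st$loss * length(sel)
      eCorrect <- eCorrect + sum(max.col(st$probs) - 1L == y[sel])
    }
    trainLoss <- eLoss / n; trainAcc <- eCorrect / n
    # batch-norm calibration: evaluation-mode statistics are recomputed as
    # the average over up to four training batches (momentum 1/b accumulates
    # the exact mean), so validation metrics and any later evaluation-mode
    # use (Grad-CAM, the service) see faithful activations
    b <- 0L
    for (start in seq(1L, min(n, 4L * cfg@batchSize), by = cfg@batchSize)) {
      b <- b + 1L
      sel <- ord[start:min(start + cfg@batchSize - 1L, n)]
      eng_calibrate_bn(model@ptr, x[, , , sel, drop = FALSE], 1 / b)
    }
    if (hasVal) {
      ev <- evalOnSet(model, vx, vy, cfg@batchSize)
      valLoss <- ev$loss; valAcc <- ev$acc
    } else {
      valLoss <- NA_real_; valAcc <- NA_real_
    }
    rows[[epoch]] <- data.frame(epoch = epoch, train_loss = trainLoss,
                                train_acc = trainAcc, val_loss = valLoss,
                                val_acc = valAcc, lr = lr)
    monitored <- if (hasVal) valLoss else trainLoss
    if (monitored < best - 1e-8) {
      best <- monitored
      stopWait <- 0; lrWait <- 0
      if (hasVal) bestW <- eng_get_weights(model@ptr)
    } else {
      stopWait <- stopWait + 1; lrWait <- lrWait + 1
      if (lrWait >= cfg@lrPatience) { lr <- lr * cfg@lrDecayFactor; lrWait <- 0 }
    }
    if (!is.na(cfg@stopAtTrainAccuracy) &&
        trainAcc >= cfg@stopAtTrainAccuracy) {
      stopReason <- "train_accuracy_target"
      break
    }
    if (is.finite(cfg@earlyStopPatience) && stopWait >= cfg@earlyStopPatience) {
      stopReason <- "early_stop"
      break
    }
  }
  if (hasVal && !is.null(bestW)) eng_set_weights(model@ptr, bestW)
  log <- if (length(rows)) do.call(rbind, rows) else
    data.frame(epoch = integer(), train_loss = numeric(),
               train_acc = numeric(), val_loss = numeric(),
               val_acc = numeric(), lr = numeric())
  list(model = model, log = log, stopReason = stopReason)
}

#' Predicted class indices for a batch
#'
#' @param model a classifier [LesionNet-class].
#' @param x images (list or batch array).
#' @return integer vector of 0-based class indices.
#' @export
predictClasses <- function(model, x) {
  max.col(netProbs(model, asBatchArray(x))) - 1L
}

#' Run an architecture / GeM-exponent ablation grid
#'
#' Trains every variant of the grid on the same seeded data and reports the
#' four headline test metrics per variant, mirroring the published ablation
#' tables.
#'
#' @param grid data.frame with columns `variant` (see [assembleModel()]),
#'   `gemP` and `mrf`.
#' @param data list with `trainX`, `trainY`, `testX`, `testY` and optional
#'   `valX`, `valY`.
#' @param cfg a [TrainConfig-class].
#' @param inputSize model input side length.
#' @return data.frame: variant, gem_p, mrf, precision, recall, f1, accuracy
#'   (macro metrics and overall accuracy, percent).
#' @export
runAblation <- function(grid, data, cfg = trainConfig(), inputSize = 64L) {
  if (nrow(grid) == 0L) stop("empty ablation grid")
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    v <- as.character(grid$variant[i] %||% "two_stream")
    p <- grid$gemP[i] %||% 4
    m <- grid$mrf[i] %||% TRUE
    model <- assembleModel(v, inputSize = inputSize, gemP = p, mrf = m,
                           seed = cfg@seed)
    fit <- trainModel(model, data$trainX, data$trainY, data$valX, data$valY, cfg)
    yTest <- labelsToIndex(data$testY)
    pred <- predictClasses(fit$model, data$testX)
    cm <- lesionConfusionMatrix(yTest, pred)
    met <- classMetrics(cm)
    macro <- met[met$class == "macro", ]
    out[[i]] <- data.frame(variant = v, gem_p = p, mrf = m,
                           precision = macro$precision, recall = macro$recall,
                           f1 = macro$f1, accuracy = macro$accuracy)
  }
  do.call(rbind, out)
}
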