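# Multiclass evaluation: confusion matrix, one-vs-rest precision / recall /
# F1 / accuracy on the percent scale with macro (unweighted class mean) and
# micro (pooled counts) averages, one-vs-rest ROC/AUC, Grad-CAM maps, and
# report rendering / deltas.

#' Confusion matrix over the seven lesion classes
#'
#' @param yTrue,yPred equal-length vectors of 0-based class indices, class
#'   names, or factors.
#' @param nClasses number of classes (default 7).
#' @return integer `nClasses` x `nClasses` matrix; rows are actual classes,
#'   columns predicted, labelled by class name.
#' @export
#' @examples
#' lesionConfusionMatrix(c(4, 4), c(5, 5))["Mel", "Nv"]
lesionConfusionMatrix <- function(yTrue, yPred, nClasses = 7L) {
  yTrue <- labelsToIndex(yTrue); yPred <- labelsToIndex(yPred)
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  if (length(yTrue) && (min(c(yTrue, yPred)) < 0L ||
                        max(c(yTrue, yPred)) >= nClasses))
    stop("labels must lie in 0..", nClasses - 1L)
  lev <- 0:(nClasses - 1L)
  cm <- table(factor(yTrue, levels = lev), factor(yPred, levels = lev))
  cm <- unclass(cm)
  dimnames(cm) <- list(actual = lesionClasses()[lev + 1L],
                       predicted = lesionClasses()[lev + 1L])
  cm
}

# one-vs-rest counts per class
ovrCounts <- function(cm) {
  n <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- n - tp - fp - fn
  data.frame(class = rownames(cm), tp = tp, fp = fp, fn = fn, tn = tn,
             support = rowSums(cm), row.names = NULL,
             stringsAsFactors = FALSE)
}

safeDiv <- function(num, den) ifelse(den == 0, 0, num / den)

#' F1 score from precision and recall
#'
#' The harmonic mean `2 P R / (P + R)`, on whatever scale `precision` and
#' `recall` share (the package reports percent).
#'
#' @param precision,recall numeric (vectorised).
#' @return numeric.
#' @export
#' @examples
#' round(f1Score(83.53, 95.04), 2)
f1Score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Per-class and averaged classification metrics
#'
#' One-vs-rest precision, recall, F1 and accuracy per class (percent scale),
#' with a `macro` row (unweighted means over classes, accuracy = overall
#' accuracy) and a `micro` row (metrics of the pooled one-vs-rest counts).
#' For single-label multiclass data micro-precision = micro-recall =
#' micro-F1 = overall accuracy. Zero-denominator divisions yield 0 and set
#' the `flagged` column.
#'
#' @param cm confusion matrix from [lesionConfusionMatrix()].
#' @return data.frame with columns `class`, `support`, `precision`,
#'   `recall`, `f1`, `accuracy`, `flagged`.
#' @export
classMetrics <- function(cm) {
  if (!is.matrix(cm) || sum(cm) == 0) stop("empty confusion matrix")
  ct <- ovrCounts(cm)
  n <- sum(cm)
  prec <- 100 * safeDiv(ct$tp, ct$tp + ct$fp)
  rec <- 100 * safeDiv(ct$tp, ct$tp + ct$fn)
  f1 <- f1Score(prec, rec)
  acc <- 100 * (ct$tp + ct$tn) / n
  flagged <- (ct$tp + ct$fp == 0) | (ct$tp + ct$fn == 0)
  overall <- 100 * sum(diag(cm)) / n
  per <- data.frame(class = ct$class, support = ct$support, precision = prec,
                    recall = rec, f1 = f1, accuracy = acc, flagged = flagged,
                    stringsAsFactors = FALSE)
  macro <- data.frame(class = "macro", support = n,
                      precision = mean(prec), recall = mean(rec),
                      f1 = mean(f1), accuracy = overall, flagged = any(flagged))
  tp <- sum(ct$tp); fp <- sum(ct$fp); fn <- sum(ct$fn)
  mp <- 100 * safeDiv(tp, tp + fp); mr <- 100 * safeDiv(tp, tp + fn)
  micro <- data.frame(class = "micro", support = n, precision = mp,
                      recall = mr, f1 = f1Score(mp, mr), accuracy = overall,
                      flagged = FALSE)
  rbind(per, macro, micro)
}

binaryRoc <- function(lab, sc) {
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0L || n0 == 0L)
    return(list(fpr = c(0, 1), tpr = c(0, 1), auc = NA_real_))
  ord <- order(sc, decreasing = TRUE)
  lab <- lab[ord]; sc <- sc[ord]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tpr <- c(0, tp[keep] / n1); fpr <- c(0, fp[keep] / n0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' One-vs-rest ROC curves and AUCs
#'
#' Per-class ROC by threshold sweep of each class's softmax score against
#' the rest, AUC by the trapezoid rule (equivalent to the Mann-Whitney rank
#' statistic with ties at 0.5). The micro average pools every (sample,
#' class) binary decision; the macro average is the unweighted mean of the
#' defined per-class AUCs — classes absent from `yTrue` have undefined AUC
#' and are excluded with a warning.
#'
#' @param yTrue labels (0-based, names, or factor).
#' @param scores N x K matrix of class probabilities (rows sum to ~1).
#' @return list with `perClass` (per class: fpr, tpr, auc), `aucs` (named
#'   vector), `macro_auc`, `micro_auc`, `micro` (pooled curve).
#' @export
rocAuc <- function(yTrue, scores) {
  yTrue <- labelsToIndex(yTrue)
  if (is.null(dim(scores)) || nrow(scores) != length(yTrue))
    stop("scores must be an N x K matrix matching yTrue")
  K <- ncol(scores)
  if (any(yTrue < 0L | yTrue >= K)) stop("labels must lie in 0..", K - 1L)
  perClass <- vector("list", K)
  aucs <- numeric(K)
  for (k in seq_len(K)) {
    perClass[[k]] <- binaryRoc(yTrue == (k - 1L), scores[, k])
    aucs[k] <- perClass[[k]]$auc
  }
  names(perClass) <- names(aucs) <- lesionClasses()[seq_len(K)]
  if (anyNA(aucs))
    warning("classes absent from yTrue excluded from the macro average: ",
            paste(names(aucs)[is.na(aucs)], collapse = ", "))
  onehot <- as.vector(outer(yTrue, 0:(K - 1L), `==`))
  micro <- binaryRoc(onehot, as.vector(scores))
  list(perClass = perClass, aucs = aucs,
       macro_auc = mean(aucs, na.rm = TRUE), micro_auc = micro$auc,
       micro = micro)
}

#' Grad-CAM heat map
#'
#' Gradient-weighted class-activation map: the gradient of the target-class
#' logit with respect to a convolutional node's activations is spatially
#' averaged into channel weights, the weighted activation sum is
#' ReLU-rectified, bilinearly upsampled to the input size, and normalised to
#' `[0, 1]` (an all-zero map stays zero).
#'
#' @param model a classifier [LesionNet-class].
#' @param image a [LabeledImage-class] or H x W x 3 integer array.
#' @param targetClass 0-based class index or class name.
#' @param layer node name of a spatial feature map. The default is the
#'   two-stream output map (`"fuse_concat"`, the concatenation of the two
#'   backbone streams) when the model has one, else the fusion-block output
#'   (`"features"`).
#' @return H x W matrix in `[0, 1]` at the model's input size.
#' @export
gradCam <- function(model, image, targetClass, layer = NULL) {
  if (is(image, "LabeledImage")) image <- pixels(image)
  assertRgb(image)
  if (is.null(layer)) {
    nodeNames <- vapply(model@spec$nodes, `[[`, "", "name")
    layer <- if ("fuse_concat" %in% nodeNames) "fuse_concat" else "features"
  }
  cls <- labelsToIndex(targetClass)
  x <- array(image / 255, dim = c(dim(image), 1L))
  cam <- eng_gradcam(model@ptr, x, cls, layer)
  up <- upsampleBilinear(cam, dim(image)[1], dim(image)[2])
  m <- max(up)
  if (m > 0) up <- up / m
  up
}

#' Build an evaluation report
#'
#' @param metrics data.frame from [classMetrics()].
#' @param cm confusion matrix.
#' @param roc optional result of [rocAuc()].
#' @return an [EvalReport-class].
#' @export
evalReport <- function(metrics, cm, roc = list()) {
  new("EvalReport", metrics = metrics, confusion = cm, roc = roc)
}

#' Evaluate a classifier on a labelled set
#'
#' Runs the model, then assembles the confusion matrix, the metric table and
#' the ROC/AUC set into an [EvalReport-class]. The single-label identity
#' micro-precision = micro-recall = accuracy is asserted on every report.
#'
#' @param model a classifier [LesionNet-class].
#' @param x images (list or batch array).
#' @param y labels.
#' @param nClasses number of classes.
#' @return an [EvalReport-class].
#' @export
evaluateModel <- function(model, x, y, nClasses = 7L) {
  y <- labelsToIndex(y)
  probs <- netProbs(model, asBatchArray(x))
  pred <- max.col(probs) - 1L
  cm <- lesionConfusionMatrix(y, pred, nClasses)
  met <- classMetrics(cm)
  micro <- met[met$class == "micro", ]
  stopifnot(isTRUE(all.equal(micro$precision, micro$accuracy)))
  roc <- rocAuc(y, probs)
  evalReport(met, cm, roc)
}

#' Difference between two metric rows or reports
#'
#' Subtracts the four headline metrics (precision, recall, F1, accuracy) of
#' `b` from those of `a`, rounded to two decimals — the ablation-comparison
#' arithmetic of the published tables.
#'
#' @param a,b [EvalReport-class] objects (macro rows are compared) or
#'   one-row data.frames / named vectors with the four metric fields.
#' @return data.frame with columns `precision`, `recall`, `f1`, `accuracy`.
#' @export
#' @examples
#' ref <- referenceVariantMetrics()
#' reportDelta(ref[ref$variant == "improved_vgg16", ],
#'             ref[ref$variant == "vgg16", ])
reportDelta <- function(a, b) {
  pick <- function(x) {
    if (is(x, "EvalReport")) x <- x@metrics[x@metrics$class == "macro", ]
    x <- as.list(x)
    vapply(c("precision", "recall", "f1", "accuracy"), function(f)
      as.numeric(x[[f]]), 0)
  }
  va <- pick(a); vb <- pick(b)
  as.data.frame(as.list(round(va - vb, 2)))
}

#' Write an evaluation report to files
#'
#' Emits `metrics.csv` (two-decimal percent scale), `confusion.csv`,
#' `roc_points.csv`, and PNG renderings of the confusion matrix and ROC
#' curves.
#'
#' @param report an [EvalReport-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  met <- report@metrics
  for (f in c("precision", "recall", "f1", "accuracy"))
    met[[f]] <- round(met[[f]], 2)
  write.csv(met, file.path(dir, "metrics.csv"), row.names = FALSE)
  write.csv(as.data.frame(report@confusion), file.path(dir, "confusion.csv"),
            row.names = TRUE)
  if (length(report@roc)) {
    pts <- do.call(rbind, lapply(names(report@roc$perClass), function(cl) {
      pc <- report@roc$perClass[[cl]]
      data.frame(class = cl, fpr = pc$fpr, tpr = pc$tpr)
    }))
    write.csv(pts, file.path(dir, "roc_points.csv"), row.names = FALSE)
  }
  grDevices::png(file.path(dir, "confusion.png"), 600, 600)
  graphics::image(seq_len(ncol(report@confusion)),
                  seq_len(nrow(report@confusion)),
                  t(report@confusion[nrow(report@confusion):1, ]),
                  xlab = "predicted", ylab = "actual", axes = FALSE,
                  main = "Confusion matrix")
  graphics::axis(1, seq_len(ncol(report@confusion)), colnames(report@confusion))
  graphics::axis(2, seq_len(nrow(report@confusion)),
                 rev(rownames(report@confusion)))
  grDevices::dev.off()
  if (length(report@roc)) {
    grDevices::png(file.path(dir, "roc.png"), 600, 600)
    graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                   xlab = "FPR", ylab = "TPR", main = "One-vs-rest ROC")
    cols <- grDevices::rainbow(length(report@roc$perClass))
    for (i in seq_along(report@roc$perClass)) {
      pc <- report@roc$perClass[[i]]
      graphics::lines(pc$fpr, pc$tpr, col = cols[i])
    }
    graphics::legend("bottomright", names(report@roc$perClass), col = cols,
                     lty = 1, cex = 0.8)
    grDevices::dev.off()
  }
  invisible(dir)
}
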