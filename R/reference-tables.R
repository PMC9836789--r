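# Published reference numbers for the ISIC2018 (HAM10000) seven-class task and
# for the two-stream architecture family. These tables are *inputs*: the split
# planner, the balancing planner and the metric worked examples are validated
# against them.

#' ISIC2018 per-class image totals
#'
#' Total dermoscopy image counts per lesion class in the ISIC2018 Task 3
#' (HAM10000) classification dataset, in the fixed class order.
#'
#' @return Named integer vector (Akiec, Bcc, Bkl, Df, Mel, Nv, Vasc).
#' @export
#' @examples
#' sum(isicClassTotals())  # 10015
isicClassTotals <- function() {
  setNames(c(327L, 514L, 1099L, 115L, 1113L, 6705L, 142L), lesionClasses())
}

#' Published ISIC2018 train/test/validation division
#'
#' The per-class counts of the published 7:2:1 division of ISIC2018 used as
#' the per-class override table by [splitDataset()]: the published counts
#' deviate slightly from exact 70/20/10 rounding, so they are reproduced
#' verbatim rather than recomputed.
#'
#' @return data.frame with columns `class`, `train`, `test`, `val`.
#' @export
#' @examples
#' colSums(isicSplitCounts()[, -1])  # 7020, 1998, 997
isicSplitCounts <- function() {
  data.frame(
    class = lesionClasses(),
    train = c(230L, 361L, 771L, 81L, 780L, 4697L, 100L),
    test  = c(65L, 102L, 219L, 23L, 222L, 1339L, 28L),
    val   = c(32L, 51L, 109L, 11L, 111L, 669L, 14L),
    stringsAsFactors = FALSE
  )
}

#' Published augmented-training-set targets
#'
#' Per-class training-set sizes after augmentation-based balancing: every
#' class except melanocytic nevus (Nv) is expanded towards the Nv count.
#'
#' @return Named integer vector in the fixed class order.
#' @export
#' @examples
#' sum(isicAugmentedTargets())  # 34946
isicAugmentedTargets <- function() {
  setNames(c(4251L, 5040L, 5383L, 4536L, 5439L, 4697L, 5600L), lesionClasses())
}

#' Reported benchmark metrics of the architecture variants
#'
#' Published test-set precision, recall, F1 and accuracy (percent) of the
#' architecture variants on ISIC2018: plain VGG-16, the residual-augmented
#' ("improved") VGG-16 with and without the multireceptive-field block, plain
#' DenseNet-121, and the full two-stream model with and without the
#' multireceptive-field block. Used as worked-example inputs for the metric
#' formulas and the report-delta operation; reproducing them by training
#' requires the full ISIC2018 dataset and is out of scope.
#'
#' @return data.frame with columns `variant`, `precision`, `recall`, `f1`,
#'   `accuracy` (all percent).
#' @export
referenceVariantMetrics <- function() {
  data.frame(
    variant = c("vgg16", "improved_vgg16_no_mrf", "improved_vgg16",
                "densenet121", "two_stream_no_mrf", "two_stream"),
    precision = c(66.43, 76.47, 77.85, 80.94, 82.88, 83.53),
    recall    = c(75.09, 83.23, 85.52, 87.61, 94.10, 95.04),
    f1        = c(70.50, 79.71, 81.50, 84.14, 88.13, 88.91),
    accuracy  = c(72.48, 86.32, 87.60, 88.14, 90.17, 91.24),
    stringsAsFactors = FALSE
  )
}

#' Reported GeM pooling-exponent sweep
#'
#' Published test accuracy (percent) of the full two-stream model as the GeM
#' pooling exponent p is varied; `Inf` denotes global max pooling and `1`
#' average pooling. The best value, p = 4, is the package default.
#'
#' @return data.frame with columns `p` and `accuracy`.
#' @export
referenceGemSweep <- function() {
  data.frame(p = c(1, 2, 3, 4, 5, Inf),
             accuracy = c(88.15, 89.87, 90.58, 91.24, 89.17, 89.03))
}

#' Reported total parameter count of the full model, in millions
#' @return A number (millions of trainable parameters).
#' @export
referenceParameterCountM <- function() 19.70
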