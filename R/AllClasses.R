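#' Labelled dermoscopy image
#'
#' An 8-bit RGB image together with its lesion class and provenance. The
#' fixed class order of [lesionClasses()] links `classIndex` (0-6) and
#' `className`.
#'
#' @slot pixels integer array H x W x 3, values 0-255.
#' @slot className one of the seven lesion classes.
#' @slot classIndex integer 0-6 consistent with `className`.
#' @slot isAugmented logical; `TRUE` for augmentation products.
#' @slot sourceId identifier of the originating image.
#' @export
setClass("LabeledImage", representation(
  pixels = "array", className = "character", classIndex = "integer",
  isAugmented = "logical", sourceId = "character"
))

setValidity("LabeledImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "pixels must be H x W x 3")
  r <- range(object@pixels)
  if (r[1] < 0 || r[2] > 255) msg <- c(msg, "pixel values must lie in [0, 255]")
  if (!object@className %in% lesionClasses()) msg <- c(msg, "unknown class name")
  else if (classIndex(object@className) != object@classIndex)
    msg <- c(msg, "classIndex inconsistent with className")
  if (length(msg)) msg else TRUE
})

#' @describeIn LabeledImage constructor.
#' @param pixels,className,isAugmented,sourceId see slots.
#' @export
labeledImage <- function(pixels, className, isAugmented = FALSE,
                         sourceId = "img") {
  new("LabeledImage", pixels = pixels, className = className,
      classIndex = classIndex(className), isAugmented = isAugmented,
      sourceId = sourceId)
}

setMethod("show", "LabeledImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("LabeledImage %dx%d  class %s (%d)%s  source %s\n",
              d[1], d[2], object@className, object@classIndex,
              if (object@isAugmented) " [augmented]" else "", object@sourceId))
})

#' Hair ground truth for a synthetic image
#'
#' @slot mask logical matrix, `TRUE` at hair-stroke pixels.
#' @slot strokeCount number of strokes drawn.
#' @export
setClass("HairTruth", representation(mask = "matrix", strokeCount = "integer"))

setValidity("HairTruth", function(object) {
  msg <- character()
  if (object@strokeCount < 0L) msg <- c(msg, "strokeCount must be >= 0")
  if ((sum(object@mask) > 0L) != (object@strokeCount > 0L))
    msg <- c(msg, "mask must be empty exactly when strokeCount is 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic dermoscopy generator configuration
#'
#' Controls the seeded generator: image size, per-class lesion appearance
#' (colour, border irregularity, texture amplitude), hair artefacts, and the
#' skin-tone range. The same configuration and seed always reproduce
#' byte-identical images.
#'
#' @slot imageSize side length in pixels.
#' @slot classPalette named list, one entry per class, each with `color`
#'   (RGB centre, 0-255), `spread` (per-channel half-range), `irregularity`
#'   (border perturbation in `[0,1]`) and `texture` (amplitude in `[0,1]`).
#' @slot hairProbability probability that an image receives hair strokes.
#' @slot hairCountRange integer interval for the stroke count.
#' @slot hairWidthRange stroke width interval in pixels.
#' @slot skinToneLow,skinToneHigh RGB interval for the background skin.
#' @slot seed base seed of the generator.
#' @export
setClass("SynthConfig", representation(
  imageSize = "integer", classPalette = "list", hairProbability = "numeric",
  hairCountRange = "integer", hairWidthRange = "numeric",
  skinToneLow = "numeric", skinToneHigh = "numeric", seed = "integer"
))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@imageSize < 16L) msg <- c(msg, "imageSize must be >= 16")
  if (!all(lesionClasses() %in% names(object@classPalette)))
    msg <- c(msg, "classPalette must contain all 7 lesion classes")
  if (object@hairProbability < 0 || object@hairProbability > 1)
    msg <- c(msg, "hairProbability must lie in [0, 1]")
  if (any(object@hairCountRange < 0L) || diff(object@hairCountRange) < 0)
    msg <- c(msg, "hairCountRange must be a nonnegative increasing interval")
  if (any(object@hairWidthRange <= 0) || diff(object@hairWidthRange) < 0)
    msg <- c(msg, "hairWidthRange must be a positive increasing interval")
  if (length(msg)) msg else TRUE
})

#' Hair-removal configuration
#'
#' Parameters of black-hat hair detection and fast-marching inpainting. The
#' defaults (17x17 box element, mask threshold 10/255, inpaint radius 1)
#' capture hairs thinner than about 8 px in a 224x224 dermoscopy image.
#'
#' @slot seShape structuring element shape, `"box"` or `"disc"`.
#' @slot seSize odd structuring element side length in pixels, >= 3.
#' @slot maskThreshold black-hat intensity threshold on the 0-255 scale.
#' @slot inpaintRadius neighbourhood radius (px) of the inpainting average.
#' @export
setClass("HairRemovalConfig", representation(
  seShape = "character", seSize = "integer", maskThreshold = "numeric",
  inpaintRadius = "numeric"
))

setValidity("HairRemovalConfig", function(object) {
  msg <- character()
  if (!object@seShape %in% c("box", "disc")) msg <- c(msg, "seShape must be box or disc")
  if (object@seSize < 3L || object@seSize %% 2L == 0L)
    msg <- c(msg, "seSize must be odd and >= 3")
  if (object@maskThreshold <= 0 || object@maskThreshold >= 255)
    msg <- c(msg, "maskThreshold must lie in (0, 255)")
  if (object@inpaintRadius < 1) msg <- c(msg, "inpaintRadius must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn HairRemovalConfig constructor with the package defaults.
#' @param seShape,seSize,maskThreshold,inpaintRadius see slots.
#' @export
hairRemovalConfig <- function(seShape = "box", seSize = 17L,
                              maskThreshold = 10, inpaintRadius = 1) {
  new("HairRemovalConfig", seShape = seShape, seSize = as.integer(seSize),
      maskThreshold = maskThreshold, inpaintRadius = inpaintRadius)
}

#' Augmentation configuration
#'
#' The six augmentation operations applied in fixed order: random rotation,
#' horizontal/vertical shift, zoom, shear, flips, and resize. Out-of-frame
#' pixels are filled by reflection.
#'
#' @slot rotationRange degrees; rotation drawn from `[-r, r]`.
#' @slot shiftFraction fraction of the image side for shifts.
#' @slot zoomRange interval around 1 for isotropic zoom.
#' @slot shearRange degrees; shear drawn from `[-s, s]`.
#' @slot flipHorizontal,flipVertical flip probabilities.
#' @slot outputSize side length after the final resize.
#' @export
setClass("AugmentationConfig", representation(
  rotationRange = "numeric", shiftFraction = "numeric", zoomRange = "numeric",
  shearRange = "numeric", flipHorizontal = "numeric", flipVertical = "numeric",
  outputSize = "integer"
))

setValidity("AugmentationConfig", function(object) {
  msg <- character()
  if (any(object@zoomRange <= 0) || diff(object@zoomRange) < 0)
    msg <- c(msg, "zoomRange must be a positive increasing interval")
  for (p in c(object@flipHorizontal, object@flipVertical))
    if (p < 0 || p > 1) msg <- c(msg, "flip probabilities must lie in [0, 1]")
  if (object@shiftFraction < 0 || object@shiftFraction > 1)
    msg <- c(msg, "shiftFraction must lie in [0, 1]")
  if (object@outputSize < 1L) msg <- c(msg, "outputSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn AugmentationConfig constructor with the package defaults.
#' @param rotationRange,shiftFraction,zoomRange,shearRange see slots.
#' @param flipHorizontal,flipVertical,outputSize see slots.
#' @export
augmentationConfig <- function(rotationRange = 180, shiftFraction = 0.1,
                               zoomRange = c(0.9, 1.1), shearRange = 10,
                               flipHorizontal = 0.5, flipVertical = 0.5,
                               outputSize = 224L) {
  new("AugmentationConfig", rotationRange = rotationRange,
      shiftFraction = shiftFraction, zoomRange = zoomRange,
      shearRange = shearRange, flipHorizontal = flipHorizontal,
      flipVertical = flipVertical, outputSize = as.integer(outputSize))
}

#' GeM pooling parameters
#'
#' The generalized-mean pooling exponent `p` shared across channels (p = 1 is
#' average pooling, p -> Inf approaches max pooling) and the small positive
#' guard added to activations before exponentiation.
#'
#' @slot p pooling exponent, `>= 1` (may be `Inf` for exact max pooling).
#' @slot eps positive numerical guard.
#' @export
setClass("GeMParams", representation(p = "numeric", eps = "numeric"))

setValidity("GeMParams", function(object) {
  msg <- character()
  if (!is.infinite(object@p) && object@p < 1) msg <- c(msg, "p must be >= 1")
  if (object@eps <= 0) msg <- c(msg, "eps must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeMParams constructor; the default exponent is the published
#'   optimum p = 4.
#' @param p,eps see slots.
#' @export
gemParams <- function(p = 4, eps = 1e-6) new("GeMParams", p = p, eps = eps)

#' Training configuration
#'
#' The training protocol: Adam with batch size 16 and initial learning rate
#' 1e-4, decayed by a factor of 10 when the validation loss plateaus, early
#' stopping after 5 non-improving epochs, and a 28-epoch cap.
#'
#' @slot batchSize minibatch size.
#' @slot initialLr initial learning rate.
#' @slot lrDecayFactor multiplicative decay on plateau (0 < f < 1).
#' @slot lrPatience plateau epochs before a decay step.
#' @slot earlyStopPatience non-improving epochs before stopping (`Inf` to
#'   disable).
#' @slot maxEpochs epoch cap.
#' @slot seed seed for shuffling.
#' @slot stopAtTrainAccuracy optional early exit once the training accuracy
#'   reaches this fraction (`NA` to disable); used by overfitting smoke tests.
#' @export
setClass("TrainConfig", representation(
  batchSize = "integer", initialLr = "numeric", lrDecayFactor = "numeric",
  lrPatience = "numeric", earlyStopPatience = "numeric", maxEpochs = "integer",
  seed = "integer", stopAtTrainAccuracy = "numeric"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@lrDecayFactor <= 0 || object@lrDecayFactor >= 1)
    msg <- c(msg, "lrDecayFactor must lie in (0, 1)")
  if (object@lrPatience < 1) msg <- c(msg, "lrPatience must be >= 1")
  if (object@earlyStopPatience < 1) msg <- c(msg, "earlyStopPatience must be >= 1")
  if (object@maxEpochs < 0L) msg <- c(msg, "maxEpochs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn TrainConfig constructor with the protocol defaults.
#' @param batchSize,initialLr,lrDecayFactor,lrPatience see slots.
#' @param earlyStopPatience,maxEpochs,seed,stopAtTrainAccuracy see slots.
#' @export
trainConfig <- function(batchSize = 16L, initialLr = 1e-4,
                        lrDecayFactor = 0.1, lrPatience = 3,
                        earlyStopPatience = 5, maxEpochs = 28L, seed = 1L,
                        stopAtTrainAccuracy = NA_real_) {
  new("TrainConfig", batchSize = as.integer(batchSize), initialLr = initialLr,
      lrDecayFactor = lrDecayFactor, lrPatience = lrPatience,
      earlyStopPatience = earlyStopPatience, maxEpochs = as.integer(maxEpochs),
      seed = as.integer(seed), stopAtTrainAccuracy = stopAtTrainAccuracy)
}

#' A built lesion-classification network
#'
#' Wraps the native network graph together with its specification, so that
#' models can be rebuilt from checkpoints and inspected.
#'
#' @slot ptr external pointer to the native network.
#' @slot spec the graph specification list used to build it.
#' @slot classes output class names (empty for bare feature streams).
#' @slot inputSize input side length in pixels.
#' @slot variant architecture variant label.
#' @slot gemP GeM exponent of the pooling head (`NA` for bare streams).
#' @export
setClass("LesionNet", representation(
  ptr = "externalptr", spec = "list", classes = "character",
  inputSize = "integer", variant = "character", gemP = "numeric"
))

setMethod("show", "LesionNet", function(object) {
  cat(sprintf("LesionNet '%s'  input %dx%dx3  %.2fM parameters\n",
              object@variant, object@inputSize, object@inputSize,
              countParameters(object) / 1e6))
  if (length(object@classes))
    cat("  classes:", paste(object@classes, collapse = ", "), "\n")
  if (!is.na(object@gemP)) cat("  GeM p =", object@gemP, "\n")
})

#' Evaluation report
#'
#' Confusion matrix, per-class and macro/micro metrics, and one-vs-rest
#' ROC/AUC results of a classifier on a labelled set.
#'
#' @slot metrics data.frame of per-class rows plus `macro` and `micro` rows.
#' @slot confusion 7x7 integer matrix, rows = actual, columns = predicted.
#' @slot roc list with per-class curves/AUCs and micro/macro summaries
#'   (may be empty when scores were not supplied).
#' @export
setClass("EvalReport", representation(
  metrics = "data.frame", confusion = "matrix", roc = "list"
))

setMethod("show", "EvalReport", function(object) {
  acc <- object@metrics$accuracy[object@metrics$class == "micro"]
  cat(sprintf("EvalReport: %d samples, accuracy %.2f%%\n",
              sum(object@confusion), acc))
  if (length(object@roc))
    cat(sprintf("  macro-AUC %.3f  micro-AUC %.3f\n",
                object@roc$macro_auc, object@roc$micro_auc))
})

#' Result of the thresholded classification service
#'
#' @slot status `"accepted"` or `"reupload_requested"`.
#' @slot className,classIndex predicted class.
#' @slot probability winning softmax probability.
#' @slot elapsed forward-pass wall time in seconds.
#' @slot probs all seven class probabilities.
#' @slot threshold acceptance threshold used.
#' @export
setClass("ClassificationResult", representation(
  status = "character", className = "character", classIndex = "integer",
  probability = "numeric", elapsed = "numeric", probs = "numeric",
  threshold = "numeric"
))

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("%s: %s (p = %.3f, %.3fs)%s\n",
              if (object@status == "accepted") "Accepted" else "Reupload requested",
              object@className, object@probability, object@elapsed,
              sprintf(" [threshold %.2f]", object@threshold)))
})
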