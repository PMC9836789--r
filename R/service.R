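# Stateless classification service: image in, thresholded decision out.
# Inputs below the confidence threshold are answered with a reupload
# request rather than a (likely wrong) label.

readRgbImage <- function(path) {
  ebi <- tryCatch(suppressWarnings(EBImage::readImage(path)),
                  error = function(e)
    stop("unreadable image file: ", path))
  a <- EBImage::imageData(ebi)
  if (length(dim(a)) != 3L || dim(a)[3] < 3L)
    stop("format error: an RGB image is required: ", path)
  a <- a[, , 1:3, drop = FALSE]
  aperm(array(as.integer(clamp255(round(a * 255))), dim = dim(a)), c(2L, 1L, 3L))
}

#' Classify one dermoscopy image with a confidence threshold
#'
#' Resizes the image to the model input, runs a forward pass, and applies
#' the acceptance rule: if the winning softmax probability is strictly below
#' `threshold` (default 0.9, guarding in particular the melanoma call) the
#' status is `"reupload_requested"`; at or above it the prediction is
#' accepted. Elapsed time measures the forward pass only.
#'
#' @param image file path, [LabeledImage-class], or integer H x W x 3 array.
#' @param model a [LesionNet-class] or a checkpoint path
#'   (see [saveCheckpoint()]).
#' @param threshold global acceptance threshold in `[0, 1]`.
#' @param classThresholds optional named vector of per-class overrides,
#'   applied to the predicted class.
#' @return a [ClassificationResult-class].
#' @export
classifyImage <- function(image, model, threshold = 0.9,
                          classThresholds = NULL) {
  if (is.character(model)) model <- loadCheckpoint(model)
  if (is.character(image)) image <- readRgbImage(image)
  if (is(image, "LabeledImage")) image <- pixels(image)
  assertRgb(image)
  img <- resizeImage(image, model@inputSize)
  x <- batchFromImages(list(img))
  t0 <- Sys.time()
  probs <- netProbs(model, x)[1, ]
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  classes <- if (length(model@classes)) model@classes else
    lesionClasses()[seq_along(probs)]
  names(probs) <- classes
  win <- which.max(probs)
  thr <- threshold
  if (!is.null(classThresholds) && classes[win] %in% names(classThresholds))
    thr <- classThresholds[[classes[win]]]
  status <- if (probs[win] < thr) "reupload_requested" else "accepted"
  new("ClassificationResult", status = status, className = classes[win],
      classIndex = win - 1L, probability = unname(probs[win]),
      elapsed = elapsed, probs = probs, threshold = thr)
}

#' Serialise a classification result to JSON
#'
#' @param result a [ClassificationResult-class].
#' @return a JSON string.
#' @export
resultToJson <- function(result) {
  jsonlite::toJSON(list(
    status = result@status, class_name = result@className,
    class_index = result@classIndex, probability = result@probability,
    elapsed_seconds = result@elapsed, probabilities = as.list(result@probs),
    threshold = result@threshold
  ), auto_unbox = TRUE, digits = NA)
}

#' Classify a directory or list of images
#'
#' Per-image thresholded classification with an optional truth manifest.
#' Unreadable files are skipped with a warning. When truth labels are
#' supplied the summary reports the success rate (and per-group rates if the
#' truth has a `group` column) and the most-confused actual/predicted class
#' pair — the off-diagonal maximum of the batch confusion matrix.
#'
#' @param images directory path or character vector of image files.
#' @param model a [LesionNet-class] or checkpoint path.
#' @param truth optional data.frame with columns `path`, `class_name`
#'   (and optionally `group`).
#' @param threshold acceptance threshold.
#' @return list with `results` (per-image data.frame) and `summary` (list
#'   with `success_rate`, `most_confused`, optionally `groups`), or only
#'   `results` when no truth is given.
#' @export
batchClassify <- function(images, model, truth = NULL, threshold = 0.9) {
  if (is.character(model)) model <- loadCheckpoint(model)
  if (length(images) == 1L && dir.exists(images))
    images <- list.files(images, pattern = "\\.(png|jpe?g)$", full.names = TRUE,
                         ignore.case = TRUE)
  if (length(images) == 0L) stop("no images to classify")
  rows <- list()
  for (p in images) {
    res <- tryCatch(classifyImage(p, model, threshold), error = function(e) {
      warning("skipping ", p, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    rows[[p]] <- data.frame(path = p, status = res@status,
                            class_name = res@className,
                            class_index = res@classIndex,
                            probability = res@probability,
                            elapsed = res@elapsed, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  if (is.null(truth) || nrow(truth) == 0L) return(list(results = results))
  tr <- merge(results, truth[, intersect(c("path", "class_name", "group"),
                                         names(truth))],
              by = "path", suffixes = c("", "_true"))
  ok <- tr$class_name == tr$class_name_true
  cm <- lesionConfusionMatrix(classIndex(tr$class_name_true),
                              classIndex(tr$class_name))
  off <- cm; diag(off) <- 0L
  mc <- if (any(off > 0)) {
    ij <- which(off == max(off), arr.ind = TRUE)[1, ]
    sprintf("%s->%s", rownames(cm)[ij[1]], colnames(cm)[ij[2]])
  } else NA_character_
  summary <- list(success_rate = 100 * mean(ok), most_confused = mc)
  if ("group" %in% names(tr))
    summary$groups <- vapply(split(ok, tr$group), function(v) 100 * mean(v), 0)
  list(results = results, summary = summary)
}
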