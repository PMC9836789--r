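# Preprocessing pipeline: bilinear resize, black-hat hair detection with
# fast-marching inpainting, the six augmentation operations, stratified
# 7:2:1 splitting and augmentation-based class balancing.

#' Resize an RGB image with bilinear resampling
#'
#' Resizes to `size` x `size` without aspect-ratio padding (the standard
#' 600x450 -> 224x224 dermoscopy step). A same-size input is returned
#' pixel-identical.
#'
#' @param img integer H x W x 3 array, values 0-255.
#' @param size target side length in pixels.
#' @return integer `size` x `size` x 3 array.
#' @export
resizeImage <- function(img, size = 224L) {
  assertRgb(img)
  size <- as.integer(size)
  if (size < 1L) stop("size must be >= 1")
  if (dim(img)[1] == size && dim(img)[2] == size)
    return(array(as.integer(img), dim = dim(img)))
  out <- fromEBImage(EBImage::resize(toEBImage(img), w = size, h = size))
  array(as.integer(out), dim = c(size, size, 3L))
}

#' Convert an RGB image to luminance grayscale
#'
#' ITU-R 601 weighting: `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param img integer H x W x 3 array.
#' @return double matrix on the 0-255 scale.
#' @export
rgbToGray <- function(img) {
  assertRgb(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Detect hair pixels with the morphological black-hat transform
#'
#' Converts to grayscale, applies the black-hat transform (closing minus
#' image) with the configured structuring element, and thresholds: thin dark
#' structures narrower than the element — hairs — light up, flat regions give
#' exactly zero.
#'
#' @param img integer H x W x 3 array.
#' @param cfg a [HairRemovalConfig-class]; see [hairRemovalConfig()].
#' @return logical H x W matrix (`TRUE` = hair pixel).
#' @export
detectHairMask <- function(img, cfg = hairRemovalConfig()) {
  assertRgb(img)
  validObject(cfg)
  d <- dim(img)
  if (cfg@seSize > d[1] || cfg@seSize > d[2])
    stop("structuring element larger than the image")
  g <- rgbToGray(img) / 255
  kern <- EBImage::makeBrush(cfg@seSize, shape = cfg@seShape)
  bh <- EBImage::blackTopHat(t(g), kern)     # EBImage works in (x, y)
  t(bh) * 255 > cfg@maskThreshold
}

#' Inpaint masked pixels by fast-marching propagation
#'
#' Fills masked (hair) pixels in increasing order of distance from the mask
#' boundary; each pixel receives the inverse-square-distance weighted average
#' of already-known pixels in its neighbourhood, so values propagate inward
#' from the boundary front. Unmasked pixels are returned bit-identical.
#'
#' @param img integer H x W x 3 array.
#' @param mask logical H x W matrix of pixels to fill.
#' @param radius neighbourhood radius in pixels (>= 1).
#' @return integer H x W x 3 array.
#' @export
inpaintHair <- function(img, mask, radius = 1) {
  assertRgb(img)
  if (!all(dim(mask) == dim(img)[1:2])) stop("mask dimensions must match image")
  mode(mask) <- "logical"
  if (!any(mask)) return(array(as.integer(img), dim = dim(img)))
  if (all(mask)) stop("degenerate mask: no known pixels to propagate from")
  H <- dim(img)[1]; W <- dim(img)[2]
  r <- max(2L, as.integer(ceiling(radius)) + 1L)

  # order of the advancing front: distance of each masked pixel to the
  # nearest known pixel (EBImage::distmap measures within the foreground)
  dmap <- t(EBImage::distmap(t(mask * 1)))
  ord <- order(dmap[mask])
  idx <- which(mask)[ord]

  known <- !mask
  c1 <- matrix(as.numeric(img[, , 1]), H)
  c2 <- matrix(as.numeric(img[, , 2]), H)
  c3 <- matrix(as.numeric(img[, , 3]), H)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[!(off$dy == 0 & off$dx == 0), ]
  ody <- off$dy; odx <- off$dx
  for (p in idx) {
    y <- (p - 1L) %% H + 1L
    x <- (p - 1L) %/% H + 1L
    yy <- y + ody; xx <- x + odx
    ok <- yy >= 1L & yy <= H & xx >= 1L & xx <= W
    yy <- yy[ok]; xx <- xx[ok]
    q <- yy + (xx - 1L) * H
    kq <- known[q]
    if (!any(kq)) next  # filled on a later sweep by construction of the order
    q <- q[kq]
    wgt <- 1 / ((yy[kq] - y)^2 + (xx[kq] - x)^2)
    sw <- sum(wgt)
    c1[p] <- sum(c1[q] * wgt) / sw
    c2[p] <- sum(c2[q] * wgt) / sw
    c3[p] <- sum(c3[q] * wgt) / sw
    known[p] <- TRUE
  }
  out <- array(c(c1, c2, c3), dim = dim(img))
  array(as.integer(clamp255(round(out))), dim = dim(img))
}

#' Remove hair from an image (detection + inpainting)
#'
#' @param img integer H x W x 3 array.
#' @param cfg a [HairRemovalConfig-class].
#' @return list with `image` (dehaired array) and `mask` (detected hair).
#' @export
removeHair <- function(img, cfg = hairRemovalConfig()) {
  mask <- detectHairMask(img, cfg)
  if (all(mask)) stop("degenerate hair mask covers the whole image")
  list(image = inpaintHair(img, mask, cfg@inpaintRadius), mask = mask)
}

# inverse-mapped affine sampling with bilinear interpolation and mirror
# (reflect) padding; A maps output (x, y) homogeneous coords to input coords
affineSample <- function(img, Ainv, outH, outW) {
  H <- dim(img)[1]; W <- dim(img)[2]
  xo <- rep(seq_len(outW), each = outH)
  yo <- rep(seq_len(outH), times = outW)
  xs <- Ainv[1, 1] * xo + Ainv[1, 2] * yo + Ainv[1, 3]
  ys <- Ainv[2, 1] * xo + Ainv[2, 2] * yo + Ainv[2, 3]
  reflect <- function(v, n) {
    if (n == 1L) return(rep(1, length(v)))
    period <- 2 * (n - 1)
    v <- (v - 1) %% period
    ifelse(v > (n - 1), period - v, v) + 1
  }
  xs <- reflect(xs, W); ys <- reflect(ys, H)
  x0 <- pmin(floor(xs), W - 1L); x0 <- pmax(x0, 1L)
  y0 <- pmin(floor(ys), H - 1L); y0 <- pmax(y0, 1L)
  fx <- xs - x0; fy <- ys - y0
  i00 <- y0 + (x0 - 1L) * H
  out <- array(0, dim = c(outH, outW, 3L))
  for (ch in 1:3) {
    v <- as.numeric(img[, , ch])
    p <- v[i00] * (1 - fy) * (1 - fx) + v[i00 + 1L] * fy * (1 - fx) +
         v[i00 + H] * (1 - fy) * fx + v[i00 + H + 1L] * fy * fx
    out[, , ch] <- matrix(p, outH, outW)
  }
  out
}

#' Apply the six-operation random augmentation
#'
#' In fixed order: random rotation, horizontal/vertical shift, zoom, shear,
#' flips, then resize to `outputSize`. All transforms act about the image
#' centre, out-of-frame pixels are mirror-filled, and the draw is fully
#' determined by `seed`. The label is preserved and the result is marked
#' augmented.
#'
#' @param img a [LabeledImage-class] or an integer H x W x 3 array.
#' @param cfg an [AugmentationConfig-class]; see [augmentationConfig()].
#' @param seed integer seed.
#' @return Same type as `img` (a [LabeledImage-class] with
#'   `isAugmented = TRUE`, or an array).
#' @export
augmentImage <- function(img, cfg = augmentationConfig(), seed = 1L) {
  validObject(cfg)
  isLab <- is(img, "LabeledImage")
  px <- if (isLab) pixels(img) else img
  assertRgb(px)
  H <- dim(px)[1]; W <- dim(px)[2]
  out <- withSeed(seed, {
    theta <- runif(1, -cfg@rotationRange, cfg@rotationRange) * pi / 180
    shx <- runif(1, -cfg@shiftFraction, cfg@shiftFraction) * W
    shy <- runif(1, -cfg@shiftFraction, cfg@shiftFraction) * H
    zoom <- runif(1, cfg@zoomRange[1], cfg@zoomRange[2])
    shear <- tan(runif(1, -cfg@shearRange, cfg@shearRange) * pi / 180)
    fh <- runif(1) < cfg@flipHorizontal
    fv <- runif(1) < cfg@flipVertical

    cx <- (W + 1) / 2; cy <- (H + 1) / 2
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    shr <- matrix(c(1, 0, shear, 1), 2)
    scl <- diag(c(zoom * (if (fh) -1 else 1), zoom * (if (fv) -1 else 1)))
    M <- rot %*% shr %*% scl
    # forward map: p_out = M (p_in - c) + c + shift; invert for sampling
    Minv <- solve(M)
    tr <- c(cx + shx, cy + shy)
    Ainv <- cbind(Minv, c(cx, cy) - Minv %*% tr)
    smp <- affineSample(px, Ainv, H, W)
    array(as.integer(clamp255(round(smp))), dim = c(H, W, 3L))
  })
  out <- resizeImage(out, cfg@outputSize)
  if (isLab)
    labeledImage(out, img@className, isAugmented = TRUE, sourceId = img@sourceId)
  else out
}

#' Stratified 7:2:1 dataset split
#'
#' Splits a manifest per class into train/test/validation. Each class is
#' shuffled with the given seed and partitioned by largest-remainder
#' rounding of the ratio (order train, test, val), or — when `overrides` is
#' supplied, as with the published division of [isicSplitCounts()] — by the
#' exact per-class counts given there.
#'
#' @param manifest data.frame with at least `class_name` (and any id columns).
#' @param ratio positive length-3 vector, train:test:val.
#' @param seed integer shuffle seed.
#' @param overrides optional data.frame with columns `class`, `train`,
#'   `test`, `val` giving exact per-class counts.
#' @return The manifest with a `split` column (`"train"`, `"test"`, `"val"`).
#' @export
#' @examples
#' m <- data.frame(class_name = rep("Nv", 10))
#' table(splitDataset(m, seed = 1)$split)
splitDataset <- function(manifest, ratio = c(7, 2, 1), seed = 1L,
                         overrides = NULL) {
  if (any(ratio <= 0) || length(ratio) != 3L) stop("ratio must be 3 positive numbers")
  classes <- unique(manifest$class_name)
  n0 <- table(manifest$class_name)
  empty <- setdiff(classes, names(n0)[n0 > 0])
  if (length(empty)) stop("cannot stratify empty class: ", paste(empty, collapse = ", "))
  manifest$split <- NA_character_
  frac <- ratio / sum(ratio)
  withSeed(seed, {
    for (cl in classes) {
      rows <- which(manifest$class_name == cl)
      rows <- rows[sample.int(length(rows))]
      n <- length(rows)
      if (!is.null(overrides)) {
        o <- overrides[overrides$class == cl, , drop = FALSE]
        if (nrow(o) != 1L) stop("no override row for class ", cl)
        counts <- c(o$train, o$test, o$val)
        if (sum(counts) != n)
          stop(sprintf("override counts for %s sum to %d but class has %d images",
                       cl, sum(counts), n))
      } else {
        exact <- n * frac
        counts <- floor(exact)
        rem <- n - sum(counts)
        if (rem > 0) {
          give <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
          counts[give] <- counts[give] + 1L
        }
      }
      lab <- rep(c("train", "test", "val"), counts)
      manifest$split[rows] <- lab
    }
  })
  manifest
}

#' Plan augmentation-based class balancing of the training split
#'
#' For every class whose training count is below its target, appends
#' augmented copies round-robin over the class's original training rows
#' (so per-original multiplicities differ by at most one) with fresh
#' deterministic seeds, until the count equals the target. Only the train
#' split changes and only by `is_augmented` rows.
#'
#' @param manifest a split manifest (see [splitDataset()]).
#' @param targets named vector (class -> target training count); defaults to
#'   the largest class's count for every class (the Nv-matching rule).
#' @param seed integer seed for the per-copy augmentation seeds.
#' @return The manifest with appended augmented rows (columns preserved;
#'   augmented rows get `is_augmented = TRUE` and a new `seed`).
#' @export
balanceTrainingSet <- function(manifest, targets = NULL, seed = 1L) {
  if (!"split" %in% names(manifest)) stop("manifest must be split first")
  if (!"is_augmented" %in% names(manifest)) manifest$is_augmented <- FALSE
  tr <- manifest[manifest$split == "train" & !manifest$is_augmented, , drop = FALSE]
  cnt <- table(tr$class_name)
  if (is.null(targets)) {
    targets <- setNames(rep(max(cnt), length(cnt)), names(cnt))
  }
  for (cl in names(targets)) {
    cur <- if (cl %in% names(cnt)) cnt[[cl]] else 0L
    if (targets[[cl]] < cur)
      stop(sprintf("target for %s (%d) is below its current count (%d)",
                   cl, targets[[cl]], cur))
  }
  extra <- list()
  augSeeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L,
                                        sum(pmax(unlist(targets) -
                                          as.integer(cnt[names(targets)]), 0), na.rm = TRUE) + 1L))
  si <- 0L
  for (cl in names(targets)) {
    rows <- which(tr$class_name == cl)
    deficit <- targets[[cl]] - length(rows)
    if (deficit <= 0 || length(rows) == 0L) next
    take <- rep(rows, length.out = deficit)  # round-robin: spread <= 1
    add <- tr[take, , drop = FALSE]
    add$is_augmented <- TRUE
    si2 <- si + seq_len(deficit)
    if ("seed" %in% names(add)) add$seed <- augSeeds[si2]
    si <- si + deficit
    extra[[cl]] <- add
  }
  if (length(extra)) manifest <- rbind(manifest, do.call(rbind, extra))
  rownames(manifest) <- NULL
  manifest
}

#' Per-class, per-split tallies of a manifest
#'
#' @param manifest a split manifest.
#' @return table of class x split counts.
#' @export
manifestTallies <- function(manifest) {
  table(manifest$class_name, manifest$split)
}
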