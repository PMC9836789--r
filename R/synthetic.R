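# Seeded synthetic dermoscopy generator. Images are built from three layers:
# a skin-tone background with mild value noise, one elliptical lesion whose
# colour, border irregularity and texture amplitude are class-dependent, and
# optional dark curvilinear hair strokes (quadratic Bezier curves) with exact
# ground-truth masks. Everything is drawn from a private RNG stream, so a
# fixed (config, seed) pair reproduces byte-identical 8-bit output.

#' Default per-class lesion appearance palette
#'
#' Colour centres follow the gross clinical appearance of the seven classes:
#' melanoma (Mel) very dark brown, nevus (Nv) medium brown, benign keratosis
#' (Bkl) light brown, basal cell carcinoma (Bcc) pearly pink, actinic
#' keratosis (Akiec) erythematous red-orange, dermatofibroma (Df) dusky tan,
#' vascular lesions (Vasc) red-purple. Border irregularity and texture are
#' higher for the malignant classes.
#'
#' @return Named list with `color`, `spread`, `irregularity`, `texture` per
#'   class.
#' @export
defaultClassPalette <- function() {
  list(
    Akiec = list(color = c(225, 150, 120), spread = 12, irregularity = 0.45, texture = 0.60),
    Bcc   = list(color = c(195, 110, 100), spread = 12, irregularity = 0.40, texture = 0.35),
    Bkl   = list(color = c(150, 100, 60),  spread = 12, irregularity = 0.30, texture = 0.55),
    Df    = list(color = c(170, 130, 110), spread = 10, irregularity = 0.15, texture = 0.25),
    Mel   = list(color = c(60, 35, 30),    spread = 15, irregularity = 0.80, texture = 0.65),
    Nv    = list(color = c(120, 70, 50),   spread = 12, irregularity = 0.20, texture = 0.30),
    Vasc  = list(color = c(185, 45, 65),   spread = 12, irregularity = 0.20, texture = 0.20)
  )
}

#' @describeIn SynthConfig constructor with the package defaults.
#' @param imageSize,classPalette,hairProbability,hairCountRange see slots.
#' @param hairWidthRange,skinToneLow,skinToneHigh,seed see slots.
#' @export
synthConfig <- function(imageSize = 224L, classPalette = defaultClassPalette(),
                        hairProbability = 0.5, hairCountRange = c(3L, 8L),
                        hairWidthRange = c(1.5, 3), skinToneLow = c(190, 140, 120),
                        skinToneHigh = c(235, 190, 170), seed = 0L) {
  new("SynthConfig", imageSize = as.integer(imageSize),
      classPalette = classPalette, hairProbability = hairProbability,
      hairCountRange = as.integer(hairCountRange),
      hairWidthRange = hairWidthRange, skinToneLow = skinToneLow,
      skinToneHigh = skinToneHigh, seed = as.integer(seed))
}

# seeded value noise: an (n+1)^2 grid of uniforms bilinearly upsampled to S^2
valueNoise <- function(S, cells = 8L) {
  g <- matrix(runif((cells + 1L)^2, -1, 1), cells + 1L)
  upsampleBilinear(g, S, S)
}

# draw one anti-aliased quadratic Bezier stroke into an alpha accumulator;
# returns the updated alpha matrix
drawStroke <- function(alpha, p0, p1, p2, width, S) {
  nt <- 4L * S
  t <- seq(0, 1, length.out = nt)
  bx <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  by <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  r <- width / 2
  w <- ceiling(r + 1)
  off <- expand.grid(dy = -w:w, dx = -w:w)
  for (i in seq_len(nt)) {
    cy <- by[i]; cx <- bx[i]
    yy <- round(cy) + off$dy; xx <- round(cx) + off$dx
    ok <- yy >= 1 & yy <= S & xx >= 1 & xx <= S
    if (!any(ok)) next
    d <- sqrt((yy[ok] - cy)^2 + (xx[ok] - cx)^2)
    a <- pmin(pmax(r + 0.5 - d, 0), 1)
    idx <- cbind(yy[ok], xx[ok])
    alpha[idx] <- pmax(alpha[idx], a)
  }
  alpha
}

# hair layer: stroke alpha map plus the truth mask; count only strokes that
# actually marked at least one mask pixel
drawHairLayer <- function(S, nStrokes, widthRange) {
  alpha <- matrix(0, S, S)
  count <- 0L
  for (k in seq_len(nStrokes)) {
    p0 <- c(runif(1, 1, S), runif(1, 1, S))
    ang <- runif(1, 0, 2 * pi)
    len <- runif(1, 0.4, 0.9) * S
    p2 <- p0 + len * c(cos(ang), sin(ang))
    mid <- (p0 + p2) / 2
    perp <- c(-sin(ang), cos(ang)) * runif(1, -S / 4, S / 4)
    p1 <- mid + perp
    w <- runif(1, widthRange[1], widthRange[2])
    before <- sum(alpha > 0.5)
    alpha <- drawStroke(alpha, c(p0[2], p0[1]), c(p1[2], p1[1]),
                        c(p2[2], p2[1]), w, S)
    if (sum(alpha > 0.5) > before) count <- count + 1L
  }
  list(alpha = alpha, mask = alpha > 0.5, count = count)
}

# skin background + one class-conditioned elliptical lesion; returns the
# clean image (double, 0-255) plus the lesion alpha and bounding box
drawLesionImage <- function(cls, cfg) {
  S <- cfg@imageSize
  pal <- cfg@classPalette[[cls]]
  tone <- runif(3, cfg@skinToneLow, cfg@skinToneHigh)
  noise <- valueNoise(S) * 6
  img <- array(0, dim = c(S, S, 3))
  for (ch in 1:3) img[, , ch] <- tone[ch] + noise

  cy <- S / 2 + runif(1, -S / 10, S / 10)
  cx <- S / 2 + runif(1, -S / 10, S / 10)
  a <- runif(1, S / 7, S / 4)
  b <- runif(1, S / 7, S / 4)
  phi <- runif(1, 0, pi)
  nh <- 512L
  th <- seq(0, 2 * pi, length.out = nh + 1L)[-(nh + 1L)]
  m <- rep(1, nh)
  for (k in 2:5) {
    ck <- runif(1, -1, 1); pk <- runif(1, 0, 2 * pi)
    m <- m + pal$irregularity * 0.35 * (ck / k) * sin(k * th + pk)
  }
  m <- pmax(m, 0.35)

  ys <- matrix(rep(seq_len(S), S), S) - cy
  xs <- matrix(rep(seq_len(S), each = S), S) - cx
  u <- (xs * cos(phi) + ys * sin(phi)) / a
  v <- (-xs * sin(phi) + ys * cos(phi)) / b
  rho <- sqrt(u^2 + v^2)
  thp <- atan2(v, u) %% (2 * pi)
  mi <- m[pmin(floor(thp / (2 * pi) * nh) + 1L, nh)]
  alpha <- pmin(pmax((mi - rho) * min(a, b) / 1.5, 0), 1)

  base <- pal$color + runif(3, -pal$spread, pal$spread)
  tex <- valueNoise(S, cells = 16L) * pal$texture * 30
  for (ch in 1:3)
    img[, , ch] <- img[, , ch] * (1 - alpha) + (base[ch] + tex) * alpha

  mask <- alpha > 0.5
  box <- if (any(mask)) {
    rws <- range(which(rowSums(mask) > 0)); cls2 <- range(which(colSums(mask) > 0))
    c(rws[1], cls2[1], rws[2], cls2[2])
  } else c(NA_integer_, NA_integer_, NA_integer_, NA_integer_)
  list(img = img, alpha = alpha, mask = mask, box = box)
}

#' Generate one synthetic dermoscopy image with hair ground truth
#'
#' Draws a skin-tone background, one elliptical lesion whose colour, border
#' irregularity and texture come from the class palette, and (with
#' probability `hairProbability`) dark hair strokes. The hair-free image and
#' the exact stroke mask are returned alongside, so hair detection and
#' inpainting can be scored against ground truth.
#'
#' @param cls one of [lesionClasses()].
#' @param cfg a [SynthConfig-class]; see [synthConfig()].
#' @param seed integer seed; the same `(cls, cfg, seed)` triple always
#'   reproduces byte-identical output.
#' @return List with `image` (a [LabeledImage-class]), `hair` (a
#'   [HairTruth-class]), `clean` (hair-free integer pixel array),
#'   `lesionMask` (logical matrix) and `lesionBox` (`c(y0, x0, y1, x1)`).
#' @export
#' @examples
#' g <- generateImage("Nv", synthConfig(imageSize = 64L), seed = 1)
#' dim(pixels(g$image))
generateImage <- function(cls, cfg = synthConfig(), seed = 1L) {
  if (!is.character(cls) || length(cls) != 1L || !cls %in% lesionClasses())
    stop("unknown lesion class: ", cls)
  validObject(cfg)
  withSeed(seed, {
    S <- cfg@imageSize
    les <- drawLesionImage(cls, cfg)
    img <- les$img
    clean <- array(as.integer(clamp255(round(img))), dim = dim(img))

    hairOn <- runif(1) < cfg@hairProbability
    if (hairOn) {
      n <- if (cfg@hairCountRange[1] == cfg@hairCountRange[2]) cfg@hairCountRange[1]
           else sample(cfg@hairCountRange[1]:cfg@hairCountRange[2], 1L)
      hl <- drawHairLayer(S, n, cfg@hairWidthRange)
      shade <- runif(1, 30, 80)
      hcol <- c(shade, shade * 0.85, shade * 0.7)
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] * (1 - hl$alpha) + hcol[ch] * hl$alpha
      mask <- hl$mask; count <- hl$count
    } else {
      mask <- matrix(FALSE, S, S); count <- 0L
    }
    px <- array(as.integer(clamp255(round(img))), dim = dim(img))
    list(
      image = labeledImage(px, cls, sourceId = sprintf("synth_%s_%d", cls, seed)),
      hair = new("HairTruth", mask = mask, strokeCount = count),
      clean = clean,
      lesionMask = les$mask,
      lesionBox = les$box
    )
  })
}

#' Generate a plain-skin field with planted hair strokes
#'
#' Hair strokes on textured skin with no lesion: the isolation fixture for
#' scoring hair detection (stroke coverage and background false positives).
#'
#' @param cfg a [SynthConfig-class].
#' @param seed integer seed.
#' @param strokes stroke count; defaults to a draw from `hairCountRange`.
#' @return List with `image` (integer array), `hair` (a
#'   [HairTruth-class]) and `clean` (the hair-free skin field).
#' @export
generateHairField <- function(cfg = synthConfig(), seed = 1L, strokes = NULL) {
  validObject(cfg)
  withSeed(seed, {
    S <- cfg@imageSize
    tone <- runif(3, cfg@skinToneLow, cfg@skinToneHigh)
    noise <- valueNoise(S) * 6
    img <- array(0, dim = c(S, S, 3))
    for (ch in 1:3) img[, , ch] <- tone[ch] + noise
    clean <- array(as.integer(clamp255(round(img))), dim = dim(img))
    n <- if (is.null(strokes))
      sample(cfg@hairCountRange[1]:cfg@hairCountRange[2], 1L) else as.integer(strokes)
    hl <- drawHairLayer(S, n, cfg@hairWidthRange)
    shade <- runif(1, 30, 80)
    hcol <- c(shade, shade * 0.85, shade * 0.7)
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] * (1 - hl$alpha) + hcol[ch] * hl$alpha
    list(image = array(as.integer(clamp255(round(img))), dim = dim(img)),
         hair = new("HairTruth", mask = hl$mask, strokeCount = hl$count),
         clean = clean)
  })
}

#' Generate a labelled synthetic dataset
#'
#' Generates `counts[c]` images for each class `c`, each from a per-image
#' seed derived deterministically from `cfg@seed`, and a manifest describing
#' them. When `dir` is given, images are written as PNG files and the
#' manifest as `manifest.csv`.
#'
#' @param counts named integer vector (class -> count); classes absent from
#'   the vector get zero images.
#' @param cfg a [SynthConfig-class].
#' @param dir optional output directory for PNGs and the manifest CSV.
#' @return List with `images` (list of [generateImage()] results) and
#'   `manifest` (data.frame with columns `path`, `class_name`, `class_index`,
#'   `split`, `is_augmented`, `seed`).
#' @export
#' @examples
#' ds <- generateDataset(c(Nv = 2, Mel = 1), synthConfig(imageSize = 48L))
#' table(ds$manifest$class_name)
generateDataset <- function(counts, cfg = synthConfig(), dir = NULL) {
  if (is.null(names(counts)) || !all(names(counts) %in% lesionClasses()))
    stop("counts must be named by lesion classes")
  if (any(counts < 0)) stop("counts must be nonnegative")
  counts <- counts[counts > 0]
  total <- sum(counts)
  seeds <- withSeed(cfg@seed, sample.int(.Machine$integer.max - 1L, max(total, 1L)))
  images <- vector("list", total)
  rows <- vector("list", total)
  i <- 0L
  for (cl in names(counts)) {
    for (k in seq_len(counts[[cl]])) {
      i <- i + 1L
      g <- generateImage(cl, cfg, seed = seeds[i])
      images[[i]] <- g
      path <- sprintf("%s_%04d.png", cl, k)
      rows[[i]] <- data.frame(
        path = path, class_name = cl, class_index = classIndex(cl),
        split = NA_character_, is_augmented = FALSE, seed = seeds[i],
        stringsAsFactors = FALSE
      )
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        EBImage::writeImage(toEBImage(pixels(g$image)), file.path(dir, path))
      }
    }
  }
  manifest <- if (total > 0) do.call(rbind, rows) else
    data.frame(path = character(), class_name = character(),
               class_index = integer(), split = character(),
               is_augmented = logical(), seed = integer())
  manifest$source_id <- vapply(images, function(g) g$image@sourceId, "")[seq_len(nrow(manifest))]
  if (!is.null(dir) && total > 0)
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  list(images = images, manifest = manifest)
}

#' Class counts proportional to the published training distribution
#'
#' Scales the published per-class basic-training counts (Nv 4697, Mel 780,
#' Bkl 771, Bcc 361, Akiec 230, Vasc 100, Df 81) by `scale` and rounds to the
#' nearest integer, preserving the characteristic class imbalance at desk
#' scale.
#'
#' @param scale positive scaling factor (e.g. 0.01).
#' @return Named integer vector in the fixed class order.
#' @export
#' @examples
#' isicScaledCounts(0.01)
isicScaledCounts <- function(scale) {
  stopifnot(scale > 0)
  sc <- isicSplitCounts()
  setNames(as.integer(round(sc$train * scale)), sc$class)
}
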