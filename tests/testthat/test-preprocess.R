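test_that("resizing follows the bilinear contract", {
  set.seed(1)
  big <- array(as.integer(sample(0:255, 600 * 450 * 3, TRUE)),
               dim = c(450L, 600L, 3L))
  out <- resizeImage(big, 224L)
  expect_identical(dim(out), c(224L, 224L, 3L))

  same <- array(as.integer(sample(0:255, 224 * 224 * 3, TRUE)),
                dim = c(224L, 224L, 3L))
  expect_identical(resizeImage(same, 224L), same)

  const <- array(77L, dim = c(2L, 2L, 3L))
  up <- resizeImage(const, 4L)
  expect_true(all(up == 77L))

  expect_error(resizeImage(array(0L, dim = c(0L, 4L, 3L))), "empty")
})

test_that("black-hat detection lights up strokes, not flat or bright areas", {
  flat <- array(128L, dim = c(64L, 64L, 3L))
  expect_identical(sum(detectHairMask(flat, hairRemovalConfig(seSize = 9L))), 0L)

  # near-maximal threshold suppresses everything
  hf <- generateHairField(smallSynthConfig(128L), seed = 3, strokes = 4)
  hi <- hairRemovalConfig(maskThreshold = 254)
  expect_identical(sum(detectHairMask(hf$image, hi)), 0L)

  # planted strokes: high coverage, almost no background response
  m <- detectHairMask(hf$image)
  truth <- hf$hair@mask
  expect_gte(sum(m & truth) / sum(truth), 0.8)
  expect_lte(sum(m & !truth) / sum(!truth), 0.02)

  expect_error(detectHairMask(flat, hairRemovalConfig(seSize = 101L)),
               "larger than the image")
  expect_error(hairRemovalConfig(seSize = 16L), "odd")
  expect_error(hairRemovalConfig(maskThreshold = 0), "maskThreshold")
})

test_that("hair detection is translation-equivariant away from borders", {
  hf <- generateHairField(smallSynthConfig(96L), seed = 5, strokes = 3)
  img <- hf$image
  sh <- array(0L, dim = dim(img))
  sh[6:96, 4:96, ] <- img[1:91, 1:93, ]
  m0 <- detectHairMask(img)
  m1 <- detectHairMask(sh)
  # compare on a deep interior window, shifted identically
  expect_identical(unname(m1[30:70, 30:70]), unname(m0[25:65, 27:67]))
})

test_that("inpainting fills only masked pixels and repairs planted hair", {
  img <- generateImage("Nv", smallSynthConfig(64L, hairProbability = 0),
                       seed = 2)
  px <- pixels(img$image)
  expect_identical(inpaintHair(px, matrix(FALSE, 64, 64)), px)

  const <- array(90L, dim = c(32L, 32L, 3L))
  mask <- matrix(FALSE, 32, 32); mask[10:20, 12:22] <- TRUE
  expect_true(all(inpaintHair(const, mask) == 90L))

  expect_error(inpaintHair(const, matrix(TRUE, 32, 32)), "degenerate")
  expect_error(inpaintHair(const, matrix(FALSE, 16, 16)), "dimensions")

  g <- generateImage("Mel", smallSynthConfig(128L, hairProbability = 1),
                     seed = 4)
  hairy <- pixels(g$image); clean <- g$clean; truth <- g$hair@mask
  det <- detectHairMask(hairy)
  fixed <- inpaintHair(hairy, det, 1)
  # untouched outside the detected mask
  for (ch in 1:3)
    expect_identical(fixed[, , ch][!det], hairy[, , ch][!det])
  maeBefore <- mean(abs(hairy[truth] - clean[truth]))
  maeAfter <- mean(abs(fixed[truth] - clean[truth]))
  expect_lt(maeAfter, maeBefore)
})

test_that("augmentation is seeded, label-preserving, and centre-anchored", {
  s <- smallImageSet(1, classes = "Nv", size = 48L)
  img <- s$images[[1]]
  cfg <- augmentationConfig(outputSize = 48L)
  a1 <- augmentImage(img, cfg, seed = 9)
  a2 <- augmentImage(img, cfg, seed = 9)
  expect_identical(pixels(a1), pixels(a2))
  expect_identical(a1@className, img@className)
  expect_true(a1@isAugmented)

  idcfg <- augmentationConfig(rotationRange = 0, shiftFraction = 0,
                              zoomRange = c(1, 1), shearRange = 0,
                              flipHorizontal = 0, flipVertical = 0,
                              outputSize = 48L)
  expect_identical(pixels(augmentImage(img, idcfg, seed = 1)),
                   resizeImage(pixels(img), 48L))

  # pure rotation keeps a centred disk centred
  disk <- array(235L, dim = c(49L, 49L, 3L))
  mm <- (row(matrix(0, 49, 49)) - 25)^2 + (col(matrix(0, 49, 49)) - 25)^2 <= 100
  for (ch in 1:3) { p <- disk[, , ch]; p[mm] <- 20L; disk[, , ch] <- p }
  rot <- augmentationConfig(rotationRange = 180, shiftFraction = 0,
                            zoomRange = c(1, 1), shearRange = 0,
                            flipHorizontal = 0, flipVertical = 0,
                            outputSize = 49L)
  for (s2 in 1:25) {
    a <- augmentImage(disk, rot, seed = s2)
    g <- 255 - a[, , 1]
    cy <- sum(row(g) * g) / sum(g); cx <- sum(col(g) * g) / sum(g)
    expect_lt(sqrt((cy - 25)^2 + (cx - 25)^2), 1)
  }
})

test_that("stratified splitting partitions each class at the 7:2:1 ratio", {
  m <- data.frame(class_name = rep("Nv", 10), id = 1:10)
  sp <- splitDataset(m, seed = 1)
  expect_identical(as.vector(table(sp$split)[c("train", "test", "val")]),
                   c(7L, 2L, 1L))

  m2 <- data.frame(class_name = rep(c("Mel", "Nv", "Df"), c(13, 29, 5)),
                   id = 1:47)
  sp2 <- splitDataset(m2, seed = 3)
  expect_identical(sort(sp2$id), 1:47)                  # partition: union
  expect_false(any(duplicated(sp2$id)))                 # and disjoint
  for (cl in unique(m2$class_name)) {
    cnt <- table(sp2$split[sp2$class_name == cl])
    expect_identical(sum(cnt), as.integer(sum(m2$class_name == cl)))
  }
  sp2b <- splitDataset(m2, seed = 3)
  expect_identical(sp2, sp2b)                           # reproducible
  sp2c <- splitDataset(m2, seed = 4)
  expect_false(identical(sp2$split, sp2c$split))

  expect_error(splitDataset(m2, ratio = c(7, 2)), "ratio")
  bad <- isicSplitCounts()
  expect_error(splitDataset(m2, overrides = bad), "override")
})

test_that("published division overrides reproduce the printed column totals", {
  tot <- isicClassTotals()
  man <- data.frame(class_name = rep(names(tot), tot))
  sp <- splitDataset(man, seed = 1, overrides = isicSplitCounts())
  tal <- manifestTallies(sp)
  expect_identical(as.integer(colSums(tal)[c("train", "test", "val")]),
                   c(7020L, 1998L, 997L))
  # per-class counts match the override table exactly
  ov <- isicSplitCounts()
  for (i in seq_len(nrow(ov)))
    expect_identical(as.integer(tal[ov$class[i], c("train", "test", "val")]),
                     c(ov$train[i], ov$test[i], ov$val[i]))
})

test_that("balancing appends augmented train rows round-robin to target", {
  man <- data.frame(class_name = rep(c("Nv", "Mel"), c(6, 3)),
                    source_id = paste0("s", 1:9),
                    seed = 1:9, split = "train", is_augmented = FALSE)

  same <- balanceTrainingSet(man, targets = c(Nv = 6, Mel = 3))
  expect_identical(nrow(same), nrow(man))

  bal <- balanceTrainingSet(man, targets = c(Nv = 6, Mel = 10))
  expect_identical(sum(bal$class_name == "Mel"), 10L)
  added <- bal[bal$is_augmented, ]
  expect_true(all(added$split == "train"))
  use <- table(added$source_id)
  expect_lte(diff(range(use)), 1L)                      # round-robin spread
  expect_false(any(added$seed %in% man$seed))           # fresh seeds

  expect_error(balanceTrainingSet(man, targets = c(Nv = 2, Mel = 3)),
               "below its current count")

  # default targets follow the largest class
  def <- balanceTrainingSet(man)
  expect_identical(as.integer(table(def$class_name)[["Mel"]]), 6L)
})

test_that("balancing planner reproduces the published augmented totals", {
  tot <- isicClassTotals()
  man <- data.frame(class_name = rep(names(tot), tot),
                    source_id = paste0("im", seq_len(sum(tot))),
                    seed = seq_len(sum(tot)))
  sp <- splitDataset(man, seed = 1, overrides = isicSplitCounts())
  sp$is_augmented <- FALSE
  bal <- balanceTrainingSet(sp, targets = isicAugmentedTargets(), seed = 1)
  expect_identical(sum(bal$split == "train"), 34946L)
  # only train changed, only by augmented rows
  expect_identical(sum(bal$split == "test"), 1998L)
  expect_identical(sum(bal$split == "val"), 997L)
  expect_identical(sum(bal$is_augmented), 34946L - 7020L)
})
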