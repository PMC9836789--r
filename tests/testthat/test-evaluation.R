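test_that("confusion matrices tally actual x predicted counts", {
  y <- rep(0:6, each = 2)
  cmPerfect <- lesionConfusionMatrix(y, y)
  expect_identical(unname(diag(cmPerfect)), rep(2L, 7))
  expect_identical(sum(cmPerfect), 14L)

  cm <- lesionConfusionMatrix(c(4, 4), c(5, 5))   # Mel predicted as Nv
  expect_identical(cm["Mel", "Nv"], 2L)
  expect_identical(sum(cm), 2L)

  set.seed(1)
  yr <- sample(0:6, 100, TRUE); pr <- sample(0:6, 100, TRUE)
  cmr <- lesionConfusionMatrix(yr, pr)
  expect_identical(sum(cmr), 100L)
  expect_identical(as.integer(rowSums(cmr)),
                   vapply(0:6, function(k) sum(yr == k), 0L))
  expect_error(lesionConfusionMatrix(0:3, 0:2), "equal length")
  expect_error(lesionConfusionMatrix(c(0, 9), c(0, 1)), "labels must lie")
})

test_that("the F1 worked examples reproduce the reported two-decimal values", {
  ref <- referenceVariantMetrics()
  expect_identical(round(f1Score(ref$precision, ref$recall), 2), ref$f1)
  expect_equal(f1Score(80, 80), 80)                  # equal P, R
  expect_identical(f1Score(0, 0), 0)                 # degenerate convention
})

test_that("zero-denominator metrics report 0 and are flagged", {
  cm <- matrix(0L, 7, 7, dimnames = list(lesionClasses(), lesionClasses()))
  cm[2, 3] <- 5L   # class Bcc always predicted as Bkl; nothing predicted Bcc
  met <- classMetrics(cm)
  bcc <- met[met$class == "Bcc", ]
  expect_identical(bcc$precision, 0)
  expect_identical(bcc$recall, 0)
  expect_true(bcc$flagged)
  expect_error(classMetrics(cm * 0L), "empty")
})

test_that("micro averages collapse to accuracy on random label sets", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    y <- sample(0:6, n, TRUE); p <- sample(0:6, n, TRUE)
    met <- classMetrics(lesionConfusionMatrix(y, p))
    mi <- met[met$class == "micro", ]
    acc <- 100 * mean(y == p)
    expect_equal(mi$precision, acc)
    expect_equal(mi$recall, acc)
    expect_equal(mi$f1, acc)
    expect_equal(mi$accuracy, acc)
    per <- met[!met$class %in% c("macro", "micro"), ]
    expect_true(all(per$f1 <= pmax(per$precision, per$recall) + 1e-9))
    expect_true(all(per$f1 >= pmin(per$precision, per$recall) - 1e-9))
  }
})

test_that("AUC equals the Mann-Whitney rank statistic and its invariances", {
  set.seed(5)
  lab <- c(rep(TRUE, 4), rep(FALSE, 6))
  sc <- runif(10)
  r <- DermaFusion:::binaryRoc(lab, sc)
  u <- unname(wilcox.test(sc[lab], sc[!lab], exact = TRUE)$statistic)
  expect_equal(r$auc, u / (4 * 6))
  # invariant under strictly monotone transforms
  r2 <- DermaFusion:::binaryRoc(lab, exp(3 * sc + 1))
  expect_equal(r2$auc, r$auc)
  # chance level for constant scores, 1 for perfect separation
  expect_equal(DermaFusion:::binaryRoc(lab, rep(0.5, 10))$auc, 0.5)
  expect_equal(DermaFusion:::binaryRoc(lab, ifelse(lab, 1, 0))$auc, 1)
  # curves anchored at (0,0) and (1,1)
  expect_identical(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_identical(c(tail(r$fpr, 1), tail(r$tpr, 1)), c(1, 1))
})

test_that("multiclass ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  y <- sample(0:6, 120, TRUE)
  sc <- matrix(runif(120 * 7), 120); sc <- sc / rowSums(sc)
  ra <- rocAuc(y, sc)
  for (k in 0:6) {
    pa <- as.numeric(pROC::auc(pROC::roc(
      response = y == k, predictor = sc[, k + 1],
      direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)))
    expect_equal(unname(ra$aucs[k + 1]), pa, tolerance = 1e-12)
  }
  expect_equal(ra$macro_auc, mean(ra$aucs))
  expect_true(ra$micro_auc >= 0 && ra$micro_auc <= 1)
  # an absent class is excluded from the macro average with a warning
  y2 <- pmin(y, 5L)
  expect_warning(ra2 <- rocAuc(y2, sc), "excluded")
  expect_true(is.na(ra2$aucs["Vasc"]))
  expect_equal(ra2$macro_auc, mean(ra2$aucs[1:6]))
})

test_that("reports assemble, render and difference correctly", {
  y <- rep(0:6, each = 3)
  metPerfect <- classMetrics(lesionConfusionMatrix(y, y))
  expect_true(all(metPerfect$f1 == 100))
  expect_identical(metPerfect$accuracy[metPerfect$class == "micro"], 100)

  ref <- referenceVariantMetrics()
  d <- reportDelta(ref[ref$variant == "improved_vgg16", ],
                   ref[ref$variant == "vgg16", ])
  expect_identical(d$precision, 11.42)
  expect_identical(d$recall, 10.43)
  expect_identical(d$f1, 11)
  expect_identical(d$accuracy, 15.12)
  z <- reportDelta(ref[1, ], ref[1, ])
  expect_true(all(unlist(z) == 0))

  # full report round trip on a small evaluated model (only 2 of 7 classes
  # are present, so the macro-AUC warns about the absent ones)
  s <- smallImageSet(8, classes = c("Mel", "Nv"), size = 32L)
  expect_warning(rep1 <- evaluateModel(tinyClassifier(), s$images, s$labels),
                 "excluded")
  expect_s4_class(rep1, "EvalReport")
  dir <- withr::local_tempdir()
  writeReport(rep1, dir)
  expect_true(all(file.exists(file.path(dir, c("metrics.csv", "confusion.csv",
                                               "roc_points.csv")))))
  dd <- reportDelta(rep1, rep1)
  expect_true(all(unlist(dd) == 0))
})

test_that("Grad-CAM maps are normalised, input-sized, and vanish with the gradient", {
  s <- smallImageSet(1, classes = "Mel", size = 32L)
  m <- tinyClassifier(seed = 77, cache = FALSE)
  cam <- gradCam(m, s$images[[1]], 0L)
  expect_identical(dim(cam), c(32L, 32L))
  expect_true(all(cam >= 0 & cam <= 1))
  # zero the target class's dense weights: zero gradient, all-zero map
  w <- DermaFusion:::netGetWeights(m)
  w$logits$W[, 1] <- 0
  DermaFusion:::netSetWeights(m, w)
  cam0 <- gradCam(m, s$images[[1]], 0L)
  expect_true(all(cam0 == 0))
  expect_error(gradCam(m, s$images[[1]], 0L, layer = "gem"), "spatial")
})
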