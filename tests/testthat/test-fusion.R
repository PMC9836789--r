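test_that("pooling operators satisfy their closed forms", {
  f <- array(c(1, 2, 3, 4), dim = c(2, 2, 1))
  expect_equal(poolMax(f), 4)
  expect_equal(poolAvg(f), 2.5)
  cst <- array(3.7, dim = c(5, 3, 2))
  expect_equal(poolMax(cst), c(3.7, 3.7))
  expect_equal(poolAvg(cst), c(3.7, 3.7))
  expect_equal(poolGeM(f, gemParams(p = 4)), (88.5)^0.25, tolerance = 1e-4)
  spike <- array(c(0, 0, 0, 10), dim = c(2, 2, 1))
  expect_equal(poolGeM(spike, gemParams(p = 64)), 10 * 4^(-1 / 64),
               tolerance = 1e-4)
  expect_gt(poolGeM(spike, gemParams(p = 64)), 0.95 * poolMax(spike))
})

test_that("GeM agrees with a brute-force scalar oracle on random channels", {
  set.seed(42)
  for (i in 1:100) {
    ch <- matrix(runif(49, 0, 5), 7, 7)
    p <- sample(c(2, 3, 4, 5, 8), 1)
    got <- poolGeM(ch, gemParams(p = p))
    want <- 0
    for (v in as.vector(ch)) want <- want + (v + 1e-6)^p   # explicit loop
    want <- (want / 49)^(1 / p)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("GeM interpolates between average and max pooling", {
  set.seed(7)
  for (i in 1:20) {
    f <- array(runif(7 * 7 * 4, 0, 3), dim = c(7, 7, 4))
    avg <- poolAvg(f); mx <- poolMax(f)
    prev <- rep(-Inf, 4)
    for (p in c(1, 2, 3, 4, 5, 8, 16)) {
      g <- poolGeM(f, gemParams(p = p))
      expect_true(all(g >= prev - 1e-8))            # nondecreasing in p
      expect_true(all(g >= avg - 1e-4))             # avg <= GeM
      expect_true(all(g <= mx + 1e-4))              # GeM <= max
      prev <- g
    }
    expect_equal(poolGeM(f, gemParams(p = 1)), avg, tolerance = 1e-4)
  }
})

test_that("pooling is invariant under spatial permutation", {
  set.seed(3)
  f <- array(runif(36), dim = c(6, 6, 1))
  perm <- array(sample(f), dim = dim(f))
  expect_equal(poolMax(f), poolMax(perm))
  expect_equal(poolAvg(f), poolAvg(perm))
  expect_equal(poolGeM(f, gemParams(3)), poolGeM(perm, gemParams(3)))
})

test_that("GeM rejects contract violations", {
  f <- array(c(-1, 2, 3, 4), dim = c(2, 2, 1))
  expect_error(poolGeM(f), "negative activations")
  expect_error(gemParams(p = 0.5), "p must be")
  expect_error(gemParams(eps = 0), "eps")
  expect_error(poolMax(array(0, dim = c(0, 3, 1))), "empty")
})

test_that("multireceptive-field block preserves shape and maps zero to zero", {
  set.seed(1)
  x <- array(runif(7 * 7 * 24), dim = c(7L, 7L, 24L))
  y <- multiReceptiveField(x, branchChannels = 8L, reduceChannels = 8L)
  expect_identical(dim(y), dim(x))
  z <- multiReceptiveField(array(0, dim = c(7L, 7L, 24L)),
                           branchChannels = 8L, reduceChannels = 8L)
  expect_true(all(z == 0))
})

test_that("engine GeM node matches the functional operator", {
  m <- tinyClassifier(inputSize = 32L, gemP = 3)
  set.seed(5)
  x <- array(runif(32 * 32 * 3), dim = c(32L, 32L, 3L, 1L))
  invisible(netForward(m, x))
  feats <- DermaFusion:::nodeOutput(m, "features")[, , , 1]
  gemOut <- DermaFusion:::nodeOutput(m, "gem")[1, 1, , 1]
  expect_equal(gemOut, unname(poolGeM(feats, gemParams(p = 3))),
               tolerance = 1e-5)
})

test_that("assembled classifier emits normalised probabilities", {
  m <- tinyClassifier()
  set.seed(2)
  x <- array(runif(32 * 32 * 3 * 2), dim = c(32L, 32L, 3L, 2L))
  p <- netProbs(m, x)
  expect_identical(dim(p), c(2L, 7L))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-5)
})

test_that("GeM p = 1 head equals an average-pooling head on the same weights", {
  m1 <- tinyClassifier(gemP = 1, seed = 5)
  set.seed(6)
  x <- array(runif(32 * 32 * 3), dim = c(32L, 32L, 3L, 1L))
  logits <- netForward(m1, x)[1, 1, , 1]
  feats <- DermaFusion:::nodeOutput(m1, "features")[, , , 1]
  w <- DermaFusion:::netGetWeights(m1)$logits
  manual <- as.vector(poolAvg(feats) %*% w$W) + w$b
  expect_equal(logits, manual, tolerance = 1e-4)
})

test_that("removing the fusion block strictly reduces parameters", {
  full <- assembleModel("vgg16", inputSize = 32L, seed = 1)
  bare <- assembleModel("vgg16", inputSize = 32L, mrf = FALSE, seed = 1)
  expect_lt(countParameters(bare), countParameters(full))
  expect_identical(bare@variant, "vgg16_no_mrf")
})
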