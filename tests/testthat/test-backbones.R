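test_that("parameter counting matches closed forms on single layers", {
  nd <- DermaFusion:::nd
  spec <- list(input = c(8L, 8L, 3L), nodes = list(
    nd("img", "input"),
    nd("c", "conv", "img", k = 3L, pad = 1L, cout = 8L)
  ))
  m <- DermaFusion:::buildLesionNet(spec)
  expect_identical(countParameters(m), 3 * 3 * 3 * 8 + 8)     # 224

  spec2 <- list(input = c(4L, 4L, 768L), nodes = list(
    nd("img", "input"),
    nd("c", "conv", "img", k = 1L, cout = 768L)
  ))
  m2 <- DermaFusion:::buildLesionNet(spec2)
  expect_identical(countParameters(m2), 768 * 768 + 768)      # 590592
})

test_that("engine and closed-form parameter counts agree on full streams", {
  dn <- buildDenseNetStream(seed = 1)
  vg <- buildResidualVggStream(seed = 1)
  expect_identical(countParameters(dn),
                   DermaFusion:::specParameterCount(dn@spec))
  expect_identical(countParameters(vg),
                   DermaFusion:::specParameterCount(vg@spec))
})

test_that("stage tables encode the published layout and are asserted", {
  dt <- denseNetStageTable()
  expect_identical(dt$c[dt$stage == "dense_block_1"], 256L)
  expect_identical(dt$c[dt$stage == "dense_block_4"], 768L)
  vt <- vggStageTable()
  expect_identical(vt$c[vt$stage == "projection"], 768L)
  # a wrong expectation is caught
  bad <- dt; bad$c[1] <- 999L
  dn <- buildDenseNetStream(seed = 1)
  expect_error(DermaFusion:::assertStageShapes(dn@spec, bad), "built shape")
})

test_that("both streams are spatially aligned and concatenable", {
  shpD <- DermaFusion:::inferShapes(buildDenseNetStream(seed = 1)@spec)
  shpV <- DermaFusion:::inferShapes(buildResidualVggStream(seed = 1)@spec)
  expect_identical(shpD$dn_out, c(7L, 7L, 768L))
  expect_identical(shpV$vg_out, c(7L, 7L, 768L))
})

test_that("streams forward cleanly at reduced input sizes", {
  dn <- buildDenseNetStream(inputSize = 64L, seed = 2)
  out <- netForward(dn, array(0, dim = c(64L, 64L, 3L, 1L)))
  expect_identical(dim(out), c(2L, 2L, 768L, 1L))
  expect_false(anyNA(out))                        # zero input stays finite
  vg <- buildResidualVggStream(inputSize = 64L, seed = 2)
  out2 <- netForward(vg, array(0.5, dim = c(64L, 64L, 3L, 1L)))
  expect_identical(dim(out2), c(2L, 2L, 768L, 1L))
  expect_true(all(is.finite(out2)))
  expect_error(netForward(vg, array(0, dim = c(32L, 32L, 3L, 1L))),
               "input shape mismatch")
})

test_that("zeroed block convs reduce a residual block to its skip path", {
  vg <- buildResidualVggStream(inputSize = 64L, seed = 3)
  w <- DermaFusion:::netGetWeights(vg)
  for (nm in c("vg_b1_c1", "vg_b1_c2")) {
    w[[nm]]$W[] <- 0; w[[nm]]$b[] <- 0
  }
  DermaFusion:::netSetWeights(vg, w)
  set.seed(4)
  x <- array(runif(64 * 64 * 3), dim = c(64L, 64L, 3L, 1L))
  invisible(netForward(vg, x))
  skip <- DermaFusion:::nodeOutput(vg, "vg_b1_skip")[, , , 1]
  merged <- DermaFusion:::nodeOutput(vg, "vg_b1_merge")[, , , 1]
  expect_equal(merged, pmax(skip, 0), tolerance = 1e-6)
})

test_that("residual skips add parameters; removing them is a strict drop", {
  res <- buildResidualVggStream(inputSize = 64L, seed = 1)
  plain <- buildResidualVggStream(inputSize = 64L, seed = 1, residual = FALSE)
  expect_lt(countParameters(plain), countParameters(res))
})

test_that("the residual stream alone is far smaller than FC-bearing VGG-16", {
  vg <- buildResidualVggStream(seed = 1)
  # classic VGG-16's three dense layers alone: 7*7*512*4096 + 4096^2 + 4096*1000
  fcParams <- 7 * 7 * 512 * 4096 + 4096 * 4096 + 4096 * 1000
  expect_lt(countParameters(vg), fcParams)
})

test_that("stream summaries mirror the layout tables", {
  dn <- buildDenseNetStream(seed = 1)
  sm <- streamSummary(dn)
  expect_true(all(c("node", "operator", "output") %in% names(sm)))
  expect_identical(sm$output[sm$node == "dn_out"], "7 x 7 x 768")
  expect_match(sm$operator[sm$node == "dn_stem_conv"], "7x7 conv")
})
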