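# The network engine is hand-rolled, so its backward pass is validated
# against central finite differences on a graph that exercises every layer
# type (conv with/without bias, batch norm, ReLU, max/avg pooling, channel
# concat, residual add, GeM, dense).

gradCheckSpec <- function() {
  nd <- DermaFusion:::nd
  list(input = c(8L, 8L, 3L), nodes = list(
    nd("img", "input"),
    nd("c1", "conv", "img", k = 3L, pad = 1L, cout = 4L),
    nd("bn1", "bn", "c1"),
    nd("r1", "relu", "bn1"),
    nd("c2", "conv", "r1", k = 1L, cout = 4L, bias = FALSE),
    nd("add1", "add", c("r1", "c2")),
    nd("cat1", "concat", c("add1", "r1")),
    nd("mp", "maxpool", "cat1", k = 2L, stride = 2L),
    nd("ap", "avgpool", "mp", k = 2L, stride = 2L),
    nd("rl2", "relu", "ap"),
    nd("gem", "gem", "rl2", p = 3, eps = 1e-6),
    nd("out", "dense", "gem", cout = 3L)
  ))
}

test_that("backpropagation matches finite differences on every layer type", {
  spec <- gradCheckSpec()
  net <- DermaFusion:::buildLesionNet(spec, seed = 42)
  set.seed(7)
  x <- array(runif(8 * 8 * 3 * 2), dim = c(8L, 8L, 3L, 2L))
  y <- c(0L, 2L)
  w0 <- DermaFusion:::eng_get_weights(net@ptr)
  an <- DermaFusion:::eng_loss_grads(net@ptr, x, y)
  lossWith <- function(w) {
    p <- DermaFusion:::eng_build(spec)
    DermaFusion:::eng_set_weights(p, w)
    DermaFusion:::eng_loss_grads(p, x, y)$loss
  }
  h <- 1e-3
  for (nodeName in names(an$grads)) {
    g <- an$grads[[nodeName]]
    for (fld in names(g)) {
      tgt <- sub("^d", "", fld)
      vals <- w0[[nodeName]][[tgt]]
      set.seed(nchar(nodeName) + nchar(fld))
      for (j in sample(seq_along(vals), min(4, length(vals)))) {
        wp <- w0; wp[[nodeName]][[tgt]][j] <- vals[j] + h
        wm <- w0; wm[[nodeName]][[tgt]][j] <- vals[j] - h
        fd <- (lossWith(wp) - lossWith(wm)) / (2 * h)
        anv <- g[[fld]][j]
        # float32 forward: absolute floor absorbs FD noise near zero
        expect_lt(abs(fd - anv), 0.002 + 0.05 * (abs(fd) + abs(anv)))
      }
    }
  }
})

test_that("training steps are deterministic and reduce the loss", {
  spec <- gradCheckSpec()
  run <- function() {
    net <- DermaFusion:::buildLesionNet(spec, seed = 11)
    set.seed(3)
    x <- array(runif(8 * 8 * 3 * 4), dim = c(8L, 8L, 3L, 4L))
    y <- c(0L, 1L, 2L, 0L)
    losses <- vapply(1:80, function(i)
      DermaFusion:::eng_train_step(net@ptr, x, y, 1e-2)$loss, 0)
    losses
  }
  l1 <- run(); l2 <- run()
  expect_identical(l1, l2)
  expect_lt(tail(l1, 1), min(0.5, l1[1]))
})

test_that("the engine rejects malformed graphs and inputs", {
  nd <- DermaFusion:::nd
  expect_error(DermaFusion:::eng_build(list(input = c(4L, 4L, 3L), nodes = list(
    nd("img", "input"), nd("c", "conv", "img", k = 9L, cout = 2L)
  ))), "kernel exceeds")
  expect_error(DermaFusion:::eng_build(list(input = c(4L, 4L, 3L), nodes = list(
    nd("img", "input"), nd("d", "dense", "img", cout = 2L)
  ))), "pooled")
  expect_error(DermaFusion:::eng_build(list(input = c(4L, 4L, 3L), nodes = list(
    nd("img", "input"), nd("g", "gem", "img", p = 0.5)
  ))), "p must be")
  m <- tinyClassifier()
  expect_error(DermaFusion:::eng_forward(m@ptr, array(0, c(4L, 4L, 3L, 1L)), FALSE),
               "shape mismatch")
})

test_that("checkpoints round-trip weights and running statistics", {
  m <- tinyClassifier(seed = 9, cache = FALSE)
  set.seed(1)
  x <- array(runif(32 * 32 * 3 * 4), dim = c(32L, 32L, 3L, 4L))
  for (i in 1:3)
    DermaFusion:::eng_train_step(m@ptr, x, c(0L, 1L, 2L, 3L), 1e-3)
  p1 <- netProbs(m, x)
  path <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(m, path)
  m2 <- loadCheckpoint(path)
  expect_equal(netProbs(m2, x), p1, tolerance = 1e-7)
  expect_identical(m2@classes, m@classes)
  expect_error(loadCheckpoint(withr::local_tempfile(fileext = ".rds")),
               "checkpoint")
})
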