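# The two feature streams. Both take a 224x224x3 image and emit a spatially
# aligned 7x7x768 feature map, so channel concatenation gives the 1536
# channels the fusion head expects.
#
# DenseNet-121 stream: 7x7/2 stem conv, 3x3/2 max pool, four dense blocks of
# 6/12/24/16 BN-ReLU-1x1 / BN-ReLU-3x3 bottleneck pairs with 0.5-compression
# transitions. Blocks 1-3 use growth 32; block 4 uses growth 16, so the final
# map is natively 512 + 16*16 = 768 channels and the stage table
# (56x56x256, 28x28x512, 14x14x1024, 7x7x768) is reproduced exactly.
#
# Residual VGG-16 stream: the five canonical conv blocks (2,2,3,3,3 convs at
# 64,128,256,512,512 channels, each followed by 2x2 max pooling) with one
# wrap-around skip per block — identity when channels match, 1x1 projection
# otherwise — merged by elementwise addition + ReLU, and a final 1x1
# channel-matching conv to 768.

denseNetStreamNodes <- function(input = "img", prefix = "dn",
                                layers = c(6L, 12L, 24L, 16L),
                                growth = c(32L, 32L, 32L, 16L),
                                compression = 0.5) {
  nm <- function(...) paste0(prefix, "_", paste0(...))
  nodes <- list(
    nd(nm("stem_conv"), "conv", input, k = 7L, stride = 2L, pad = 3L,
       cout = 64L, bias = FALSE),
    nd(nm("stem_bn"), "bn", nm("stem_conv")),
    nd(nm("stem_relu"), "relu", nm("stem_bn")),
    nd(nm("pool0"), "maxpool", nm("stem_relu"), k = 3L, stride = 2L, pad = 1L)
  )
  cur <- nm("pool0")
  ch <- 64L
  for (b in seq_along(layers)) {
    g <- growth[b]
    for (l in seq_len(layers[b])) {
      id <- nm("b", b, "_l", l)
      nodes <- c(nodes, list(
        nd(paste0(id, "_bn1"), "bn", cur),
        nd(paste0(id, "_r1"), "relu", paste0(id, "_bn1")),
        nd(paste0(id, "_c1"), "conv", paste0(id, "_r1"), k = 1L,
           cout = 4L * g, bias = FALSE),
        nd(paste0(id, "_bn2"), "bn", paste0(id, "_c1")),
        nd(paste0(id, "_r2"), "relu", paste0(id, "_bn2")),
        nd(paste0(id, "_c2"), "conv", paste0(id, "_r2"), k = 3L, pad = 1L,
           cout = g, bias = FALSE),
        nd(paste0(id, "_cat"), "concat", c(cur, paste0(id, "_c2")))
      ))
      cur <- paste0(id, "_cat")
      ch <- ch + g
    }
    if (b < length(layers)) {
      ch2 <- as.integer(ch * compression)
      id <- nm("t", b)
      nodes <- c(nodes, list(
        nd(paste0(id, "_bn"), "bn", cur),
        nd(paste0(id, "_r"), "relu", paste0(id, "_bn")),
        nd(paste0(id, "_c"), "conv", paste0(id, "_r"), k = 1L, cout = ch2,
           bias = FALSE),
        nd(paste0(id, "_pool"), "avgpool", paste0(id, "_c"), k = 2L, stride = 2L)
      ))
      cur <- paste0(id, "_pool")
      ch <- ch2
    }
  }
  nodes <- c(nodes, list(
    nd(nm("bn_final"), "bn", cur),
    nd(nm("out"), "relu", nm("bn_final"))
  ))
  nodes
}

residualVggStreamNodes <- function(input = "img", prefix = "vg",
                                   widths = c(64L, 128L, 256L, 512L, 512L),
                                   nconvs = c(2L, 2L, 3L, 3L, 3L),
                                   projectTo = 768L, residual = TRUE) {
  nm <- function(...) paste0(prefix, "_", paste0(...))
  nodes <- list()
  cur <- input
  ch <- 3L
  for (b in seq_along(widths)) {
    w <- widths[b]
    blockIn <- cur
    for (j in seq_len(nconvs[b])) {
      cnv <- nm("b", b, "_c", j)
      nodes <- c(nodes, list(nd(cnv, "conv", cur, k = 3L, pad = 1L, cout = w)))
      cur <- cnv
      lastConv <- j == nconvs[b]
      if (!lastConv || !residual) {
        rl <- nm("b", b, "_r", j)
        nodes <- c(nodes, list(nd(rl, "relu", cur)))
        cur <- rl
      }
    }
    if (residual) {
      if (ch == w) {
        skip <- blockIn  # identity mapping: channels already match
      } else {
        skip <- nm("b", b, "_skip")
        nodes <- c(nodes, list(nd(skip, "conv", blockIn, k = 1L, cout = w)))
      }
      nodes <- c(nodes, list(
        nd(nm("b", b, "_add"), "add", c(cur, skip)),
        nd(nm("b", b, "_merge"), "relu", nm("b", b, "_add"))
      ))
      cur <- nm("b", b, "_merge")
    }
    nodes <- c(nodes, list(nd(nm("b", b, "_pool"), "maxpool", cur, k = 2L,
                              stride = 2L)))
    cur <- nm("b", b, "_pool")
    ch <- w
  }
  if (!is.null(projectTo) && projectTo != ch) {
    nodes <- c(nodes, list(
      nd(nm("proj"), "conv", cur, k = 1L, cout = as.integer(projectTo)),
      nd(nm("out"), "relu", nm("proj"))
    ))
  } else {
    nodes <- c(nodes, list(nd(nm("out"), "relu", cur)))
  }
  nodes
}

#' Expected stage shapes of the DenseNet-121 stream
#'
#' @param inputSize input side length.
#' @return data.frame with columns `stage`, `node`, `h`, `w`, `c`.
#' @export
denseNetStageTable <- function(inputSize = 224L) {
  s <- inputSize
  data.frame(
    stage = c("convolution", "pooling", "dense_block_1", "transition_1",
              "dense_block_2", "transition_2", "dense_block_3",
              "transition_3", "dense_block_4"),
    node = c("dn_stem_conv", "dn_pool0", "dn_b1_l6_cat", "dn_t1_pool",
             "dn_b2_l12_cat", "dn_t2_pool", "dn_b3_l24_cat", "dn_t3_pool",
             "dn_out"),
    h = c(s / 2, s / 4, s / 4, s / 8, s / 8, s / 16, s / 16, s / 32, s / 32),
    w = c(s / 2, s / 4, s / 4, s / 8, s / 8, s / 16, s / 16, s / 32, s / 32),
    c = c(64L, 64L, 256L, 128L, 512L, 256L, 1024L, 512L, 768L),
    stringsAsFactors = FALSE
  )
}

#' Expected stage shapes of the residual VGG-16 stream
#'
#' Only the internally consistent stages of the published layout are
#' asserted; the final map is the 768-channel 7x7 output.
#'
#' @param inputSize input side length.
#' @return data.frame with columns `stage`, `node`, `h`, `w`, `c`.
#' @export
vggStageTable <- function(inputSize = 224L) {
  s <- inputSize
  data.frame(
    stage = c("vgg_block_1", "pooling_1", "vgg_block_2", "pooling_2",
              "vgg_block_3", "pooling_3", "vgg_block_4", "pooling_4",
              "vgg_block_5", "pooling_5", "projection"),
    node = c("vg_b1_merge", "vg_b1_pool", "vg_b2_merge", "vg_b2_pool",
             "vg_b3_merge", "vg_b3_pool", "vg_b4_merge", "vg_b4_pool",
             "vg_b5_merge", "vg_b5_pool", "vg_out"),
    h = c(s, s / 2, s / 2, s / 4, s / 4, s / 8, s / 8, s / 16, s / 16,
          s / 32, s / 32),
    w = c(s, s / 2, s / 2, s / 4, s / 4, s / 8, s / 8, s / 16, s / 16,
          s / 32, s / 32),
    c = c(64L, 64L, 128L, 128L, 256L, 256L, 512L, 512L, 512L, 512L, 768L),
    stringsAsFactors = FALSE
  )
}

assertStageShapes <- function(spec, table) {
  shp <- inferShapes(spec)
  for (i in seq_len(nrow(table))) {
    nodeName <- table$node[i]
    if (!nodeName %in% names(shp)) stop("missing stage node: ", nodeName)
    got <- shp[[nodeName]]
    want <- c(table$h[i], table$w[i], table$c[i])
    if (!all(got == want))
      stop(sprintf("stage '%s' (%s): built shape %s, expected %s",
                   table$stage[i], nodeName, paste(got, collapse = "x"),
                   paste(want, collapse = "x")))
  }
  invisible(TRUE)
}

#' Build the DenseNet-121 feature stream
#'
#' Stem 7x7/2 conv and 3x3/2 pool, dense blocks of 6/12/24/16 bottleneck
#' (1x1 then 3x3) conv pairs with 0.5-compression transitions, ending in a
#' 7x7x768 feature map; no classification head. Every stage shape of the
#' published layout is asserted at build time.
#'
#' @param inputSize input side length (default 224).
#' @param seed weight-initialisation seed.
#' @return a [LesionNet-class] whose terminal node is the feature map.
#' @export
buildDenseNetStream <- function(inputSize = 224L, seed = 1L) {
  spec <- list(input = c(inputSize, inputSize, 3L),
               nodes = c(list(nd("img", "input")), denseNetStreamNodes("img")))
  if (inputSize == 224L) assertStageShapes(spec, denseNetStageTable())
  buildLesionNet(spec, variant = "densenet121_stream", seed = seed)
}

#' Build the residual-augmented VGG-16 feature stream
#'
#' Five VGG conv blocks (2,2,3,3,3 convs; widths 64,128,256,512,512) each
#' wrapped by a skip connection (identity when channels match, 1x1 projection
#' otherwise) merged by addition + ReLU before 2x2 max pooling, and a final
#' 1x1 channel-matching conv to the 768-channel 7x7 output. `residual =
#' FALSE` gives the plain VGG-16 stream (ablation).
#'
#' @param inputSize input side length (default 224).
#' @param seed weight-initialisation seed.
#' @param residual include the per-block skip connections.
#' @return a [LesionNet-class] whose terminal node is the feature map.
#' @export
buildResidualVggStream <- function(inputSize = 224L, seed = 1L,
                                   residual = TRUE) {
  spec <- list(input = c(inputSize, inputSize, 3L),
               nodes = c(list(nd("img", "input")),
                         residualVggStreamNodes("img", residual = residual)))
  if (inputSize == 224L && residual) assertStageShapes(spec, vggStageTable())
  buildLesionNet(spec, variant = if (residual) "improved_vgg16_stream"
                 else "vgg16_stream", seed = seed)
}

#' Text summary of a model's stages
#'
#' One row per node with its operator and output size, for diffing against
#' the published layout tables.
#'
#' @param model a [LesionNet-class].
#' @return data.frame with columns `node`, `operator`, `output`.
#' @export
streamSummary <- function(model) {
  shp <- inferShapes(model@spec)
  data.frame(
    node = vapply(model@spec$nodes, `[[`, "", "name"),
    operator = vapply(model@spec$nodes, function(n) {
      if (n$op == "conv") sprintf("%dx%d conv", n$k %||% 3L, n$k %||% 3L)
      else n$op
    }, ""),
    output = vapply(model@spec$nodes, function(n)
      paste(shp[[n$name]], collapse = " x "), ""),
    stringsAsFactors = FALSE
  )
}
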