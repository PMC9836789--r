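# Fusion head: multireceptive-field block over the concatenated streams,
# generalized-mean (GeM) pooling, and the softmax classifier. The functional
# pooling operators are also exported on plain arrays, with channel k pooled
# over its spatial activation set X_k:
#   max pooling      H_k = max_{x in X_k} x
#   average pooling  H_k = (1/|X_k|) sum x
#   GeM pooling      H_k = ((1/|X_k|) sum x^p)^(1/p)

asFeatureMap <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("feature map must be an H x W x C array")
  if (any(dim(x)[1:2] < 1L)) stop("feature map has empty spatial extent")
  x
}

#' Global pooling of a feature map
#'
#' Reduce an H x W x C feature map to a length-C vector, one value per
#' channel: the spatial maximum (`poolMax`), the spatial mean (`poolAvg`),
#' or the generalized mean (`poolGeM`), the p-power mean of the activations
#' (shifted by the small guard `eps`). GeM interpolates between average
#' pooling (p = 1) and max pooling (p -> Inf): for nonnegative input every
#' GeM value lies between the average- and max-pooled values, and it is
#' nondecreasing in p.
#'
#' @param x H x W x C array (a matrix is treated as a single channel).
#' @param g a [GeMParams-class]; see [gemParams()]. The default exponent is
#'   the published optimum p = 4.
#' @return numeric vector of length C.
#' @export
#' @examples
#' f <- array(c(1, 2, 3, 4), dim = c(2, 2, 1))
#' poolMax(f)            # 4
#' poolAvg(f)            # 2.5
#' poolGeM(f, gemParams(p = 4))  # ((1+16+81+256)/4)^(1/4)
poolMax <- function(x) {
  x <- asFeatureMap(x)
  apply(x, 3, max)
}

#' @rdname poolMax
#' @export
poolAvg <- function(x) {
  x <- asFeatureMap(x)
  apply(x, 3, mean)
}

#' @rdname poolMax
#' @export
poolGeM <- function(x, g = gemParams()) {
  x <- asFeatureMap(x)
  validObject(g)
  if (min(x) < 0)
    stop("negative activations violate the post-ReLU contract of GeM pooling")
  if (is.infinite(g@p)) return(apply(x, 3, max))
  apply(x + g@eps, 3, function(ch) mean(ch^g@p)^(1 / g@p))
}

# multireceptive-field node set: per kernel a 1x1 reduction then the k x k
# same-padded conv (Inception-style bottleneck), channel concatenation, and
# the closing 1x1 conv + ReLU restoring `outChannels`
mrfNodes <- function(input, prefix = "mrf", kernels = c(3L, 5L, 7L),
                     branchChannels = 64L, reduceChannels = 64L,
                     outChannels = 1536L) {
  nodes <- list()
  tips <- character()
  for (k in kernels) {
    rid <- sprintf("%s_k%d_reduce", prefix, k)
    rrl <- sprintf("%s_k%d_rrelu", prefix, k)
    cid <- sprintf("%s_k%d_conv", prefix, k)
    crl <- sprintf("%s_k%d_relu", prefix, k)
    nodes <- c(nodes, list(
      nd(rid, "conv", input, k = 1L, cout = as.integer(reduceChannels)),
      nd(rrl, "relu", rid),
      nd(cid, "conv", rrl, k = as.integer(k), pad = as.integer((k - 1) / 2),
         cout = as.integer(branchChannels)),
      nd(crl, "relu", cid)
    ))
    tips <- c(tips, crl)
  }
  nodes <- c(nodes, list(
    nd(paste0(prefix, "_concat"), "concat", tips),
    nd(paste0(prefix, "_1x1"), "conv", paste0(prefix, "_concat"), k = 1L,
       cout = as.integer(outChannels)),
    nd("features", "relu", paste0(prefix, "_1x1"))
  ))
  nodes
}

#' Apply a multireceptive-field block to a feature map
#'
#' Parallel same-padded convolutions with different kernel sizes (default
#' 3x3, 5x5, 7x7, each behind a 1x1 channel reduction), channel
#' concatenation, and a closing 1x1 convolution + ReLU that restores the
#' input channel count. Weights are He-initialised from `seed`; use
#' [assembleModel()] for the trained setting.
#'
#' @param x H x W x C array (H, W >= max kernel with same-padding support).
#' @param kernels odd kernel sizes of the parallel branches.
#' @param branchChannels,reduceChannels branch widths.
#' @param seed weight seed.
#' @return H x W x C array.
#' @export
multiReceptiveField <- function(x, kernels = c(3L, 5L, 7L),
                                branchChannels = 64L, reduceChannels = 64L,
                                seed = 1L) {
  x <- asFeatureMap(x)
  d <- dim(x)
  spec <- list(input = c(d[1], d[2], d[3]),
               nodes = c(list(nd("f", "input")),
                         mrfNodes("f", kernels = kernels,
                                  branchChannels = branchChannels,
                                  reduceChannels = reduceChannels,
                                  outChannels = d[3])))
  net <- buildLesionNet(spec, variant = "mrf_block", seed = seed)
  out <- eng_forward(net@ptr, array(x, dim = c(d, 1L)), FALSE)
  array(out[, , , 1], dim = d)
}

#' Assemble a lesion classifier
#'
#' Builds one of the architecture variants: the full two-stream model
#' (DenseNet-121 stream + residual VGG-16 stream, channel concatenation to
#' 1536), or a single-stream ablation. The head applies the
#' multireceptive-field block (unless `mrf = FALSE`), GeM pooling with
#' exponent `gemP`, and a dense softmax layer over the seven classes.
#'
#' @param variant `"two_stream"`, `"densenet121"`, `"improved_vgg16"` or
#'   `"vgg16"` (plain VGG stream, no residual skips).
#' @param inputSize input side length (default 224).
#' @param gemP GeM pooling exponent (default 4; `1` is average pooling,
#'   `Inf` max pooling).
#' @param gemEps numerical guard added before exponentiation.
#' @param mrf include the multireceptive-field block (`FALSE` for the "(-)"
#'   ablation).
#' @param mrfKernels,branchChannels,reduceChannels fusion-block widths.
#' @param nClasses number of output classes.
#' @param seed weight-initialisation seed.
#' @return a [LesionNet-class] classifier; its terminal node emits logits
#'   and [netProbs()] returns softmax probabilities.
#' @export
#' @examples
#' m <- assembleModel("two_stream", inputSize = 64L, seed = 1)
#' countParameters(m)
assembleModel <- function(variant = c("two_stream", "densenet121",
                                      "improved_vgg16", "vgg16"),
                          inputSize = 224L, gemP = 4, gemEps = 1e-6,
                          mrf = TRUE, mrfKernels = c(3L, 5L, 7L),
                          branchChannels = 64L, reduceChannels = 64L,
                          nClasses = 7L, seed = 1L) {
  variant <- match.arg(variant)
  if (!is.infinite(gemP) && gemP < 1) stop("gemP must be >= 1")
  inputSize <- as.integer(inputSize)
  nodes <- list(nd("img", "input"))
  streams <- character()
  if (variant %in% c("two_stream", "densenet121")) {
    nodes <- c(nodes, denseNetStreamNodes("img"))
    streams <- c(streams, "dn_out")
  }
  if (variant %in% c("two_stream", "improved_vgg16", "vgg16")) {
    nodes <- c(nodes, residualVggStreamNodes("img",
                                             residual = variant != "vgg16"))
    streams <- c(streams, "vg_out")
  }
  nodes <- c(nodes, list(nd("fuse_concat", "concat", streams)))
  spec0 <- list(input = c(inputSize, inputSize, 3L), nodes = nodes)
  cin <- inferShapes(spec0)[["fuse_concat"]][3]
  if (length(streams) == 2L) {
    shp <- inferShapes(spec0)
    s1 <- shp[[streams[1]]]; s2 <- shp[[streams[2]]]
    if (!all(s1 == s2))
      stop("stream outputs misaligned: ", paste(s1, collapse = "x"), " vs ",
           paste(s2, collapse = "x"))
  }
  if (mrf) {
    nodes <- c(nodes, mrfNodes("fuse_concat", kernels = mrfKernels,
                               branchChannels = branchChannels,
                               reduceChannels = reduceChannels,
                               outChannels = cin))
  } else {
    nodes <- c(nodes, list(nd("features", "concat", "fuse_concat")))
  }
  nodes <- c(nodes, list(
    nd("gem", "gem", "features", p = gemP, eps = gemEps),
    nd("logits", "dense", "gem", cout = as.integer(nClasses))
  ))
  spec <- list(input = c(inputSize, inputSize, 3L), nodes = nodes)
  label <- if (mrf) variant else paste0(variant, "_no_mrf")
  buildLesionNet(spec, classes = lesionClasses()[seq_len(nClasses)],
                 variant = label, gemP = gemP, seed = seed)
}
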