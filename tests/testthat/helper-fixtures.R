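# Shared fixtures, built once per test run.

fixtures <- new.env(parent = emptyenv())

# small synthetic config for fast tests
smallSynthConfig <- function(size = 64L, hairProbability = 0.5) {
  synthConfig(imageSize = as.integer(size), hairProbability = hairProbability)
}

# a tiny convolutional classifier (not the full two-stream model) for cheap
# training / evaluation / service tests
tinyClassifier <- function(inputSize = 32L, nClasses = 7L, seed = 1L,
                           gemP = 4, cache = TRUE) {
  key <- sprintf("tiny_%d_%d_%d_%s", inputSize, nClasses, seed, gemP)
  if (cache && !is.null(fixtures[[key]])) return(fixtures[[key]])
  nd <- DermaFusion:::nd
  spec <- list(input = c(inputSize, inputSize, 3L), nodes = list(
    nd("img", "input"),
    nd("c1", "conv", "img", k = 3L, pad = 1L, stride = 2L, cout = 8L),
    nd("r1", "relu", "c1"),
    nd("c2", "conv", "r1", k = 3L, pad = 1L, stride = 2L, cout = 16L),
    nd("bn2", "bn", "c2"),
    nd("r2", "relu", "bn2"),
    nd("features", "concat", "r2"),
    nd("gem", "gem", "features", p = gemP, eps = 1e-6),
    nd("logits", "dense", "gem", cout = as.integer(nClasses))
  ))
  m <- DermaFusion:::buildLesionNet(spec,
                                    classes = lesionClasses()[seq_len(nClasses)],
                                    variant = "tiny", gemP = gemP, seed = seed)
  if (cache) fixtures[[key]] <- m
  m
}

# a deterministic "constant probability" classifier: zero weights, dense bias
# set so softmax output equals `probs` for every input
constantClassifier <- function(probs, inputSize = 32L) {
  m <- tinyClassifier(inputSize, nClasses = length(probs), seed = 1L,
                      cache = FALSE)
  w <- DermaFusion:::netGetWeights(m)
  for (nm in names(w)) {
    for (fld in c("W", "b")) {
      if (!is.null(w[[nm]][[fld]])) w[[nm]][[fld]][] <- 0
    }
    if (!is.null(w[[nm]][["gamma"]])) w[[nm]][["gamma"]][] <- 1
  }
  w[["logits"]][["b"]] <- log(probs)
  DermaFusion:::netSetWeights(m, w)
  m
}

# small labelled image set with lesion boxes
smallImageSet <- function(n, classes = c("Mel", "Nv"), size = 32L,
                          seedBase = 100L) {
  imgs <- list(); labs <- integer(0); boxes <- list()
  cfg <- smallSynthConfig(size, hairProbability = 0)
  for (i in seq_len(n)) {
    cl <- classes[(i - 1) %% length(classes) + 1]
    g <- generateImage(cl, cfg, seed = seedBase + i)
    imgs[[i]] <- g$image
    labs[i] <- classIndex(cl)
    boxes[[i]] <- g$lesionBox
  }
  list(images = imgs, labels = labs, boxes = boxes)
}
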