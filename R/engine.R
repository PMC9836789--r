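# R-side interface to the native network graph: spec construction, seeded
# weight initialisation, shape inference, forward/evaluation helpers and
# checkpointing. A graph spec is list(input = c(H, W, C), nodes = list(...))
# where each node is a list with name, op, inputs and op parameters; nodes
# must be listed in topological order.

nd <- function(name, op, inputs = NULL, ...) {
  out <- list(name = name, op = op, ...)
  if (!is.null(inputs)) out$inputs <- inputs
  out
}

# replicate the engine's shape inference so stage shapes can be asserted and
# parameter counts cross-checked without touching native code
inferShapes <- function(spec) {
  shp <- list()
  res <- list()
  for (n in spec$nodes) {
    s <- switch(n$op,
      input = spec$input,
      conv = {
        p <- shp[[n$inputs[1]]]
        k <- n$k %||% 3L; st <- n$stride %||% 1L; pd <- n$pad %||% 0L
        c(floor((p[1] + 2 * pd - k) / st) + 1L,
          floor((p[2] + 2 * pd - k) / st) + 1L, n$cout %||% p[3])
      },
      maxpool = ,
      avgpool = {
        p <- shp[[n$inputs[1]]]
        k <- n$k %||% 2L; st <- n$stride %||% k; pd <- n$pad %||% 0L
        c(floor((p[1] + 2 * pd - k) / st) + 1L,
          floor((p[2] + 2 * pd - k) / st) + 1L, p[3])
      },
      bn = ,
      relu = shp[[n$inputs[1]]],
      concat = {
        ins <- lapply(n$inputs, function(i) shp[[i]])
        c(ins[[1]][1], ins[[1]][2], sum(vapply(ins, function(v) v[3], 0)))
      },
      add = shp[[n$inputs[1]]],
      gem = c(1L, 1L, shp[[n$inputs[1]]][3]),
      dense = c(1L, 1L, n$cout),
      stop("unknown op ", n$op)
    )
    shp[[n$name]] <- as.integer(s)
  }
  shp
}

# closed-form trainable parameter count from a spec (engine-independent)
specParameterCount <- function(spec) {
  shp <- inferShapes(spec)
  total <- 0
  for (n in spec$nodes) {
    if (n$op == "conv") {
      cin <- shp[[n$inputs[1]]][3]
      k <- n$k %||% 3L
      total <- total + k * k * cin * n$cout +
        (if (isTRUE(n$bias) || is.null(n$bias)) n$cout else 0)
    } else if (n$op == "dense") {
      total <- total + shp[[n$inputs[1]]][3] * n$cout + n$cout
    } else if (n$op == "bn") {
      total <- total + 2 * shp[[n$inputs[1]]][3]
    }
  }
  total
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# He-normal initialisation of all conv/dense weights, drawn from one seeded
# stream in node order
initNetWeights <- function(spec, ptr, seed) {
  shp <- inferShapes(spec)
  w <- list()
  withSeed(seed, {
    for (n in spec$nodes) {
      if (n$op == "conv") {
        cin <- shp[[n$inputs[1]]][3]
        k <- n$k %||% 3L
        fan <- k * k * cin
        W <- matrix(rnorm(fan * n$cout, sd = sqrt(2 / fan)), fan, n$cout)
        e <- list(W = W)
        if (isTRUE(n$bias) || is.null(n$bias)) e$b <- numeric(n$cout)
        w[[n$name]] <- e
      } else if (n$op == "dense") {
        cin <- shp[[n$inputs[1]]][3]
        W <- matrix(rnorm(cin * n$cout, sd = sqrt(2 / cin)), cin, n$cout)
        w[[n$name]] <- list(W = W, b = numeric(n$cout))
      }
    }
  })
  eng_set_weights(ptr, w)
  invisible(w)
}

buildLesionNet <- function(spec, classes = character(), variant = "custom",
                           gemP = NA_real_, seed = 1L) {
  ptr <- eng_build(spec)
  initNetWeights(spec, ptr, seed)
  new("LesionNet", ptr = ptr, spec = spec, classes = classes,
      inputSize = as.integer(spec$input[1]), variant = variant, gemP = gemP)
}

#' @describeIn countParameters trainable parameters of the native network.
#' @export
setMethod("countParameters", "LesionNet", function(object) {
  eng_nparams(object@ptr)
})

#' Stack images into a network input batch
#'
#' @param imgs a [LabeledImage-class], an integer array, or a list of either.
#' @return double array H x W x 3 x N scaled to `[0, 1]`.
#' @export
batchFromImages <- function(imgs) {
  if (!is.list(imgs)) imgs <- list(imgs)
  arrs <- lapply(imgs, function(im) {
    if (is(im, "LabeledImage")) im <- pixels(im)
    im / 255
  })
  d <- dim(arrs[[1]])
  out <- array(0, dim = c(d[1], d[2], 3L, length(arrs)))
  for (i in seq_along(arrs)) out[, , , i] <- arrs[[i]]
  out
}

#' Forward pass through a built network
#'
#' @param model a [LesionNet-class].
#' @param x input batch from [batchFromImages()].
#' @param training `TRUE` for training-mode batch norm.
#' @return The terminal node's output, array H x W x C x N.
#' @export
netForward <- function(model, x, training = FALSE) {
  eng_forward(model@ptr, x, training)
}

#' Class probabilities for a batch (evaluation mode)
#'
#' @param model a classifier [LesionNet-class].
#' @param x input batch.
#' @return N x K matrix of softmax probabilities.
#' @export
netProbs <- function(model, x) {
  eng_eval(model@ptr, x, integer())$probs
}

# output of a named node from the most recent forward pass
nodeOutput <- function(model, name) eng_node_output(model@ptr, name)

#' Save / load a model checkpoint
#'
#' The checkpoint stores the graph spec, all weights (including batch-norm
#' running statistics), the class order and the head configuration, so the
#' model can be rebuilt exactly.
#'
#' @param model a [LesionNet-class].
#' @param path file path.
#' @return `loadCheckpoint` returns the rebuilt [LesionNet-class].
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(spec = model@spec, weights = eng_get_weights(model@ptr),
               classes = model@classes, variant = model@variant,
               gemP = model@gemP), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop("corrupt or unreadable checkpoint: ", path))
  if (!all(c("spec", "weights") %in% names(ck)))
    stop("corrupt checkpoint: missing spec or weights")
  ptr <- eng_build(ck$spec)
  eng_set_weights(ptr, ck$weights)
  new("LesionNet", ptr = ptr, spec = ck$spec, classes = ck$classes,
      inputSize = as.integer(ck$spec$input[1]), variant = ck$variant,
      gemP = ck$gemP)
}

netGetWeights <- function(model) eng_get_weights(model@ptr)
netSetWeights <- function(model, w) { eng_set_weights(model@ptr, w); invisible(model) }
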