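#' Count trainable parameters
#'
#' Total number of trainable parameters (conv/dense weights and biases,
#' batch-norm scale and shift) of a built network.
#'
#' @param object a [LesionNet-class] model.
#' @return A double (counts exceed integer range for large models).
#' @export
setGeneric("countParameters", function(object) standardGeneric("countParameters"))

#' Pixels accessor
#' @param object a [LabeledImage-class].
#' @return integer array H x W x 3.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "LabeledImage", function(object) object@pixels)
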