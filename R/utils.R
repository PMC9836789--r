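#' The seven lesion classes in their fixed index order
#'
#' Class indices 0 to 6 map to Akiec (actinic keratosis / intraepithelial
#' carcinoma), Bcc (basal cell carcinoma), Bkl (benign keratosis), Df
#' (dermatofibroma), Mel (melanoma), Nv (melanocytic nevus) and Vasc
#' (vascular lesion). Every labelled object in the package uses this order.
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' lesionClasses()
lesionClasses <- function() {
  c("Akiec", "Bcc", "Bkl", "Df", "Mel", "Nv", "Vasc")
}

#' Map a class name to its 0-based index (and back)
#'
#' @param x class name (for `classIndex`) or 0-based index (for `className`).
#' @return Integer 0-6, or a class name.
#' @export
classIndex <- function(x) {
  i <- match(x, lesionClasses())
  if (anyNA(i)) stop("unknown lesion class: ", paste(x[is.na(i)], collapse = ", "))
  i - 1L
}

#' @rdname classIndex
#' @export
className <- function(x) {
  x <- as.integer(x)
  if (any(x < 0L | x > 6L)) stop("class index must be in 0..6")
  lesionClasses()[x + 1L]
}

# run `expr` under a private RNG stream; the caller's RNG state is untouched
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# validate an 8-bit RGB image array (H x W x 3, values 0..255)
assertRgb <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(what, " must be an H x W x 3 array")
  if (dim(img)[1] < 1L || dim(img)[2] < 1L) stop(what, " is empty")
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 255) stop(what, " values must lie in [0, 255]")
  invisible(TRUE)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

# our arrays are (row = y, col = x, channel); EBImage Images are (x, y, channel)
toEBImage <- function(img) {
  EBImage::Image(aperm(img, c(2L, 1L, 3L)) / 255, colormode = "Color")
}

fromEBImage <- function(ebi) {
  a <- EBImage::imageData(ebi)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  aperm(array(clamp255(round(a * 255)), dim = dim(a)), c(2L, 1L, 3L))
}

# bilinear upsample of a matrix to nr x nc (used for Grad-CAM maps)
upsampleBilinear <- function(m, nr, nc) {
  yo <- seq(0.5, nrow(m) - 0.5, length.out = nr)
  xo <- seq(0.5, ncol(m) - 0.5, length.out = nc)
  y0 <- pmin(pmax(floor(yo - 0.5) + 1L, 1L), nrow(m))
  x0 <- pmin(pmax(floor(xo - 0.5) + 1L, 1L), ncol(m))
  y1 <- pmin(y0 + 1L, nrow(m)); x1 <- pmin(x0 + 1L, ncol(m))
  fy <- pmin(pmax(yo - 0.5 - (y0 - 1L), 0), 1)
  fx <- pmin(pmax(xo - 0.5 - (x0 - 1L), 0), 1)
  a <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
       m[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
       m[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
       m[y1, x1, drop = FALSE] * outer(fy, fx)
  a
}
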