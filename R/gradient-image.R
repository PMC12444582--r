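#' Construct a GrayImage
#'
#' Wraps an integer pixel matrix into a validated [GrayImage-class].
#' Rows are image rows (y, top to bottom), columns are image columns
#' (x, left to right).
#'
#' @param pixels integer-valued matrix of gray levels in
#'   \code{[0, nLevels - 1]}.
#' @param nLevels number of gray levels \code{Ng}. Defaults to the
#'   smallest power of two that accommodates the largest pixel value
#'   (minimum 2), matching the usual bit-depth convention
#'   \code{Ng = 2^b}.
#'
#' @return a [GrayImage-class] object.
#' @examples
#' GrayImage(matrix(0:3, 2, 2), nLevels = 4)
#' @export
GrayImage <- function(pixels, nLevels = NULL) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, nrow = 1L)
  if (anyNA(pixels) || any(pixels != floor(pixels)))
    stop("'pixels' must be integer-valued and free of NA")
  if (is.null(nLevels))
    nLevels <- max(2, 2^ceiling(log2(max(pixels) + 1)))
  pixels <- matrix(as.integer(pixels), nrow(pixels), ncol(pixels))
  new("GrayImage", pixels = pixels, nLevels = as.integer(nLevels))
}

#' @rdname accessors
#' @export
setMethod("pixels", "GrayImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("nLevels", "GrayImage", function(x) x@nLevels)

#' @rdname accessors
#' @export
setMethod("imageDim", "GrayImage",
  function(x) c(width = ncol(x@pixels), height = nrow(x@pixels)))

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("GrayImage: %d x %d pixels (width x height), Ng = %d\n",
              d[2L], d[1L], object@nLevels))
  cat(sprintf("  intensity range observed: [%d, %d]\n",
              min(object@pixels), max(object@pixels)))
})

#' Construct a GradientSpec
#'
#' @param nLevels number of gray levels \code{Ng >= 2}.
#' @param nabla gradient magnitude in gray levels per pixel,
#'   \code{1 <= nabla <= nLevels - 1}. A negative value is accepted as
#'   shorthand for \code{sign = -1}.
#' @param width,height image dimensions in pixels.
#' @param sign \code{+1} (ascending along the axis) or \code{-1}.
#' @param axis \code{"vertical"} (intensity varies with y, constant along
#'   each row) or \code{"horizontal"}.
#' @param phase starting offset on the gradient lattice, in
#'   \code{[0, nTilde)}; reduced modulo the period.
#'
#' @return a [GradientSpec-class] object.
#' @examples
#' GradientSpec(nLevels = 256, nabla = 3, width = 1024, height = 1024)
#' @export
GradientSpec <- function(nLevels, nabla, width, height, sign = 1L,
                         axis = c("vertical", "horizontal"), phase = 0L) {
  axis <- match.arg(axis)
  nabla <- as.integer(nabla)
  sign <- as.integer(sign)
  if (length(nabla) == 1L && !is.na(nabla) && nabla < 0L) {
    sign <- -sign
    nabla <- -nabla
  }
  nLevels <- as.integer(nLevels)
  if (length(nabla) != 1L || is.na(nabla) || nabla < 1L ||
      is.na(nLevels) || nabla > nLevels - 1L)
    stop("'nabla' must satisfy 1 <= |nabla| <= nLevels - 1 ",
         "(a constant image is not a gradient; request it explicitly ",
         "via GrayImage())")
  nt <- 1L + (nLevels - 1L) %/% nabla
  new("GradientSpec", nabla = nabla, sign = sign, axis = axis,
      phase = as.integer(phase) %% nt, nLevels = nLevels,
      width = as.integer(width), height = as.integer(height))
}

setMethod("show", "GradientSpec", function(object) {
  nt <- 1L + (object@nLevels - 1L) %/% object@nabla
  cat(sprintf(
    "GradientSpec: %s gradient, nabla = %s%d levels/pixel, Ng = %d\n",
    object@axis, if (object@sign > 0) "+" else "-", object@nabla,
    object@nLevels))
  cat(sprintf("  period nTilde = %d, phase = %d, image %d x %d\n",
              nt, object@phase, object@width, object@height))
})

#' Generate a synthetic linear-gradient (sawtooth) image
#'
#' Renders the periodic sawtooth described by a [GradientSpec-class]: along
#' the gradient axis the intensity steps through the lattice
#' \code{0, nabla, 2*nabla, ..., (nTilde - 1)*nabla} and wraps back, so the
#' pattern is periodic with period \code{nTilde = 1 + floor((Ng - 1) /
#' nabla)} pixels. The wrap happens on the lattice, not modulo \code{Ng}:
#' for \code{Ng = 7, nabla = 2} a column reads 0, 2, 4, 6, 0, 2, ... and
#' never visits odd levels. This is the image class for which the GLCM
#' scaling laws of [predictAll()] are exact.
#'
#' For a vertical gradient, row \code{y} (0-based, top row is 0) has
#' constant intensity \code{nabla * ((sign * y + phase) mod nTilde)};
#' a horizontal gradient swaps the roles of x and y.
#'
#' @param spec a [GradientSpec-class].
#' @return a [GrayImage-class] of dimensions \code{width x height}.
#' @examples
#' img <- makeLinearGradient(GradientSpec(nLevels = 7, nabla = 2,
#'                                        width = 3, height = 5))
#' pixels(img)[, 1]  # 0 2 4 6 0
#' @export
makeLinearGradient <- function(spec) {
  stopifnot(is(spec, "GradientSpec"))
  validObject(spec)
  nt <- 1L + (spec@nLevels - 1L) %/% spec@nabla
  n <- if (spec@axis == "vertical") spec@height else spec@width
  idx <- 0:(n - 1L)
  ramp <- spec@nabla * ((spec@sign * idx + spec@phase) %% nt)
  px <- if (spec@axis == "vertical") {
    matrix(ramp, nrow = spec@height, ncol = spec@width)
  } else {
    matrix(ramp, nrow = spec@height, ncol = spec@width, byrow = TRUE)
  }
  GrayImage(px, nLevels = spec@nLevels)
}

#' Requantize an image to a coarser gray-level count
#'
#' Linear binning to \code{nLevels} bins with edges uniform on
#' \code{[0, max(pixels) + 1)}; useful before [computeGLCM()] on
#' high-bit-depth input, where a dense \code{Ng x Ng} co-occurrence matrix
#' would be impractical.
#'
#' @param img a [GrayImage-class].
#' @param nLevels target number of gray levels.
#' @return a [GrayImage-class] with \code{nLevels} levels.
#' @export
quantizeImage <- function(img, nLevels) {
  stopifnot(is(img, "GrayImage"))
  nLevels <- as.integer(nLevels)
  if (is.na(nLevels) || nLevels < 2L)
    stop("'nLevels' must be an integer >= 2")
  width <- (max(pixels(img)) + 1) / nLevels
  GrayImage(floor(pixels(img) / width), nLevels = nLevels)
}
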