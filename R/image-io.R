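#' Read a grayscale image from PNG or TIFF
#'
#' Reads a single-channel integer image and wraps it in a
#' [GrayImage-class]. The gray-level count is inferred from the stored bit
#' depth as \code{Ng = 2^bitdepth} unless overridden. Multi-channel (RGB /
#' RGBA) and floating-point inputs are rejected.
#'
#' @param path file path ending in \code{.png}, \code{.tif} or
#'   \code{.tiff}.
#' @param nLevels optional override for the inferred gray-level count.
#' @return a [GrayImage-class].
#' @seealso [writeGrayImage()]
#' @export
readGrayImage <- function(path, nLevels = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path, info = TRUE)
    info <- attr(a, "info")
    if (length(dim(a)) == 3L || !identical(info$color.type, "gray"))
      stop("'", path, "' is not a single-channel grayscale PNG ",
           "(color type: ", info$color.type, "); convert to grayscale first")
    bd <- info$bit.depth
    pix <- round(a * (2^bd - 1))
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    if (length(dim(a)) == 3L ||
        isTRUE(attr(a, "samples.per.pixel") > 1L))
      stop("'", path, "' is not a single-channel grayscale TIFF; ",
           "convert to grayscale first")
    bd <- attr(a, "bits.per.sample")
    if (is.null(bd) || !(bd %in% c(8L, 16L)))
      stop("'", path, "' has unsupported sample depth ",
           if (is.null(bd)) "?" else bd,
           " bits; only 8- and 16-bit integer TIFFs are supported ",
           "(floating-point TIFFs are rejected)")
    pix <- a
  } else {
    stop("unsupported image format '.", ext, "'; use PNG or TIFF")
  }
  GrayImage(pix, nLevels = if (is.null(nLevels)) 2^bd else nLevels)
}

#' Write a grayscale image to PNG or TIFF
#'
#' Stores the pixel values losslessly at 8- or 16-bit depth. PNG output is
#' 8-bit; 16-bit data go to TIFF. The bit depth defaults to the smallest of
#' 8 / 16 that holds \code{nLevels(img)} levels, so a round trip through
#' [readGrayImage()] restores both the pixels and the inferred \code{Ng}
#' whenever \code{nLevels} is a power of two.
#'
#' @param img a [GrayImage-class].
#' @param path destination path ending in \code{.png}, \code{.tif} or
#'   \code{.tiff}.
#' @param bitDepth 8 or 16; default chosen from \code{nLevels(img)}.
#' @return \code{path}, invisibly.
#' @export
writeGrayImage <- function(img, path, bitDepth = NULL) {
  stopifnot(is(img, "GrayImage"))
  validObject(img)
  if (is.null(bitDepth)) bitDepth <- if (nLevels(img) <= 256L) 8L else 16L
  bitDepth <- as.integer(bitDepth)
  if (!(bitDepth %in% c(8L, 16L)))
    stop("'bitDepth' must be 8 or 16")
  if (nLevels(img) > 2^bitDepth)
    stop("image has ", nLevels(img), " gray levels; they do not fit in ",
         bitDepth, " bits")
  scaled <- pixels(img) / (2^bitDepth - 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bitDepth != 8L)
      stop("PNG output is 8-bit only; use TIFF for 16-bit data")
    png::writePNG(scaled, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = bitDepth)
  } else {
    stop("unsupported image format '.", ext, "'; use PNG or TIFF")
  }
  invisible(path)
}
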