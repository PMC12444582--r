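#' Compute a gray-level co-occurrence matrix
#'
#' Counts ordered pairs of gray levels \code{(i, j)} with \code{i} at a
#' reference pixel \code{(x, y)} and \code{j} at the target pixel
#' \code{(x + dx, y + dy)}, with x pointing right, y pointing down and the
#' origin at the upper-left corner. In the default (non-cyclic) mode,
#' pairs whose target falls outside the image are dropped, so the
#' normalization total for a unit horizontal displacement on an
#' \code{Nx x Ny} image is \code{(Nx - 1) * Ny} and for a unit vertical
#' displacement \code{(Ny - 1) * Nx}. In cyclic mode the target
#' coordinates wrap modulo the image dimensions, every pixel is a
#' reference, and the total is \code{Nx * Ny}; on an image holding a whole
#' number of periods of a periodic pattern this removes edge effects
#' entirely. Counting is non-symmetric by default (\code{P[i, j]} and
#' \code{P[j, i]} are distinct); \code{symmetric = TRUE} adds the
#' transposed counts.
#'
#' @param img a [GrayImage-class].
#' @param dx,dy integer displacement (rightward, downward); not both zero.
#' @param cyclic wrap target coordinates modulo the image size.
#' @param symmetric add the transposed counts.
#' @return a [CoocMatrix-class].
#' @examples
#' img <- GrayImage(matrix(c(0, 0, 1, 1), 2, 2), nLevels = 2)
#' glcmCounts(computeGLCM(img, dx = 1, dy = 0))
#' @export
computeGLCM <- function(img, dx, dy, cyclic = FALSE, symmetric = FALSE) {
  stopifnot(is(img, "GrayImage"))
  validObject(img)
  dx <- as.integer(dx); dy <- as.integer(dy)
  if (length(dx) != 1L || length(dy) != 1L || is.na(dx) || is.na(dy))
    stop("'dx' and 'dy' must be single integers")
  if (dx == 0L && dy == 0L)
    stop("displacement (0, 0) is not a valid GLCM offset")
  px <- pixels(img)
  ny <- nrow(px); nx <- ncol(px)
  ng <- nLevels(img)
  if (ng > 4096L)
    stop("Ng = ", ng, " would give a ", ng, " x ", ng, " dense ",
         "co-occurrence matrix; requantize first with quantizeImage()")
  if (cyclic) {
    tx <- ((seq_len(nx) - 1L + dx) %% nx) + 1L
    ty <- ((seq_len(ny) - 1L + dy) %% ny) + 1L
    ref <- px
    tgt <- px[ty, tx, drop = FALSE]
  } else {
    if (abs(dx) >= nx || abs(dy) >= ny)
      stop("image (", nx, " x ", ny, ") too small for displacement (",
           dx, ", ", dy, ") without wrapping; use cyclic = TRUE")
    rx <- (max(0L, -dx) + 1L):(nx - max(0L, dx))
    ry <- (max(0L, -dy) + 1L):(ny - max(0L, dy))
    ref <- px[ry, rx, drop = FALSE]
    tgt <- px[ry + dy, rx + dx, drop = FALSE]
  }
  # bin index i*Ng + j is < 2^31 thanks to the Ng cap above
  bins <- as.integer(ref) * ng + as.integer(tgt) + 1L
  counts <- matrix(tabulate(bins, nbins = ng * ng),
                   nrow = ng, ncol = ng, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  new("CoocMatrix", counts = counts, total = as.numeric(sum(counts)),
      displacement = c(dx, dy), nLevels = ng,
      cyclic = cyclic, symmetric = symmetric)
}

#' @rdname accessors
#' @export
setMethod("glcmCounts", "CoocMatrix", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("glcmProbs", "CoocMatrix", function(x) x@counts / x@total)

#' @rdname accessors
#' @export
setMethod("glcmTotal", "CoocMatrix", function(x) x@total)

#' @rdname accessors
#' @export
setMethod("displacement", "CoocMatrix", function(x) {
  d <- x@displacement
  names(d) <- c("dx", "dy")
  d
})

#' @rdname accessors
#' @export
setMethod("nLevels", "CoocMatrix", function(x) x@nLevels)

setMethod("show", "CoocMatrix", function(object) {
  cat(sprintf(
    "CoocMatrix: Ng = %d, d = (%d, %d), %s%s\n",
    object@nLevels, object@displacement[1L], object@displacement[2L],
    if (object@cyclic) "cyclic" else "non-cyclic",
    if (object@symmetric) ", symmetric" else ""))
  cat(sprintf("  total pairs R = %d, nonzero entries: %d\n",
              as.integer(object@total), sum(object@counts > 0)))
})

#' Marginal distributions and moments of a GLCM
#'
#' Computes the reference-level marginal \code{px(i)}, the target-level
#' marginal \code{py(j)}, the absolute-difference marginal
#' \code{pdiff(k) = sum over |i - j| = k of p(i, j)} for
#' \code{k = 0, ..., Ng - 1}, and the means and standard deviations of
#' \code{px} and \code{py} (population moments of the gray-level value).
#'
#' @param g a [CoocMatrix-class] with \code{glcmTotal(g) > 0}.
#' @return a named list with elements \code{px}, \code{py}, \code{pdiff}
#'   (numeric vectors of length \code{Ng}, indexed by level/offset 0 at
#'   position 1), \code{muX}, \code{muY}, \code{sigmaX}, \code{sigmaY}.
#' @examples
#' img <- makeLinearGradient(GradientSpec(nLevels = 4, nabla = 1,
#'                                        width = 2, height = 8))
#' m <- glcmMarginals(computeGLCM(img, 0, 1, cyclic = TRUE))
#' m$muX       # 1.5
#' m$pdiff[2]  # p(|i-j| = 1) = 3/4
#' @export
glcmMarginals <- function(g) {
  stopifnot(is(g, "CoocMatrix"))
  if (g@total <= 0) stop("empty GLCM: total is 0")
  p <- glcmProbs(g)
  ng <- g@nLevels
  lev <- 0:(ng - 1L)
  px <- rowSums(p)
  py <- colSums(p)
  k <- abs(.row(dim(p)) - .col(dim(p)))
  agg <- rowsum(as.vector(p), as.vector(k))
  pdiff <- numeric(ng)
  pdiff[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  muX <- sum(lev * px)
  muY <- sum(lev * py)
  list(px = px, py = py, pdiff = pdiff, muX = muX, muY = muY,
       sigmaX = sqrt(max(0, sum(lev^2 * px) - muX^2)),
       sigmaY = sqrt(max(0, sum(lev^2 * py) - muY^2)))
}

#' Export a GLCM to CSV or sparse-triplet JSON
#'
#' CSV output is the dense \code{Ng x Ng} count matrix (no header, row
#' \code{i + 1} is reference level \code{i}); JSON output is an array of
#' \code{{i, j, count}} objects for the nonzero entries, with 0-based
#' gray levels.
#'
#' @param g a [CoocMatrix-class].
#' @param path destination file.
#' @param format \code{"csv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
writeGLCM <- function(g, path, format = c("csv", "json")) {
  stopifnot(is(g, "CoocMatrix"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.table(glcmCounts(g), path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("JSON export requires the 'jsonlite' package")
    nz <- which(glcmCounts(g) > 0, arr.ind = TRUE)
    trip <- data.frame(i = nz[, 1L] - 1L, j = nz[, 2L] - 1L,
                       count = glcmCounts(g)[nz])
    trip <- trip[order(trip$i, trip$j), ]
    jsonlite::write_json(trip, path, dataframe = "rows")
  }
  invisible(path)
}
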