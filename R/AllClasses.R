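#' @import methods
NULL

#' GrayImage: a 2-D integer-valued grayscale image
#'
#' Container for a single-channel image with a known number of gray levels
#' \code{Ng}. Pixels are stored as an integer matrix whose rows run top to
#' bottom (the y axis points down) and whose columns run left to right (the
#' x axis points right), with the origin at the upper-left corner. All pixel
#' values must lie in \code{[0, Ng - 1]}.
#'
#' @slot pixels integer matrix of gray levels, \code{[y, x]} indexed.
#' @slot nLevels integer, the number of gray levels \code{Ng} (bit depth
#'   \code{b} corresponds to \code{Ng = 2^b}).
#'
#' @seealso [GrayImage()] for the user-facing constructor,
#'   [makeLinearGradient()], [computeGLCM()]
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", nLevels = "integer"))

setValidity("GrayImage", function(object) {
  p <- object@pixels
  ng <- object@nLevels
  if (length(ng) != 1L || is.na(ng) || ng < 1L)
    return("'nLevels' must be a single integer >= 1")
  if (!is.numeric(p) || !is.matrix(p))
    return("'pixels' must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L)
    return("image must have at least one row and one column")
  if (anyNA(p))
    return("'pixels' must not contain NA")
  if (any(p != floor(p)))
    return("'pixels' must be integer-valued")
  if (any(p < 0) || any(p > ng - 1L))
    return(sprintf("all pixel values must lie in [0, %d]", ng - 1L))
  TRUE
})

#' GradientSpec: parameters of a one-dimensional linear gradient
#'
#' Describes a periodic sawtooth gradient: the intensity increases (or
#' decreases, for \code{sign = -1}) by \code{nabla} gray levels per pixel
#' along the gradient axis and wraps back to the start of the lattice after
#' one period. The lattice visits the \code{nTilde = 1 + floor((Ng - 1) /
#' nabla)} levels \code{0, nabla, 2 * nabla, ..., (nTilde - 1) * nabla};
#' the period of the pattern is \code{nTilde} pixels, not \code{Ng}.
#'
#' @slot nabla integer, gradient magnitude in gray levels per pixel;
#'   \code{1 <= nabla <= nLevels - 1}.
#' @slot sign integer, \code{+1} (intensity grows along the axis) or
#'   \code{-1} (descending gradient).
#' @slot axis character, \code{"vertical"} (intensity varies with y) or
#'   \code{"horizontal"}.
#' @slot phase integer lattice offset in \code{[0, nTilde)}; selects the
#'   starting level of the sawtooth.
#' @slot nLevels integer, number of gray levels \code{Ng >= 2}.
#' @slot width,height integer image dimensions.
#'
#' @seealso [GradientSpec()], [makeLinearGradient()]
#' @export
setClass("GradientSpec",
  representation(nabla = "integer", sign = "integer", axis = "character",
                 phase = "integer", nLevels = "integer",
                 width = "integer", height = "integer"))

setValidity("GradientSpec", function(object) {
  ng <- object@nLevels
  if (length(ng) != 1L || is.na(ng) || ng < 2L)
    return("'nLevels' must be a single integer >= 2")
  nb <- object@nabla
  if (length(nb) != 1L || is.na(nb) || nb < 1L || nb > ng - 1L)
    return("'nabla' must satisfy 1 <= nabla <= nLevels - 1")
  if (length(object@sign) != 1L || !(object@sign %in% c(-1L, 1L)))
    return("'sign' must be +1 or -1")
  if (length(object@axis) != 1L ||
      !(object@axis %in% c("vertical", "horizontal")))
    return("'axis' must be \"vertical\" or \"horizontal\"")
  nt <- 1L + (ng - 1L) %/% nb
  ph <- object@phase
  if (length(ph) != 1L || is.na(ph) || ph < 0L || ph >= nt)
    return(sprintf("'phase' must lie in [0, %d)", nt))
  if (length(object@width) != 1L || is.na(object@width) || object@width < 1L)
    return("'width' must be a positive integer")
  if (length(object@height) != 1L || is.na(object@height) ||
      object@height < 1L)
    return("'height' must be a positive integer")
  TRUE
})

#' CoocMatrix: a gray-level co-occurrence matrix
#'
#' Ordered-pair co-occurrence counts \code{P[i, j]} of gray level \code{i}
#' at a reference pixel and gray level \code{j} at the pixel offset by the
#' displacement \code{(dx, dy)} (x to the right, y down). Row index is the
#' reference level, column index the target level, both 0-based in the
#' gray-level sense (matrix element \code{[i + 1, j + 1]} holds level pair
#' \code{(i, j)}). \code{total} is the normalization constant \code{R};
#' normalized probabilities are \code{counts / total} (see [glcmProbs()]).
#'
#' @slot counts numeric matrix of non-negative pair counts, \code{Ng x Ng}.
#' @slot total numeric, sum of all counts (the normalization factor
#'   \code{R}).
#' @slot displacement integer vector \code{c(dx, dy)}, never \code{c(0,0)}.
#' @slot nLevels integer, \code{Ng}.
#' @slot cyclic logical; if \code{TRUE}, target coordinates were wrapped
#'   modulo the image dimensions (toroidal pairing, no edge loss).
#' @slot symmetric logical; if \code{TRUE}, transposed pairs were added.
#'
#' @seealso [computeGLCM()], [glcmCounts()], [glcmProbs()],
#'   [glcmMarginals()], [haralickFeatures()]
#' @export
setClass("CoocMatrix",
  representation(counts = "matrix", total = "numeric",
                 displacement = "integer", nLevels = "integer",
                 cyclic = "logical", symmetric = "logical"))

setValidity("CoocMatrix", function(object) {
  cts <- object@counts
  ng <- object@nLevels
  if (!is.matrix(cts) || nrow(cts) != ng || ncol(cts) != ng)
    return("'counts' must be an nLevels x nLevels matrix")
  if (anyNA(cts) || any(cts < 0))
    return("'counts' must be non-negative")
  if (any(cts != floor(cts)))
    return("'counts' must be integer-valued")
  if (!isTRUE(all.equal(sum(cts), object@total)))
    return("'total' must equal the sum of 'counts'")
  d <- object@displacement
  if (length(d) != 2L || all(d == 0L))
    return("'displacement' must be a length-2 integer vector != (0, 0)")
  TRUE
})

#' FeatureSet: the four Haralick texture features of one GLCM
#'
#' Scalar texture descriptors computed from a normalized GLCM: Energy/ASM
#' \code{f1 = sum p^2}, Contrast \code{f2 = sum k^2 p_{x-y}(k)},
#' Correlation \code{f3}, and Homogeneity/IDM \code{f5} in three weight
#' variants: \code{1/(1 + |i-j|)} (\code{f5IDMAbs}, the variant whose
#' analytic law is derived here), Haralick's original
#' \code{1/(1 + (i-j)^2)} (\code{f5IDMSq}), and the bit-depth-rescaled
#' \code{1/(1 + ((i-j)/Ng)^2)} (\code{f5IDMLofstedt}).
#'
#' @slot f1ASM,f2Contrast,f3Correlation,f5IDMAbs,f5IDMSq,f5IDMLofstedt
#'   numeric feature values; \code{f3Correlation} is \code{NaN} for a
#'   degenerate (zero-variance) GLCM.
#' @slot nLevels integer, gray-level count of the source GLCM.
#' @slot nNonzero integer, number of nonzero GLCM entries (lower bound
#'   \code{1/nNonzero <= f1ASM}).
#'
#' @seealso [haralickFeatures()], [normalizeFeatures()], [featureValues()]
#' @export
setClass("FeatureSet",
  representation(f1ASM = "numeric", f2Contrast = "numeric",
                 f3Correlation = "numeric", f5IDMAbs = "numeric",
                 f5IDMSq = "numeric", f5IDMLofstedt = "numeric",
                 nLevels = "integer", nNonzero = "integer"))

setValidity("FeatureSet", function(object) {
  f1 <- object@f1ASM
  if (f1 < 0 || f1 > 1) return("f1ASM must lie in [0, 1]")
  if (object@f2Contrast < 0) return("f2Contrast must be >= 0")
  f5a <- object@f5IDMAbs; f5s <- object@f5IDMSq
  if (f5a <= 0 || f5a > 1 || f5s <= 0 || f5s > 1)
    return("IDM values must lie in (0, 1]")
  if (f5s > f5a + 1e-12)
    return("squared-weight IDM cannot exceed absolute-weight IDM")
  TRUE
})

#' NormalizedFeatureSet: bit-depth-normalized Haralick features
#'
#' Features rescaled so that they become (asymptotically) independent of
#' the gray-level count \code{Ng}. The \code{"paper"} scheme follows the
#' analytically derived factors \code{f1 * Ng}, \code{f2 / Ng}, \code{f3},
#' \code{f5} (absolute-weight IDM, already asymptotically invariant); the
#' \code{"lofstedt"} scheme applies the empirical factors \code{f1 * Ng^2},
#' \code{f2 / Ng^2}, \code{f3}, and the IDM recomputed with weight
#' \code{1/(1 + ((i - j)/Ng)^2)}.
#'
#' @slot f1Tilde,f2Tilde,f3Tilde,f5Tilde numeric normalized values.
#' @slot scheme character, \code{"paper"} or \code{"lofstedt"}.
#' @slot nLevels integer, \code{Ng} used for the rescaling.
#'
#' @seealso [normalizeFeatures()]
#' @export
setClass("NormalizedFeatureSet",
  representation(f1Tilde = "numeric", f2Tilde = "numeric",
                 f3Tilde = "numeric", f5Tilde = "numeric",
                 scheme = "character", nLevels = "integer"))

setValidity("NormalizedFeatureSet", function(object) {
  if (!(object@scheme %in% c("paper", "lofstedt")))
    return("'scheme' must be \"paper\" or \"lofstedt\"")
  TRUE
})

#' ScalingPrediction: analytic feature values for a linear gradient
#'
#' Closed-form predictions of the GLCM structure and the four Haralick
#' features for a sawtooth linear-gradient image with \code{Ng} gray
#' levels, gradient magnitude \code{nabla}, probed at scalar displacement
#' \code{d} along the gradient axis. The cyclic (toroidal) GLCM of such an
#' image has exactly \code{nTilde = 1 + floor((Ng - 1)/nabla)} nonzero
#' entries, \code{m1 = nTilde - dEff} of them on the superdiagonal at
#' gray-level offset \code{kAbove = dEff * nabla} and \code{m2 = dEff} of
#' them wrapped onto the subdiagonal at \code{kBelow = -m1 * nabla}, where
#' \code{dEff = d mod nTilde}. \code{dEff == 0} is the degenerate
#' whole-period shift: all mass on the principal diagonal.
#'
#' @slot nLevels,nabla,d integer inputs (gradient sign is irrelevant: a
#'   negative gradient merely transposes the GLCM and leaves all four
#'   features unchanged).
#' @slot dEff integer, displacement reduced modulo the period.
#' @slot nTilde integer, number of nonzero GLCM entries (effective levels).
#' @slot m1,m2 integer, nonzero entries above / wrapped below the
#'   principal diagonal (0 for the degenerate case).
#' @slot kAbove,kBelow integer gray-level offsets \code{j - i} of the two
#'   diagonals.
#' @slot degenerate logical, \code{TRUE} iff \code{dEff == 0}.
#' @slot f1ASM,f2Contrast,f3Correlation,f5IDMAbs,f5IDMSq numeric predicted
#'   feature values.
#'
#' @seealso [predictAll()], [effectiveLevels()], [diagonalSplit()]
#' @export
setClass("ScalingPrediction",
  representation(nLevels = "integer", nabla = "integer", d = "integer",
                 dEff = "integer", nTilde = "integer",
                 m1 = "integer", m2 = "integer",
                 kAbove = "integer", kBelow = "integer",
                 degenerate = "logical",
                 f1ASM = "numeric", f2Contrast = "numeric",
                 f3Correlation = "numeric", f5IDMAbs = "numeric",
                 f5IDMSq = "numeric"))

setValidity("ScalingPrediction", function(object) {
  if (object@nTilde != 1L + (object@nLevels - 1L) %/% abs(object@nabla))
    return("nTilde inconsistent with nLevels and nabla")
  if (!object@degenerate && object@m1 + object@m2 != object@nTilde)
    return("m1 + m2 must equal nTilde")
  TRUE
})
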