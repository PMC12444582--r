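#' Haralick texture features of a GLCM
#'
#' The four descriptors with known analytic scaling behavior on
#' linear-gradient images, computed from the normalized GLCM
#' \code{p = glcmProbs(g)} exactly as stored (no implicit
#' symmetrization):
#' \describe{
#'   \item{Energy / Angular Second Moment}{\code{f1 = sum p(i,j)^2};
#'     measures uniformity, 1 for a single dominant entry, bounded below
#'     by \code{1/n} with \code{n} the number of nonzero entries.}
#'   \item{Contrast}{\code{f2 = sum k^2 pdiff(k)} over the
#'     absolute-difference marginal; 0 iff all mass is on the principal
#'     diagonal.}
#'   \item{Correlation}{\code{f3 = (sum i j p(i,j) - muX muY) /
#'     (sigmaX sigmaY)}; undefined (\code{NaN}, with a warning) when a
#'     marginal is a point mass.}
#'   \item{Homogeneity / Inverse Difference Moment}{\code{f5 = sum
#'     p(i,j) w(i - j)} with weight \code{w = 1/(1 + |i-j|)}
#'     (\code{"abs"}) or Haralick's original \code{1/(1 + (i-j)^2)}
#'     (\code{"squared"}).}
#' }
#'
#' @param g a [CoocMatrix-class] with \code{glcmTotal(g) > 0}.
#' @param variant IDM weight, \code{"abs"} or \code{"squared"}.
#' @return a single numeric value.
#' @seealso [haralickFeatures()] to compute all of them at once,
#'   [predictAll()] for the analytic values on linear gradients.
#' @examples
#' img <- makeLinearGradient(GradientSpec(nLevels = 4, nabla = 1,
#'                                        width = 2, height = 8))
#' g <- computeGLCM(img, 0, 1, cyclic = TRUE)
#' haralickASM(g)          # 0.25
#' haralickContrast(g)     # 3
#' haralickCorrelation(g)  # -0.2
#' haralickIDM(g)          # 0.4375
#' @name haralick-features
NULL

.checkNonEmpty <- function(g) {
  stopifnot(is(g, "CoocMatrix"))
  if (g@total <= 0) stop("empty GLCM: total is 0")
}

#' @rdname haralick-features
#' @export
haralickASM <- function(g) {
  .checkNonEmpty(g)
  sum(glcmProbs(g)^2)
}

#' @rdname haralick-features
#' @export
haralickContrast <- function(g) {
  .checkNonEmpty(g)
  m <- glcmMarginals(g)
  k <- 0:(g@nLevels - 1L)
  sum(k^2 * m$pdiff)
}

#' @rdname haralick-features
#' @export
haralickCorrelation <- function(g) {
  .checkNonEmpty(g)
  m <- glcmMarginals(g)
  if (m$sigmaX == 0 || m$sigmaY == 0) {
    warning("correlation is undefined for a zero-variance GLCM ",
            "(constant image); returning NaN")
    return(NaN)
  }
  p <- glcmProbs(g)
  lev <- 0:(g@nLevels - 1L)
  crossMoment <- as.numeric(lev %*% p %*% lev)
  (crossMoment - m$muX * m$muY) / (m$sigmaX * m$sigmaY)
}

#' @rdname haralick-features
#' @export
haralickIDM <- function(g, variant = c("abs", "squared")) {
  .checkNonEmpty(g)
  variant <- match.arg(variant)
  p <- glcmProbs(g)
  k <- .row(dim(p)) - .col(dim(p))
  w <- if (variant == "abs") 1 / (1 + abs(k)) else 1 / (1 + k^2)
  sum(p * w)
}

# Lofstedt-rescaled IDM weight: gray-level difference divided by Ng
.idmLofstedt <- function(g) {
  p <- glcmProbs(g)
  k <- .row(dim(p)) - .col(dim(p))
  sum(p / (1 + (k / g@nLevels)^2))
}

#' Compute all Haralick features of a GLCM
#'
#' Bundles [haralickASM()], [haralickContrast()], [haralickCorrelation()]
#' and the three IDM variants into a [FeatureSet-class].
#'
#' @param g a [CoocMatrix-class] with \code{glcmTotal(g) > 0}.
#' @return a [FeatureSet-class].
#' @examples
#' img <- makeLinearGradient(GradientSpec(nLevels = 4, nabla = 1,
#'                                        width = 2, height = 8))
#' haralickFeatures(computeGLCM(img, 0, 1, cyclic = TRUE))
#' @export
haralickFeatures <- function(g) {
  .checkNonEmpty(g)
  f3 <- withCallingHandlers(
    haralickCorrelation(g),
    warning = function(w) invokeRestart("muffleWarning"))
  new("FeatureSet",
      f1ASM = haralickASM(g),
      f2Contrast = haralickContrast(g),
      f3Correlation = f3,
      f5IDMAbs = haralickIDM(g, "abs"),
      f5IDMSq = haralickIDM(g, "squared"),
      f5IDMLofstedt = .idmLofstedt(g),
      nLevels = g@nLevels,
      nNonzero = sum(glcmCounts(g) > 0))
}

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureSet", function(x) {
  c(f1ASM = x@f1ASM, f2Contrast = x@f2Contrast,
    f3Correlation = x@f3Correlation, f5IDMAbs = x@f5IDMAbs,
    f5IDMSq = x@f5IDMSq, f5IDMLofstedt = x@f5IDMLofstedt)
})

#' @rdname accessors
#' @export
setMethod("nLevels", "FeatureSet", function(x) x@nLevels)

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet (Ng = %d, %d nonzero GLCM entries)\n",
              object@nLevels, object@nNonzero))
  v <- featureValues(object)
  for (nm in names(v)) cat(sprintf("  %-14s %.6g\n", nm, v[[nm]]))
})

#' Normalize Haralick features for bit-depth invariance
#'
#' The \code{"paper"} scheme uses the analytically derived factors that
#' make each feature asymptotically independent of the gray-level count:
#' \code{f1 * Ng}, \code{f2 / Ng}, \code{f3} and \code{f5} (abs-weight
#' IDM) unchanged. The \code{"lofstedt"} scheme applies the empirical
#' factors proposed in the radiomics literature: \code{f1 * Ng^2},
#' \code{f2 / Ng^2}, \code{f3} unchanged, and the IDM recomputed with the
#' rescaled weight \code{1/(1 + ((i - j)/Ng)^2)}.
#'
#' @param fs a [FeatureSet-class].
#' @param scheme \code{"paper"} or \code{"lofstedt"}.
#' @return a [NormalizedFeatureSet-class].
#' @examples
#' img <- makeLinearGradient(GradientSpec(nLevels = 4, nabla = 1,
#'                                        width = 2, height = 8))
#' fs <- haralickFeatures(computeGLCM(img, 0, 1, cyclic = TRUE))
#' featureValues(normalizeFeatures(fs))  # f1Tilde = 1
#' @export
normalizeFeatures <- function(fs, scheme = c("paper", "lofstedt")) {
  stopifnot(is(fs, "FeatureSet"))
  scheme <- match.arg(scheme)
  ng <- as.numeric(fs@nLevels)
  if (scheme == "paper") {
    new("NormalizedFeatureSet",
        f1Tilde = fs@f1ASM * ng, f2Tilde = fs@f2Contrast / ng,
        f3Tilde = fs@f3Correlation, f5Tilde = fs@f5IDMAbs,
        scheme = scheme, nLevels = fs@nLevels)
  } else {
    new("NormalizedFeatureSet",
        f1Tilde = fs@f1ASM * ng^2, f2Tilde = fs@f2Contrast / ng^2,
        f3Tilde = fs@f3Correlation, f5Tilde = fs@f5IDMLofstedt,
        scheme = scheme, nLevels = fs@nLevels)
  }
}

#' @rdname accessors
#' @export
setMethod("featureValues", "NormalizedFeatureSet", function(x) {
  c(f1Tilde = x@f1Tilde, f2Tilde = x@f2Tilde,
    f3Tilde = x@f3Tilde, f5Tilde = x@f5Tilde)
})

#' @rdname accessors
#' @export
setMethod("nLevels", "NormalizedFeatureSet", function(x) x@nLevels)

setMethod("show", "NormalizedFeatureSet", function(object) {
  cat(sprintf("NormalizedFeatureSet (scheme = %s, Ng = %d)\n",
              object@scheme, object@nLevels))
  v <- featureValues(object)
  for (nm in names(v)) cat(sprintf("  %-10s %.6g\n", nm, v[[nm]]))
})
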