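#' Accessors for image and GLCM objects
#'
#' @param x a [GrayImage-class], [CoocMatrix-class], [FeatureSet-class],
#'   [NormalizedFeatureSet-class] or [ScalingPrediction-class] object, as
#'   applicable.
#'
#' @return \code{pixels} returns the integer pixel matrix (\code{[y, x]}
#'   indexed); \code{nLevels} the gray-level count \code{Ng};
#'   \code{imageDim} \code{c(width, height)}; \code{glcmCounts} the raw
#'   pair-count matrix; \code{glcmProbs} the normalized probabilities
#'   \code{counts / total}; \code{glcmTotal} the normalization constant
#'   \code{R}; \code{displacement} the integer pair \code{c(dx, dy)};
#'   \code{featureValues} a named numeric vector of feature values.
#'
#' @examples
#' img <- makeLinearGradient(GradientSpec(nLevels = 4, nabla = 1,
#'                                        width = 4, height = 8))
#' nLevels(img)
#' g <- computeGLCM(img, dx = 0, dy = 1, cyclic = TRUE)
#' glcmTotal(g)
#' featureValues(haralickFeatures(g))
#'
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' @rdname accessors
#' @export
setGeneric("imageDim", function(x) standardGeneric("imageDim"))

#' @rdname accessors
#' @export
setGeneric("glcmCounts", function(x) standardGeneric("glcmCounts"))

#' @rdname accessors
#' @export
setGeneric("glcmProbs", function(x) standardGeneric("glcmProbs"))

#' @rdname accessors
#' @export
setGeneric("glcmTotal", function(x) standardGeneric("glcmTotal"))

#' @rdname accessors
#' @export
setGeneric("displacement", function(x) standardGeneric("displacement"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
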