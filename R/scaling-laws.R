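#' Effective gray levels of a linear gradient
#'
#' A sawtooth gradient of magnitude \code{nabla} on \code{Ng} gray levels
#' visits the lattice \code{0, nabla, ..., (nTilde - 1) * nabla} with
#' \code{nTilde = 1 + floor((Ng - 1) / nabla)} distinct levels; this is
#' also the number of nonzero entries in the cyclic GLCM of the gradient
#' image, for any displacement.
#'
#' @param nLevels gray-level count \code{Ng >= 2}.
#' @param nabla gradient magnitude; \code{1 <= |nabla| <= Ng - 1} (the
#'   sign is irrelevant).
#' @return integer \code{nTilde}.
#' @examples
#' effectiveLevels(7, 2)    # 4
#' effectiveLevels(256, 3)  # 86
#' @export
effectiveLevels <- function(nLevels, nabla) {
  nLevels <- as.integer(nLevels)
  nabla <- abs(as.integer(nabla))
  if (length(nLevels) != 1L || is.na(nLevels) || nLevels < 2L)
    stop("'nLevels' must be a single integer >= 2")
  if (length(nabla) != 1L || is.na(nabla) || nabla < 1L ||
      nabla > nLevels - 1L)
    stop("'nabla' must satisfy 1 <= |nabla| <= nLevels - 1")
  1L + (nLevels - 1L) %/% nabla
}

#' Split of nonzero GLCM entries around the principal diagonal
#'
#' For a positive gradient probed at displacement \code{d} along the
#' gradient axis, \code{m1 = nTilde - dEff} nonzero entries lie on the
#' superdiagonal at gray-level offset \code{kAbove = dEff * nabla}, and
#' the remaining \code{m2 = dEff} entries, wrapped by the sawtooth's
#' periodic return to level 0, lie on the subdiagonal at
#' \code{kBelow = -m1 * nabla}. Here \code{dEff = d mod nTilde}; a
#' whole-period displacement (\code{dEff == 0}) puts all mass on the
#' principal diagonal and is flagged \code{degenerate} with
#' \code{m1 = m2 = 0}.
#'
#' @inheritParams effectiveLevels
#' @param d integer scalar displacement along the gradient axis.
#' @return a list with integer elements \code{m1}, \code{m2},
#'   \code{kAbove}, \code{kBelow}, \code{dEff}, \code{nTilde} and logical
#'   \code{degenerate}.
#' @examples
#' diagonalSplit(4, 1, 1)  # m1 = 3, m2 = 1
#' diagonalSplit(7, 2, 1)  # m1 = 3, kAbove = 2, kBelow = -6
#' @export
diagonalSplit <- function(nLevels, nabla, d) {
  nt <- effectiveLevels(nLevels, nabla)
  nabla <- abs(as.integer(nabla))
  d <- as.integer(d)
  if (length(d) != 1L || is.na(d)) stop("'d' must be a single integer")
  dEff <- d %% nt
  if (dEff == 0L) {
    list(m1 = 0L, m2 = 0L, kAbove = 0L, kBelow = 0L,
         dEff = 0L, nTilde = nt, degenerate = TRUE)
  } else {
    m1 <- nt - dEff
    list(m1 = m1, m2 = dEff, kAbove = dEff * nabla,
         kBelow = -m1 * nabla, dEff = dEff, nTilde = nt,
         degenerate = FALSE)
  }
}

#' Analytic Haralick feature values for linear gradients
#'
#' Closed-form values of the four Haralick features for the cyclic GLCM
#' of a sawtooth linear-gradient image (all \code{nTilde} nonzero entries
#' equal \code{1/nTilde}):
#' \describe{
#'   \item{Energy}{\code{f1 = 1 / nTilde}, independent of \code{d}.}
#'   \item{Contrast}{\code{f2 = nabla^2 * dEff * (nTilde - dEff)}.}
#'   \item{Correlation}{\code{f3 = 1 - 6 dEff (nTilde - dEff) /
#'     ((nTilde - 1)(nTilde + 1))}, independent of \code{nabla} (the
#'     gray-level scale cancels); undefined for \code{nTilde = 1}.}
#'   \item{IDM}{\code{f5 = (1/nTilde) * ((nTilde - dEff)/(1 + dEff
#'     nabla) + dEff/(1 + (nTilde - dEff) nabla))} for the \code{"abs"}
#'     weight; the \code{"squared"} variant replaces each denominator
#'     \code{1 + m} by \code{1 + m^2}.}
#' }
#' For the degenerate whole-period displacement (\code{dEff == 0}) the
#' GLCM is diagonal: \code{f2 = 0}, \code{f3 = 1}, \code{f5 = 1}.
#'
#' @inheritParams diagonalSplit
#' @param variant IDM weight, \code{"abs"} or \code{"squared"}.
#' @return a single numeric value.
#' @examples
#' predictASM(7, 2)          # 0.25
#' predictContrast(7, 2, 1)  # 12
#' predictCorrelation(4, 1, 1)  # -0.2
#' predictIDM(4, 1, 1)       # 0.4375
#' @name scaling-laws
NULL

#' @rdname scaling-laws
#' @export
predictASM <- function(nLevels, nabla) {
  1 / effectiveLevels(nLevels, nabla)
}

#' @rdname scaling-laws
#' @export
predictContrast <- function(nLevels, nabla, d) {
  s <- diagonalSplit(nLevels, nabla, d)
  abs(nabla)^2 * s$dEff * (s$nTilde - s$dEff)
}

#' @rdname scaling-laws
#' @export
predictCorrelation <- function(nLevels, nabla, d) {
  s <- diagonalSplit(nLevels, nabla, d)
  nt <- s$nTilde
  if (nt == 1L) {
    warning("correlation is undefined for nTilde = 1 (constant image); ",
            "returning NaN")
    return(NaN)
  }
  1 - 6 * s$dEff * (nt - s$dEff) / ((nt - 1) * (nt + 1))
}

#' @rdname scaling-laws
#' @export
predictIDM <- function(nLevels, nabla, d, variant = c("abs", "squared")) {
  variant <- match.arg(variant)
  s <- diagonalSplit(nLevels, nabla, d)
  nt <- s$nTilde
  if (s$degenerate) return(1)
  nb <- abs(nabla)
  up <- s$dEff * nb         # |offset| of the m1 superdiagonal entries
  down <- s$m1 * nb         # |offset| of the m2 wrapped entries
  if (variant == "squared") {
    up <- up^2
    down <- down^2
  }
  (s$m1 / (1 + up) + s$m2 / (1 + down)) / nt
}

#' Contrast from Energy: the inverse relationship
#'
#' On linear gradients, Energy and Contrast are functionally related:
#' \code{f2 = nabla^2 * d * (1/f1 - d)}, since \code{1/f1 = nTilde}. This
#' reproduces [predictContrast()] for every valid \code{(Ng, nabla, d)}.
#'
#' @param f1 Energy value, \code{1/nTilde} for some integer
#'   \code{nTilde >= 1}.
#' @param nabla gradient magnitude.
#' @param d scalar displacement along the gradient axis.
#' @return the predicted Contrast value.
#' @examples
#' contrastFromASM(0.25, nabla = 2, d = 1)  # 12
#' @export
contrastFromASM <- function(f1, nabla, d) {
  if (f1 <= 0 || f1 > 1) stop("'f1' must lie in (0, 1]")
  nabla^2 * d * (1 / f1 - d)
}

#' Estimate the gradient magnitude from an Energy value
#'
#' Inverts the Energy law \code{f1 = 1 / (1 + floor((Ng - 1)/nabla))}:
#' the measured \code{f1} fixes \code{nTilde = round(1/f1)}, and every
#' \code{nabla} in \code{[1, Ng - 1]} whose floor expression reproduces
#' that \code{nTilde} is a candidate. The floor makes the inversion
#' non-unique, so a set is returned; when a measured Contrast \code{f2}
#' at a known displacement \code{d} is also supplied, candidates are
#' narrowed to those whose predicted Contrast is closest to it.
#'
#' @param f1 measured Energy, in \code{(0, 1]}.
#' @param nLevels gray-level count \code{Ng}.
#' @param f2,d optional measured Contrast and its displacement, used to
#'   disambiguate multiple candidates.
#' @return an integer vector of candidate gradient magnitudes (possibly
#'   empty when \code{1/f1} is not within 0.5 of an integer).
#' @examples
#' estimateGradient(0.25, nLevels = 7)   # 2
#' estimateGradient(1/3, nLevels = 9)    # 3 4  (non-unique)
#' estimateGradient(1/3, nLevels = 9, f2 = predictContrast(9, 4, 1), d = 1)
#' @export
estimateGradient <- function(f1, nLevels, f2 = NULL, d = NULL) {
  if (!is.numeric(f1) || length(f1) != 1L || f1 <= 0 || f1 > 1)
    stop("'f1' must be a single value in (0, 1]")
  nLevels <- as.integer(nLevels)
  ntHat <- round(1 / f1)
  if (ntHat < 1 || abs(1 / f1 - ntHat) > 0.5) return(integer(0))
  cand <- seq_len(nLevels - 1L)
  cand <- cand[1L + (nLevels - 1L) %/% cand == ntHat]
  if (length(cand) > 1L && !is.null(f2) && !is.null(d)) {
    pred <- vapply(cand, function(nb) predictContrast(nLevels, nb, d),
                   numeric(1L))
    cand <- cand[abs(pred - f2) == min(abs(pred - f2))]
  }
  cand
}

#' Full analytic prediction for a linear-gradient image
#'
#' Bundles [effectiveLevels()], [diagonalSplit()] and the four feature
#' laws of [predictASM()] and friends into one [ScalingPrediction-class].
#'
#' @inheritParams diagonalSplit
#' @return a [ScalingPrediction-class].
#' @examples
#' predictAll(4, 1, 1)  # nTilde 4, m1 3, f1 0.25, f2 3, f3 -0.2
#' @export
predictAll <- function(nLevels, nabla, d) {
  s <- diagonalSplit(nLevels, nabla, d)
  f3 <- if (s$nTilde == 1L) NaN else
    if (s$degenerate) 1 else predictCorrelation(nLevels, nabla, d)
  new("ScalingPrediction",
      nLevels = as.integer(nLevels), nabla = as.integer(abs(nabla)),
      d = as.integer(d), dEff = s$dEff, nTilde = s$nTilde,
      m1 = s$m1, m2 = s$m2, kAbove = s$kAbove, kBelow = s$kBelow,
      degenerate = s$degenerate,
      f1ASM = predictASM(nLevels, nabla),
      f2Contrast = predictContrast(nLevels, nabla, d),
      f3Correlation = f3,
      f5IDMAbs = predictIDM(nLevels, nabla, d, "abs"),
      f5IDMSq = predictIDM(nLevels, nabla, d, "squared"))
}

#' @rdname accessors
#' @export
setMethod("featureValues", "ScalingPrediction", function(x) {
  c(f1ASM = x@f1ASM, f2Contrast = x@f2Contrast,
    f3Correlation = x@f3Correlation, f5IDMAbs = x@f5IDMAbs,
    f5IDMSq = x@f5IDMSq)
})

#' @rdname accessors
#' @export
setMethod("nLevels", "ScalingPrediction", function(x) x@nLevels)

setMethod("show", "ScalingPrediction", function(object) {
  cat(sprintf(
    "ScalingPrediction: Ng = %d, nabla = %d, d = %d (dEff = %d)%s\n",
    object@nLevels, object@nabla, object@d, object@dEff,
    if (object@degenerate) " [degenerate: diagonal GLCM]" else ""))
  cat(sprintf("  nTilde = %d, m1 = %d (k = %+d), m2 = %d (k = %+d)\n",
              object@nTilde, object@m1, object@kAbove,
              object@m2, object@kBelow))
  v <- featureValues(object)
  for (nm in names(v)) cat(sprintf("  %-14s %.6g\n", nm, v[[nm]]))
})
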