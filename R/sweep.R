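#' Sweep gradients and displacements: measured vs analytic features
#'
#' Generates one sawtooth-gradient image per gradient magnitude, computes
#' its GLCM at each displacement along the gradient axis, measures the
#' four Haralick features, and compares them with the closed-form
#' predictions of [predictAll()]. In \code{"cyclic"} mode the GLCM wraps
#' at the image border and the image height is snapped down to the
#' largest multiple of the period \code{nTilde} not exceeding the
#' requested height (at least one period), so the laws hold to floating
#' point precision. In \code{"noncyclic"} mode the requested dimensions
#' are used verbatim and edge effects leave a small discrepancy of order
#' \code{d / Ny} plus the truncation of the last partial period.
#'
#' @param nLevels gray-level count \code{Ng}.
#' @param gradients integer vector of gradient magnitudes to sweep.
#' @param displacements integer vector of scalar displacements along the
#'   gradient axis.
#' @param width,height image dimensions in pixels.
#' @param mode \code{"noncyclic"} (finite-image convention) or
#'   \code{"cyclic"} (toroidal, exact).
#' @param axis gradient axis, \code{"vertical"} or \code{"horizontal"};
#'   displacements are taken along this axis.
#' @param rtol relative tolerance recorded in the \code{withinTol}
#'   column; defaults to \code{1e-12} in cyclic mode and \code{0.02} in
#'   noncyclic mode.
#'
#' @return a data.frame with one row per (gradient, displacement,
#'   feature) combination and columns \code{nLevels}, \code{nabla},
#'   \code{d}, \code{nTilde}, \code{feature} (\code{"f1"}, \code{"f2"},
#'   \code{"f3"}, \code{"f5"}; the IDM rows use the absolute-difference
#'   weight), \code{measured}, \code{predicted}, \code{absError},
#'   \code{relError}, \code{mode}, \code{degenerate}, \code{withinTol}.
#'   Degenerate rows (whole-period displacement, or a zero-variance GLCM
#'   making \code{f3} undefined) are flagged, not dropped; their
#'   \code{withinTol} is \code{NA}.
#' @examples
#' rows <- runSweep(nLevels = 4, gradients = 1, displacements = 1,
#'                  width = 8, height = 8, mode = "cyclic")
#' subset(rows, feature == "f2")  # measured 3, predicted 3
#' @seealso [sweepSummary()], [sweepShapes()], [plotSweep()]
#' @export
runSweep <- function(nLevels = 256L, gradients = 1:7,
                     displacements = 1:8, width = 1024L, height = 1024L,
                     mode = c("noncyclic", "cyclic"),
                     axis = c("vertical", "horizontal"), rtol = NULL) {
  mode <- match.arg(mode)
  axis <- match.arg(axis)
  cyclic <- mode == "cyclic"
  if (is.null(rtol)) rtol <- if (cyclic) 1e-12 else 0.02
  featNames <- c("f1", "f2", "f3", "f5")
  out <- vector("list", length(gradients) * length(displacements))
  n <- 0L
  for (nb in as.integer(gradients)) {
    nt <- effectiveLevels(nLevels, nb)
    h <- if (cyclic) nt * max(1L, height %/% nt) else height
    spec <- GradientSpec(nLevels = nLevels, nabla = nb,
                         width = width, height = h, axis = axis)
    img <- makeLinearGradient(spec)
    for (d in as.integer(displacements)) {
      dxy <- if (axis == "vertical") c(0L, d) else c(d, 0L)
      g <- computeGLCM(img, dxy[1L], dxy[2L], cyclic = cyclic)
      fs <- haralickFeatures(g)
      pr <- predictAll(nLevels, nb, d)
      meas <- featureValues(fs)[c("f1ASM", "f2Contrast",
                                  "f3Correlation", "f5IDMAbs")]
      pred <- featureValues(pr)[c("f1ASM", "f2Contrast",
                                  "f3Correlation", "f5IDMAbs")]
      degen <- pr@degenerate | (featNames == "f3" &
                                  (is.nan(meas) | is.nan(pred)))
      absErr <- abs(meas - pred)
      relErr <- ifelse(pred == 0, absErr, absErr / abs(pred))
      n <- n + 1L
      out[[n]] <- data.frame(
        nLevels = nLevels, nabla = nb, d = d, nTilde = nt,
        feature = featNames, measured = unname(meas),
        predicted = unname(pred), absError = unname(absErr),
        relError = unname(relErr), mode = mode, degenerate = degen,
        withinTol = ifelse(degen, NA, unname(relErr) <= rtol),
        row.names = NULL)
    }
  }
  if (n == 0L) {
    return(data.frame(nLevels = integer(0), nabla = integer(0),
                      d = integer(0), nTilde = integer(0),
                      feature = character(0), measured = numeric(0),
                      predicted = numeric(0), absError = numeric(0),
                      relError = numeric(0), mode = character(0),
                      degenerate = logical(0), withinTol = logical(0)))
  }
  do.call(rbind, out)
}

#' Summarize a sweep: worst-case agreement per feature
#'
#' @param rows a data.frame from [runSweep()].
#' @return a data.frame with one row per feature: the number of
#'   non-degenerate rows, the maximum absolute and relative errors over
#'   them, and how many fell within the tolerance.
#' @export
sweepSummary <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L)
    return(data.frame(feature = character(0), n = integer(0),
                      maxAbsError = numeric(0), maxRelError = numeric(0),
                      nWithinTol = integer(0)))
  ok <- !rows$degenerate
  do.call(rbind, lapply(split(rows[ok, ], rows$feature[ok]), function(x) {
    data.frame(feature = x$feature[1L], n = nrow(x),
               maxAbsError = max(x$absError),
               maxRelError = max(x$relError),
               nWithinTol = sum(x$withinTol), row.names = NULL)
  }))
}

#' Check the qualitative shapes of the measured feature curves
#'
#' Verifies, per gradient magnitude, the characteristic dependence of
#' each measured feature on the displacement \code{d}: Energy flat in
#' \code{d}; Contrast and \code{1 - Correlation} proportional to
#' \code{d * (nTilde - d)} (Pearson correlation above
#' \code{1 - shapeTol}); IDM non-increasing in \code{d} over
#' \code{d <= nTilde / 2}.
#'
#' @param rows a data.frame from [runSweep()].
#' @param flatTol maximum allowed relative spread of Energy across
#'   \code{d}.
#' @param shapeTol slack on the Pearson correlation for the parabolic
#'   shapes.
#' @return a data.frame with one row per gradient and logical columns
#'   \code{f1Flat}, \code{f2Parabolic}, \code{f3Parabolic},
#'   \code{f5Decreasing}.
#' @export
sweepShapes <- function(rows, flatTol = 0.02, shapeTol = 0.01) {
  rows <- rows[!rows$degenerate, ]
  do.call(rbind, lapply(split(rows, rows$nabla), function(x) {
    nt <- x$nTilde[1L]
    f1 <- x$measured[x$feature == "f1"]
    f2 <- x$measured[x$feature == "f2"]
    f3 <- x$measured[x$feature == "f3"]
    f5 <- x$measured[x$feature == "f5"]
    d2 <- x$d[x$feature == "f2"]
    d5 <- x$d[x$feature == "f5"]
    shape <- d2 * (nt - d2)
    early <- d5 <= nt / 2
    data.frame(
      nabla = x$nabla[1L],
      f1Flat = diff(range(f1)) <= flatTol * mean(f1),
      f2Parabolic = stats::cor(f2, shape) >= 1 - shapeTol,
      f3Parabolic = stats::cor(1 - f3, shape) >= 1 - shapeTol,
      f5Decreasing = all(diff(f5[early][order(d5[early])]) <= 1e-9),
      row.names = NULL)
  }))
}

#' Plot measured vs predicted features against displacement
#'
#' One panel per feature: markers for the measured values, lines for the
#' analytic predictions, one series per gradient magnitude.
#'
#' @param rows a data.frame from [runSweep()].
#' @return a ggplot object.
#' @export
plotSweep <- function(rows) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the 'ggplot2' package")
  rows$nabla <- factor(rows$nabla)
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$d, colour = .data$nabla)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted,
                                    group = .data$nabla)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$measured)) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "displacement d", y = "feature value",
                  colour = expression(nabla),
                  title = "Haralick features: measured (points) vs analytic (lines)")
}
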