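# Growth and apoptosis scoring from live-cell imaging channels: cell surface
# area from phase contrast (label-free confluence surrogate) and integrated
# Annexin V+/YOYO-3+ intensity normalized to cell area ("apoptotic material").

#' Cell surface area from a phase-contrast image
#'
#' Phase-contrast cell footprints are textured while free background is
#' smooth, so the footprint mask is obtained by thresholding a local-variance
#' image (box window) with Otsu's method. Returns the mask area in px; a
#' blank field returns 0.
#'
#' @param phase phase-contrast matrix.
#' @param window odd box window width for the local variance (px).
#' @return non-negative integer area in px.
#' @export
cellArea <- function(phase, window = 7L) {
  phase <- .asMatrix(phase)
  stopifnot(window %% 2 == 1, window >= 3)
  if (max(phase) == min(phase)) return(0L)
  k <- matrix(1 / window^2, window, window)
  m1 <- as.matrix(EBImage::filter2(phase, k))
  m2 <- as.matrix(EBImage::filter2(phase^2, k))
  v <- sqrt(pmax(m2 - m1^2, 0))       # local sd
  if (max(v) == 0) return(0L)
  thr <- .otsuVec(as.vector(v))
  mask <- v > thr
  # close small gaps the variance ridge leaves inside footprints, then erode
  # back the half-window the box filter dilated the support by
  mask <- as.matrix(EBImage::closing(mask, EBImage::makeBrush(5, "disc"))) > 0
  mask <- as.matrix(EBImage::erode(mask, EBImage::makeBrush(window, "disc"))) > 0
  as.integer(sum(mask))
}

#' Integrated apoptotic material per unit cell area
#'
#' The double-positive region is \code{annexin > t_a AND yoyo3 > t_y}
#' (an OR mode is available for sensitivity analysis). The statistic is the
#' summed annexin + yoyo3 intensity over that region divided by the
#' phase-contrast cell area: 0 when the region is empty, an error when the
#' region is non-empty but the cell area is 0 (undefined normalization).
#' Multiplying both fluorescence channels (and thresholds) by a constant
#' scales the statistic by the same constant.
#'
#' @param annexin,yoyo3,phase aligned channel matrices.
#' @param posThreshold numeric pair \code{c(annexin, yoyo3)} of absolute
#'   positivity thresholds, or \code{"otsu"} for per-channel Otsu.
#' @param combine \code{"and"} (default, double-positive) or \code{"or"}.
#' @param window local-variance window passed to [cellArea()].
#' @return non-negative scalar.
#' @examples
#' a <- matrix(0, 32, 32); y <- matrix(0, 32, 32); p <- matrix(0, 32, 32)
#' apoptoticMaterial(a, y, p, posThreshold = c(10, 10))  # 0: no positives
#' @export
apoptoticMaterial <- function(annexin, yoyo3, phase,
                              posThreshold = "otsu",
                              combine = c("and", "or"),
                              window = 7L) {
  annexin <- .asMatrix(annexin); yoyo3 <- .asMatrix(yoyo3)
  phase <- .asMatrix(phase)
  combine <- match.arg(combine)
  stopifnot(all(dim(annexin) == dim(yoyo3)), all(dim(annexin) == dim(phase)))
  if (identical(posThreshold, "otsu")) {
    ta <- .otsuVec(as.vector(annexin)); ty <- .otsuVec(as.vector(yoyo3))
  } else {
    stopifnot(is.numeric(posThreshold), length(posThreshold) == 2L)
    ta <- posThreshold[1]; ty <- posThreshold[2]
  }
  pos <- if (combine == "and") (annexin > ta) & (yoyo3 > ty)
         else (annexin > ta) | (yoyo3 > ty)
  if (!any(pos)) return(0)
  area <- cellArea(phase, window = window)
  if (area == 0)
    stop("undefined normalization: positive apoptosis signal but zero cell area")
  sum(annexin[pos] + yoyo3[pos]) / area
}
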