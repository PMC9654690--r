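# Nuclei segmentation chain: rolling-ball background correction, median
# denoising, channel merging, locally adaptive thresholding, distance-transform
# watershed, small-mask removal. Pixel conventions: (row, col), origin
# top-left. Labelling is 4-connected (EBImage::bwlabel); the distance
# transform is Euclidean.

.asMatrix <- function(x) {
  if (!is.matrix(x)) stop("expected a single-channel y-by-x matrix")
  x
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale morphological opening with a
#' disc structuring element of the given radius (the classical flat-disc
#' implementation of the rolling-ball background) and subtracts it. A constant
#' image maps to zero, the output is non-negative and pointwise below the
#' input, and adding a constant offset to the input leaves the output
#' unchanged.
#'
#' @param image single-channel numeric matrix, values >= 0.
#' @param radiusPx ball radius in px; must exceed the typical object radius so
#'   that objects are removed from the background estimate.
#' @return background-subtracted matrix, same dimensions.
#' @examples
#' img <- matrix(100, 64, 64); img[30:34, 30:34] <- 600
#' corr <- rollingBall(img, 10)
#' range(corr)
#' @export
rollingBall <- function(image, radiusPx) {
  image <- .asMatrix(image)
  if (length(radiusPx) != 1L || radiusPx <= 0)
    stop("radiusPx must be a positive scalar")
  m <- max(image)
  if (m == 0) return(image)
  brush <- EBImage::makeBrush(2L * floor(radiusPx) + 1L, shape = "disc")
  bg <- m * EBImage::opening(image / m, brush)
  pmax(image - bg, 0)
}

#' Median denoising
#'
#' Replaces every pixel with the median of its \code{radiusPx} x
#' \code{radiusPx} neighborhood (odd window width). Idempotent on
#' piecewise-constant images away from edges; removes impulse noise.
#'
#' @param image single-channel numeric matrix.
#' @param radiusPx odd positive integer window width (e.g. 3 for a 3x3
#'   neighborhood).
#' @return filtered matrix.
#' @export
medianDenoise <- function(image, radiusPx) {
  image <- .asMatrix(image)
  if (length(radiusPx) != 1L || radiusPx <= 0 || radiusPx %% 2 != 1)
    stop("radiusPx must be a positive odd integer window width")
  if (radiusPx == 1L) return(image)
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(image)
  y <- (image - lo) / (hi - lo)
  out <- EBImage::medianFilter(y, size = (radiusPx - 1L) / 2L)
  as.matrix(out) * (hi - lo) + lo
}

#' Merge two fluorescence channels
#'
#' Pixelwise sum of the (already background-corrected) red and green channels;
#' commutative in its arguments. Nuclei visible in either reporter channel are
#' visible in the merge, so one segmentation serves both classes.
#'
#' @param red,green equally shaped numeric matrices.
#' @return their pixelwise sum.
#' @export
mergeChannels <- function(red, green) {
  red <- .asMatrix(red); green <- .asMatrix(green)
  if (!all(dim(red) == dim(green)))
    stop("channel shapes differ: ", paste(dim(red), collapse = "x"), " vs ",
         paste(dim(green), collapse = "x"))
  red + green
}

#' Segmentation parameters
#'
#' Defaults derive from the expected nucleus size: the small-mask cutoff is
#' 25\% of the area of a circle at the minimum expected radius, and the
#' watershed seed separation is 0.7 x the median expected radius. The adaptive
#' threshold uses a block of 1/8 of the smaller image dimension; its offset
#' defaults to 5\% of the image maximum (\code{NULL} = auto), which keeps flat
#' background — where roughly half of the pixels sit marginally above their
#' local mean — out of the mask.
#'
#' @param cellRadiusRange expected nucleus radius range (px) from which
#'   area/seed defaults are derived.
#' @param rollingBallRadiusPx rolling-ball radius (px).
#' @param medianRadiusPx odd median window width (px).
#' @param adaptiveBlockFrac adaptive threshold block size as a fraction of the
#'   smaller image dimension.
#' @param adaptiveOffset absolute intensity offset added to the local mean;
#'   \code{NULL} for 0.05 x image max.
#' @param minObjectAreaPx masks below this area are removed.
#' @param watershedMinSeedDistancePx minimum separation of distance-transform
#'   seed maxima (the maxima-suppression neighborhood width).
#' @param watershedTolerance minimum distance-map depth (px) between a seed
#'   maximum and its saddle for a split to be kept.
#' @return classed parameter list for [segmentNuclei()].
#' @export
segParams <- function(cellRadiusRange = c(8, 13),
                      rollingBallRadiusPx = 4 * max(cellRadiusRange),
                      medianRadiusPx = 3L,
                      adaptiveBlockFrac = 1 / 8,
                      adaptiveOffset = NULL,
                      minObjectAreaPx = round(0.25 * pi * min(cellRadiusRange)^2),
                      watershedMinSeedDistancePx = 0.7 * median(cellRadiusRange),
                      watershedTolerance = 0.5) {
  stopifnot(rollingBallRadiusPx > 0, medianRadiusPx %% 2 == 1,
            adaptiveBlockFrac > 0, adaptiveBlockFrac <= 1,
            minObjectAreaPx > 0, watershedMinSeedDistancePx > 0,
            watershedTolerance > 0)
  p <- list(rollingBallRadiusPx = rollingBallRadiusPx,
            medianRadiusPx = as.integer(medianRadiusPx),
            adaptiveBlockFrac = adaptiveBlockFrac,
            adaptiveOffset = adaptiveOffset,
            minObjectAreaPx = as.integer(minObjectAreaPx),
            watershedMinSeedDistancePx = watershedMinSeedDistancePx,
            watershedTolerance = watershedTolerance)
  class(p) <- "SegParams"
  p
}

#' Segment nuclei from a background-corrected image
#'
#' Locally adaptive (local mean + offset) thresholding, optional
#' distance-transform watershed to split touching nuclei (seeds are local
#' maxima of the Euclidean distance map separated by at least
#' \code{watershedMinSeedDistancePx}), removal of masks below
#' \code{minObjectAreaPx}, and compaction of labels to \code{1..nObjects}.
#' With \code{doWatershed = FALSE}, connected masks are labelled as-is
#' (4-connectivity), reproducing pipelines whose masks may contain multiple
#' nuclei — see [excludeMultinucleated()].
#'
#' @param image background-corrected single-channel matrix (e.g. the output of
#'   [mergeChannels()] on rolling-ball-corrected channels).
#' @param params a [segParams()] object.
#' @param doWatershed split touching objects (default TRUE).
#' @return a [LabelMap-class]; an all-zero image yields 0 objects.
#' @examples
#' fld <- generateField(synthImageConfig(fieldSize = c(256, 256), nCells = 8,
#'                                       seed = 5))
#' corr <- rollingBall(channelPlane(fld$image, "dna"), 50)
#' seg <- segmentNuclei(corr, segParams())
#' nObjects(seg)
#' @export
segmentNuclei <- function(image, params = segParams(), doWatershed = TRUE) {
  image <- .asMatrix(image)
  empty <- function() LabelMap(matrix(0L, nrow(image), ncol(image)))
  m <- max(image)
  if (m <= 0) return(empty())
  block <- round(min(dim(image)) * params$adaptiveBlockFrac)
  w <- max(1L, (block - 1L) %/% 2L)
  offset <- if (is.null(params$adaptiveOffset)) 0.05 * m else params$adaptiveOffset
  binary <- EBImage::thresh(image / m, w = w, h = w, offset = offset / m)
  binary <- as.matrix(binary)
  if (!any(binary > 0)) return(empty())
  comp <- as.matrix(EBImage::bwlabel(binary))
  lab <- if (doWatershed) {
    dm <- EBImage::distmap(binary)
    ws <- as.matrix(EBImage::watershed(dm, tolerance = params$watershedTolerance,
                                       ext = .seedExt(params$watershedMinSeedDistancePx)))
    # restrict the watershed to within-component splits: with a wide seed
    # neighborhood a small object near a larger one loses its seed and gets
    # flooded with the neighbor's label across background, so labels are
    # re-keyed on (component, basin) pairs
    key <- comp * (max(ws) + 1) + ws
    key[comp == 0L] <- 0
    matrix(match(key, sort(unique(key[key > 0]))), nrow(comp), ncol(comp)) |>
      (\(x) { x[is.na(x)] <- 0L; x })()
  } else {
    comp
  }
  .compactLabels(lab, params$minObjectAreaPx)
}

# drop objects below minArea, renumber labels to 1..n
.compactLabels <- function(lab, minArea = 1L) {
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n == 0L) return(LabelMap(lab))
  areas <- tabulate(lab, nbins = n)
  keep <- which(areas >= minArea)
  lut <- integer(n + 1L)
  lut[keep + 1L] <- seq_along(keep)
  LabelMap(matrix(lut[lab + 1L], nrow(lab), ncol(lab)))
}

# the maxima-suppression neighborhood half-width equivalent to a minimum
# seed separation (neighborhood width 2*ext+1 ~ the separation)
.seedExt <- function(minSeedDist) max(1L, floor(minSeedDist / 2))

# number of distance-transform seed maxima in one binary mask, under the
# same seeding rule the watershed uses
.seedCount <- function(mask, minSeedDist, tolerance = 0.5) {
  if (!any(mask > 0)) return(0L)
  dm <- EBImage::distmap(mask)
  ws <- EBImage::watershed(dm, tolerance = tolerance,
                           ext = .seedExt(minSeedDist))
  as.integer(max(ws))
}

#' Match a segmentation against ground truth
#'
#' Centroid-in-mask matching: a ground-truth cell is recovered when its
#' painted centroid falls inside an object that claims no other centroid.
#'
#' @param map a [LabelMap-class].
#' @param truth a [GroundTruth-class].
#' @return list with \code{recall}, \code{precision}, and \code{labelOfCell}
#'   (integer vector, 0 = unmatched, aligned to \code{gtCells(truth)}).
#' @export
matchSegmentation <- function(map, truth) {
  cells <- gtCells(truth)
  lab <- labelMatrix(map)
  n <- nObjects(map)
  if (!nrow(cells))
    return(list(recall = NA_real_, precision = NA_real_,
                labelOfCell = integer(0)))
  hit <- lab[cbind(pmin(pmax(round(cells$y), 1L), nrow(lab)),
                   pmin(pmax(round(cells$x), 1L), ncol(lab)))]
  claims <- tabulate(hit[hit > 0], nbins = max(n, 1L))
  good <- hit > 0 & claims[pmax(hit, 1L)] == 1L
  list(recall = mean(good),
       precision = if (n > 0) sum(claims == 1L) / n else NA_real_,
       labelOfCell = as.integer(ifelse(good, hit, 0L)))
}
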