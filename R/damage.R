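# DNA-damage readouts: foci per nucleus (gamma-H2AX / 53BP1) from z-stack
# maximum intensity projections, and the percentage of cells harboring at
# least one micronucleus.

#' Focus-counting parameters
#'
#' Defaults (at 0.32 um/px): focus area bounds \[4, 200\] px, per-nucleus Otsu
#' thresholding on the damage-channel MIP restricted to the nucleus mask, and
#' a light Gaussian pre-smoothing (sd 1 px). Two guards suppress spurious
#' detections in nuclei that carry no foci: the intensity range inside the
#' nucleus must exceed \code{minContrast} counts, and a candidate focus is
#' kept only when its peak rises at least \code{minProminenceMads}
#' median-absolute-deviations above the median nucleus intensity (an Otsu
#' split of pure noise or of a smooth background fails one of the two).
#'
#' @param focusMinAreaPx,focusMaxAreaPx inclusive focus area bounds (px).
#' @param thresholdMethod \code{"per-nucleus-otsu"} (default), \code{"otsu"}
#'   (one global threshold) or \code{"fixed"}.
#' @param fixedThreshold absolute threshold when \code{thresholdMethod} is
#'   \code{"fixed"}.
#' @param excludeMultinucleated drop masks containing multiple nuclei before
#'   counting (the ex vivo biopsy profile).
#' @param smoothSigma Gaussian pre-smoothing sd in px (0 disables).
#' @param minContrast minimum within-nucleus intensity range (counts).
#' @param minProminenceMads minimum focus-peak prominence in MADs.
#' @param wsTolerance watershed tolerance for splitting merged foci, as a
#'   fraction of the above-threshold dynamic range.
#' @param minSeedDistancePx seed separation used by the multinucleated rule.
#' @return classed parameter list for [countFoci()].
#' @export
fociParams <- function(focusMinAreaPx = 4L, focusMaxAreaPx = 200L,
                       thresholdMethod = c("per-nucleus-otsu", "otsu", "fixed"),
                       fixedThreshold = NA_real_,
                       excludeMultinucleated = FALSE,
                       smoothSigma = 0.75,
                       minContrast = 50,
                       minProminenceMads = 5,
                       wsTolerance = 0.08,
                       minSeedDistancePx = 7) {
  thresholdMethod <- match.arg(thresholdMethod)
  stopifnot(focusMinAreaPx > 0, focusMinAreaPx < focusMaxAreaPx,
            smoothSigma >= 0, minContrast >= 0, wsTolerance > 0)
  if (thresholdMethod == "fixed" && !is.finite(fixedThreshold))
    stop("fixedThreshold must be supplied for thresholdMethod = 'fixed'")
  p <- list(focusMinAreaPx = as.integer(focusMinAreaPx),
            focusMaxAreaPx = as.integer(focusMaxAreaPx),
            thresholdMethod = thresholdMethod,
            fixedThreshold = fixedThreshold,
            excludeMultinucleated = excludeMultinucleated,
            smoothSigma = smoothSigma, minContrast = minContrast,
            minProminenceMads = minProminenceMads,
            wsTolerance = wsTolerance,
            minSeedDistancePx = minSeedDistancePx)
  class(p) <- "FociParams"
  p
}

.otsuVec <- function(vals) {
  r <- range(vals)
  if (diff(r) == 0) return(r[2])
  EBImage::otsu(matrix((vals - r[1]) / diff(r), nrow = 1),
                range = c(0, 1)) * diff(r) + r[1]
}

#' Count damage foci per nucleus
#'
#' Takes the maximum intensity projection of the damage channel, thresholds it
#' per nucleus (auto-thresholding restricted to the nucleus mask by default),
#' keeps connected components within the configured area bounds, splits
#' multi-peaked components by an intensity watershed, and counts per nucleus.
#' A focus overlapping the nucleus boundary is counted for the nucleus that
#' contains its peak pixel; foci outside any nucleus are ignored.
#'
#' @param stack an [ImageStack-class] with a \code{damage} role (and
#'   \code{dna} when \code{excludeMultinucleated} is set).
#' @param nuclei a [LabelMap-class] on the same field.
#' @param params a [fociParams()] object.
#' @return data.frame with columns \code{cell_id, n_foci, nucleus_area_px};
#'   empty when no nuclei are present. When masks were excluded as
#'   multinucleated the returned \code{cell_id}s refer to the compacted map in
#'   \code{attr(x, "nuclei")}.
#' @examples
#' cfg <- synthImageConfig(fieldSize = c(256, 256), nCells = 6,
#'                         meanFociPerCell = 3, seed = 11)
#' fld <- generateField(cfg)
#' seg <- segmentNuclei(rollingBall(channelPlane(fld$image, "dna"), 50))
#' head(countFoci(fld$image, seg))
#' @export
countFoci <- function(stack, nuclei, params = fociParams()) {
  if (params$excludeMultinucleated)
    nuclei <- excludeMultinucleated(nuclei, mip(stack, "dna"),
                                    minSeedDistancePx = params$minSeedDistancePx)
  n <- nObjects(nuclei)
  out <- data.frame(cell_id = integer(0), n_foci = integer(0),
                    nucleus_area_px = integer(0))
  if (n == 0L) {
    attr(out, "nuclei") <- nuclei
    return(out)
  }
  dmip <- mip(stack, "damage")
  if (params$smoothSigma > 0) {
    m <- max(dmip)
    if (m > 0)
      dmip <- as.matrix(EBImage::gblur(dmip / m, sigma = params$smoothSigma)) * m
  }
  lab <- labelMatrix(nuclei)
  globalThr <- if (params$thresholdMethod == "otsu")
    .otsuVec(dmip[lab > 0]) else NA_real_
  areas <- tabulate(lab[lab > 0], nbins = n)
  counts <- integer(n)
  H <- nrow(lab); W <- ncol(lab)
  bbox <- .labelBoxes(lab, n, pad = 3L)
  for (i in seq_len(n)) {
    b <- bbox[[i]]
    sub <- dmip[b$ys, b$xs]
    inNuc <- lab[b$ys, b$xs] == i
    vals <- sub[inNuc]
    if (diff(range(vals)) < params$minContrast) next
    thr <- switch(params$thresholdMethod,
      "per-nucleus-otsu" = .otsuVec(vals),
      "otsu" = globalThr,
      "fixed" = params$fixedThreshold)
    prominence <- median(vals) + params$minProminenceMads * mad(vals)
    fmask <- sub > thr
    if (!any(fmask)) next
    top <- max(sub[fmask])
    if (top <= thr) next
    rel <- pmax(sub - thr, 0) / (top - thr)
    rel[!fmask] <- 0
    ws <- as.matrix(EBImage::watershed(rel, tolerance = params$wsTolerance,
                                       ext = 1))
    nf <- max(ws)
    if (nf == 0) next
    for (k in seq_len(nf)) {
      kmask <- ws == k
      a <- sum(kmask)
      if (a < params$focusMinAreaPx || a > params$focusMaxAreaPx) next
      if (params$thresholdMethod != "fixed" && max(sub[kmask]) < prominence) next
      pk <- which(kmask & rel == max(rel[kmask]), arr.ind = TRUE)[1, ]
      if (inNuc[pk[1], pk[2]]) counts[i] <- counts[i] + 1L
    }
  }
  out <- data.frame(cell_id = seq_len(n), n_foci = counts,
                    nucleus_area_px = areas)
  attr(out, "nuclei") <- nuclei
  out
}

# padded bounding boxes per label
.labelBoxes <- function(lab, n, pad = 0L) {
  idx <- which(lab > 0, arr.ind = TRUE)
  v <- lab[lab > 0]
  lapply(seq_len(n), function(i) {
    sel <- v == i
    ys <- range(idx[sel, 1]); xs <- range(idx[sel, 2])
    list(ys = max(1L, ys[1] - pad):min(nrow(lab), ys[2] + pad),
         xs = max(1L, xs[1] - pad):min(ncol(lab), xs[2] + pad))
  })
}

#' Exclude masks containing multiple nuclei
#'
#' Removes labels whose mask holds two or more distance-transform seed maxima
#' under the same seeding rule the segmentation watershed uses (local maxima
#' of the Euclidean distance map separated by at least
#' \code{minSeedDistancePx}); remaining labels are compacted. This reproduces
#' the rule that DNA-stain masks containing multiple nuclei are excluded from
#' per-cell quantification in tissue-section pipelines.
#'
#' @param nuclei a [LabelMap-class].
#' @param dnaMip the DNA-channel MIP the map was segmented from (kept for
#'   interface symmetry; the rule is driven by mask geometry).
#' @param minSeedDistancePx minimum seed separation in px.
#' @return a [LabelMap-class] with multinucleated masks removed; an empty map
#'   maps to an empty map.
#' @export
excludeMultinucleated <- function(nuclei, dnaMip = NULL, minSeedDistancePx = 7) {
  n <- nObjects(nuclei)
  if (n == 0L) return(nuclei)
  lab <- labelMatrix(nuclei)
  bbox <- .labelBoxes(lab, n, pad = 1L)
  multi <- vapply(seq_len(n), function(i) {
    mask <- lab[bbox[[i]]$ys, bbox[[i]]$xs] == i
    .seedCount(mask, minSeedDistancePx) >= 2L
  }, logical(1))
  if (!any(multi)) return(nuclei)
  message(sum(multi), " multinucleated mask(s) excluded")
  lut <- integer(n + 1L)
  lut[which(!multi) + 1L] <- seq_len(sum(!multi))
  LabelMap(matrix(lut[lab + 1L], nrow(lab), ncol(lab)))
}

#' Micronucleus-detection parameters
#'
#' @param mnMinAreaPx minimum candidate area (px).
#' @param mnMaxAreaFrac maximum candidate area as a fraction of the parent
#'   nucleus area, in (0, 1).
#' @param maxDistancePx assignment radius: candidates farther than this from
#'   every nucleus centroid are dropped (and reported via a message).
#' @return classed parameter list for [detectMicronuclei()].
#' @export
micronucleusParams <- function(mnMinAreaPx = 4L, mnMaxAreaFrac = 0.5,
                               maxDistancePx = 30) {
  stopifnot(mnMinAreaPx > 0, mnMaxAreaFrac > 0, mnMaxAreaFrac < 1,
            maxDistancePx > 0)
  p <- list(mnMinAreaPx = as.integer(mnMinAreaPx),
            mnMaxAreaFrac = mnMaxAreaFrac, maxDistancePx = maxDistancePx)
  class(p) <- "MicronucleusParams"
  p
}

#' Detect micronuclei and assign them to parent nuclei
#'
#' DNA-positive connected components (global Otsu on the DNA MIP) that are not
#' part of any segmented nucleus, with area between \code{mnMinAreaPx} and
#' \code{mnMaxAreaFrac} x the parent nucleus area, are assigned to the nucleus
#' with the nearest centroid within \code{maxDistancePx}. Distance ties are
#' broken toward the lower cell id. Unassignable candidates are dropped and
#' reported via a message.
#'
#' @param dnaMip DNA-channel maximum intensity projection (matrix).
#' @param nuclei a [LabelMap-class] segmented on the same image.
#' @param params a [micronucleusParams()] object.
#' @return named integer vector: micronucleus count per cell id.
#' @export
detectMicronuclei <- function(dnaMip, nuclei, params = micronucleusParams()) {
  dnaMip <- .asMatrix(dnaMip)
  lab <- labelMatrix(nuclei)
  n <- nObjects(nuclei)
  counts <- setNames(integer(n), seq_len(n))
  if (n == 0L) return(counts)
  thr <- .otsuVec(as.vector(dnaMip))
  cand <- dnaMip > thr
  # exclude nucleus masks plus a 1-px guard ring
  grown <- as.matrix(EBImage::dilate(lab > 0,
                                     EBImage::makeBrush(3, "box"))) > 0
  cand[grown] <- FALSE
  if (!any(cand)) return(counts)
  clab <- as.matrix(EBImage::bwlabel(cand))
  nc <- max(clab)
  if (nc == 0) return(counts)
  nucAreas <- tabulate(lab[lab > 0], nbins = n)
  nucCent <- .centroids(lab, n)
  candCent <- .centroids(clab, nc)
  candAreas <- tabulate(clab[clab > 0], nbins = nc)
  dropped <- 0L
  for (k in seq_len(nc)) {
    if (candAreas[k] < params$mnMinAreaPx) next
    d <- sqrt((nucCent[, 1] - candCent[k, 1])^2 +
              (nucCent[, 2] - candCent[k, 2])^2)
    ok <- which(d <= params$maxDistancePx &
                candAreas[k] <= params$mnMaxAreaFrac * nucAreas)
    if (!length(ok)) { dropped <- dropped + 1L; next }
    parent <- ok[order(d[ok], ok)][1]   # nearest; ties to lower cell_id
    counts[parent] <- counts[parent] + 1L
  }
  if (dropped > 0)
    message(dropped, " micronucleus candidate(s) dropped (no parent nucleus ",
            "within ", params$maxDistancePx, " px or too large)")
  counts
}

.centroids <- function(lab, n) {
  idx <- which(lab > 0, arr.ind = TRUE)
  v <- lab[lab > 0]
  cbind(y = as.vector(rowsum(idx[, 1], v)) / tabulate(v, n),
        x = as.vector(rowsum(idx[, 2], v)) / tabulate(v, n))
}

#' Percentage of cells with at least one micronucleus
#'
#' Pools per-cell micronucleus counts over one or more fields of view and
#' returns \code{100 * (#cells with >= 1 micronucleus) / (#cells)}.
#'
#' @param counts integer vector from [detectMicronuclei()], or a list of such
#'   vectors (one per field).
#' @return percentage in \[0, 100\].
#' @examples
#' percentWithMicronucleus(c(0, 1, 0, 2, 0))  # 40
#' @export
percentWithMicronucleus <- function(counts) {
  if (is.list(counts)) counts <- unlist(counts, use.names = FALSE)
  if (!length(counts)) stop("no cells: cannot compute a percentage")
  100 * mean(counts >= 1)
}
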