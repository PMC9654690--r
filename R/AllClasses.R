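#' @import methods
#' @importFrom stats median rnorm runif rpois rbinom quantile sd
#'   oneway.test p.adjust plogis uniroot rlnorm mad setNames
#' @importFrom utils modifyList
NULL

#' Multi-channel, multi-plane image container
#'
#' An \code{ImageStack} holds a fluorescence microscopy field as a numeric
#' array indexed \code{[channel, z, y, x]}, together with the biological role
#' of each channel (e.g. \code{dna}, \code{red}, \code{green}, \code{damage})
#' and the lateral pixel size in micrometers. Single-plane images use
#' \code{z = 1}. Pixel values are non-negative photon-count-like intensities.
#'
#' @slot pixels numeric array, dimensions channels x z x y x x, all values >= 0.
#' @slot channelRoles named integer vector mapping role names to channel
#'   indices; indices must be unique and within bounds.
#' @slot pixelSizeUm positive numeric scalar, micrometers per pixel.
#'
#' @seealso [channelPlane()], [mip()], [generateField()]
#' @export
setClass("ImageStack",
  representation(
    pixels = "array",
    channelRoles = "integer",
    pixelSizeUm = "numeric"
  )
)

setValidity("ImageStack", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 4L)
    return("pixels must be a 4-d array [channel, z, y, x]")
  if (any(p < 0))
    return("pixel values must be non-negative")
  roles <- object@channelRoles
  if (is.null(names(roles)) || any(!nzchar(names(roles))))
    return("channelRoles must be a named integer vector")
  if (anyDuplicated(roles) || anyDuplicated(names(roles)))
    return("channelRoles indices and names must be unique")
  if (any(roles < 1L) || any(roles > dim(p)[1L]))
    return("channelRoles indices out of bounds")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a positive scalar")
  TRUE
})

#' Integer-labelled segmentation mask
#'
#' A \code{LabelMap} is a y-by-x integer matrix in which 0 is background and
#' labels \code{1..nObjects} identify segmented objects (compact labelling:
#' every value in \code{1..nObjects} is present). Objects whose mask touches
#' the image border are flagged; they are kept for counting but excluded from
#' per-cell intensity statistics, since partial cells bias intensity-based
#' classification.
#'
#' @slot labels integer matrix (y by x), values in \code{0..nObjects}.
#' @slot border integer vector of labels touching the image border.
#'
#' @seealso [segmentNuclei()], [nObjects()], [borderLabels()]
#' @export
setClass("LabelMap",
  representation(labels = "matrix", border = "integer")
)

setValidity("LabelMap", function(object) {
  lab <- object@labels
  if (!is.numeric(lab)) return("labels must be numeric")
  if (any(lab < 0)) return("labels must be non-negative")
  n <- if (length(lab)) max(lab) else 0
  present <- sort(unique(as.integer(lab[lab > 0])))
  if (n > 0 && !identical(present, seq_len(as.integer(n))))
    return("labels must form a contiguous set 1..nObjects")
  if (any(!(object@border %in% present)))
    return("border flags must reference existing labels")
  TRUE
})

#' Ground truth record of a synthetic field
#'
#' Everything the synthetic generator painted: one row per cell (centroid,
#' radius, Fucci class, painted focus and micronucleus counts, apoptotic flag,
#' painted red/green amplitudes, painted pixel count), plus one row per painted
#' focus and per painted micronucleus referencing its parent cell.
#'
#' @slot cells data.frame with columns \code{cell_id, y, x, radius,
#'   fucci_class, n_foci, n_micronuclei, apoptotic, red_amp, green_amp,
#'   n_pixels}.
#' @slot foci data.frame with columns \code{cell_id, y, x, radius, z}.
#' @slot micronuclei data.frame with columns \code{cell_id, y, x, radius}.
#'
#' @seealso [generateField()]
#' @export
setClass("GroundTruth",
  representation(cells = "data.frame", foci = "data.frame",
                 micronuclei = "data.frame")
)

setValidity("GroundTruth", function(object) {
  ids <- object@cells$cell_id
  if (anyDuplicated(ids)) return("cell_ids must be unique")
  if (length(ids) && any(ids <= 0)) return("cell_ids must be positive")
  if (nrow(object@foci) && !all(object@foci$cell_id %in% ids))
    return("every focus must reference an existing cell_id")
  if (nrow(object@micronuclei) && !all(object@micronuclei$cell_id %in% ids))
    return("every micronucleus must reference an existing cell_id")
  TRUE
})

#' Three-component Gaussian mixture model of Fucci intensities
#'
#' Fitted on \code{log10(1 + intensity)} (red, green) features with full
#' covariances. Components are mapped to biological classes by the ratio rule:
#' the component with the highest red-to-green mean ratio is \code{red}, the
#' lowest is \code{green}, the remaining one is \code{both}. The mapping
#' depends only on component means, so relabelling mixture components never
#' changes the biological assignment.
#'
#' @slot means 3 x 2 matrix of component means in feature space
#'   (columns red, green).
#' @slot covariances 2 x 2 x 3 array of component covariances.
#' @slot weights numeric(3) mixing weights, summing to 1.
#' @slot classOfComponent character(3), a bijection onto
#'   \code{c("red","green","both")}.
#' @slot transform character scalar describing the feature transform.
#'
#' @seealso [fitFucciModel()], [classifyCells()]
#' @export
setClass("FucciModel",
  representation(
    means = "matrix",
    covariances = "array",
    weights = "numeric",
    classOfComponent = "character",
    transform = "character"
  )
)

setValidity("FucciModel", function(object) {
  if (!all(dim(object@means) == c(3L, 2L)))
    return("means must be 3 x 2")
  if (!all(dim(object@covariances) == c(2L, 2L, 3L)))
    return("covariances must be 2 x 2 x 3")
  if (abs(sum(object@weights) - 1) > 1e-9)
    return("weights must sum to 1")
  if (!setequal(object@classOfComponent, c("red", "green", "both")))
    return("classOfComponent must be a bijection onto {red, green, both}")
  TRUE
})

#' @describeIn ImageStack-class compact display
#' @param object an \code{ImageStack}
#' @export
setMethod("show", "ImageStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageStack: %d channel(s) [%s], %d z-plane(s), %d x %d px, %.3g um/px\n",
    d[1], paste(names(object@channelRoles), collapse = ", "),
    d[2], d[3], d[4], object@pixelSizeUm))
})

#' @describeIn LabelMap-class compact display
#' @param object a \code{LabelMap}
#' @export
setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap: %d object(s) on %d x %d px (%d touching border)\n",
    nObjects(object), nrow(object@labels), ncol(object@labels),
    length(object@border)))
})

#' @describeIn GroundTruth-class compact display
#' @param object a \code{GroundTruth}
#' @export
setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d cell(s), %d focus record(s), %d micronucleus record(s)\n",
    nrow(object@cells), nrow(object@foci), nrow(object@micronuclei)))
})

#' @describeIn FucciModel-class compact display
#' @param object a \code{FucciModel}
#' @export
setMethod("show", "FucciModel", function(object) {
  cat("FucciModel (3-component GMM on", object@transform, "features)\n")
  m <- cbind(object@means, weight = object@weights)
  rownames(m) <- object@classOfComponent
  colnames(m)[1:2] <- c("red", "green")
  print(round(m, 4))
})
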