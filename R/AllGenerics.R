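#' Number of segmented objects
#'
#' @param x a [LabelMap-class]
#' @return integer count of labelled objects (0 for an empty mask).
#' @examples
#' lm <- LabelMap(matrix(c(0L, 1L, 1L, 2L), 2, 2))
#' nObjects(lm)
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @rdname nObjects
#' @export
setMethod("nObjects", "LabelMap", function(x) {
  if (length(x@labels)) as.integer(max(x@labels)) else 0L
})

#' Labels of objects touching the image border
#'
#' Border-touching objects are kept for counting but excluded from per-cell
#' intensity statistics.
#'
#' @param x a [LabelMap-class]
#' @return integer vector of border-touching labels (possibly empty).
#' @export
setGeneric("borderLabels", function(x) standardGeneric("borderLabels"))

#' @rdname borderLabels
#' @export
setMethod("borderLabels", "LabelMap", function(x) x@border)

#' Label matrix accessor
#'
#' @param x a [LabelMap-class]
#' @return the integer y-by-x label matrix (0 = background).
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname labelMatrix
#' @export
setMethod("labelMatrix", "LabelMap", function(x) x@labels)

#' Channel role accessor
#'
#' @param x an [ImageStack-class]
#' @return named integer vector mapping channel roles to channel indices.
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname channelRoles
#' @export
setMethod("channelRoles", "ImageStack", function(x) x@channelRoles)

#' Pixel size accessor
#'
#' @param x an [ImageStack-class]
#' @return lateral pixel size in micrometers per pixel.
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))

#' @rdname pixelSizeUm
#' @export
setMethod("pixelSizeUm", "ImageStack", function(x) x@pixelSizeUm)

#' Ground-truth tables
#'
#' Accessors for the painted-object records of a synthetic field.
#'
#' @param x a [GroundTruth-class]
#' @return a data.frame (see the class documentation for columns).
#' @export
setGeneric("gtCells", function(x) standardGeneric("gtCells"))

#' @rdname gtCells
#' @export
setMethod("gtCells", "GroundTruth", function(x) x@cells)

#' @rdname gtCells
#' @export
setGeneric("gtFoci", function(x) standardGeneric("gtFoci"))

#' @rdname gtCells
#' @export
setMethod("gtFoci", "GroundTruth", function(x) x@foci)

#' @rdname gtCells
#' @export
setGeneric("gtMicronuclei", function(x) standardGeneric("gtMicronuclei"))

#' @rdname gtCells
#' @export
setMethod("gtMicronuclei", "GroundTruth", function(x) x@micronuclei)

#' Extract one channel plane
#'
#' @param x an [ImageStack-class]
#' @param role channel role name (e.g. \code{"dna"}).
#' @param z z-plane index (default 1).
#' @return numeric y-by-x matrix.
#' @export
setGeneric("channelPlane", function(x, role, z = 1L) standardGeneric("channelPlane"))

#' @rdname channelPlane
#' @export
setMethod("channelPlane", "ImageStack", function(x, role, z = 1L) {
  ch <- .roleIndex(x, role)
  x@pixels[ch, z, , ]
})

#' Maximum intensity projection
#'
#' Collapses the z dimension of one channel by the pixelwise maximum across
#' planes, the standard projection used before segmenting nuclei and damage
#' foci from widefield z-stacks.
#'
#' @param x an [ImageStack-class]
#' @param role channel role name.
#' @return numeric y-by-x matrix, pointwise \code{>=} every individual plane.
#' @examples
#' cfg <- synthImageConfig(fieldSize = c(64, 64), nCells = 3, zPlanes = 3, seed = 1)
#' fld <- generateField(cfg)
#' proj <- mip(fld$image, "dna")
#' @export
setGeneric("mip", function(x, role) standardGeneric("mip"))

#' @rdname mip
#' @export
setMethod("mip", "ImageStack", function(x, role) {
  ch <- .roleIndex(x, role)
  nz <- dim(x@pixels)[2L]
  out <- x@pixels[ch, 1L, , ]
  if (nz > 1L) for (z in seq(2L, nz)) out <- pmax(out, x@pixels[ch, z, , ])
  out
})

.roleIndex <- function(stack, role) {
  roles <- stack@channelRoles
  if (!role %in% names(roles))
    stop("channel role '", role, "' not present (available: ",
         paste(names(roles), collapse = ", "), ")")
  roles[[role]]
}

#' Construct an ImageStack
#'
#' @param pixels numeric array \code{[channel, z, y, x]}; a 3-d
#'   \code{[channel, y, x]} array is promoted to a single z-plane. A named
#'   list of equally sized y-by-x matrices is also accepted (one single-plane
#'   channel per element; names become the roles).
#' @param channelRoles named integer vector or character vector of role names
#'   in channel order; taken from the list names when \code{pixels} is a list.
#' @param pixelSizeUm micrometers per pixel (default 0.32, a 10x widefield
#'   objective context).
#' @return an [ImageStack-class]
#' @export
ImageStack <- function(pixels, channelRoles, pixelSizeUm = 0.32) {
  if (is.list(pixels)) {
    stopifnot(!is.null(names(pixels)), all(vapply(pixels, is.matrix, logical(1))))
    if (missing(channelRoles)) channelRoles <- names(pixels)
    d <- dim(pixels[[1]])
    arr <- array(0, dim = c(length(pixels), 1L, d[1], d[2]))
    for (i in seq_along(pixels)) arr[i, 1L, , ] <- pixels[[i]]
    pixels <- arr
  }
  if (length(dim(pixels)) == 3L)
    dim(pixels) <- c(dim(pixels)[1L], 1L, dim(pixels)[2:3])
  if (is.character(channelRoles))
    channelRoles <- setNames(seq_along(channelRoles), channelRoles)
  new("ImageStack", pixels = pixels,
      channelRoles = vapply(channelRoles, as.integer, integer(1)),
      pixelSizeUm = pixelSizeUm)
}

#' Construct a LabelMap
#'
#' Flags border-touching labels automatically.
#'
#' @param labels integer y-by-x matrix, 0 = background, labels compact.
#' @return a [LabelMap-class]
#' @export
LabelMap <- function(labels) {
  storage.mode(labels) <- "integer"
  border <- sort(unique(c(labels[1, ], labels[nrow(labels), ],
                          labels[, 1], labels[, ncol(labels)])))
  border <- border[border > 0L]
  new("LabelMap", labels = labels, border = as.integer(border))
}
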