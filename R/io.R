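# File interchange: multi-page TIFF image stacks with a channel-role sidecar
# JSON, ground truth as JSON + per-cell CSV, label maps as 16-bit TIFF,
# abundance matrices as TSV (empty cell = missing), and run configuration as
# YAML/JSON.

.TIFF_SCALE <- 65535

#' Write / read an ImageStack as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered channel-major (channel 1 planes z = 1..Z, then channel
#' 2, ...). Intensities are stored as 16-bit counts (values are clipped to
#' \[0, 65535\] and quantized to integers); the sidecar
#' (\code{<file>.json}) records channel roles, plane count, pixel size and
#' the coordinate convention ((row, col), 0-based origin top-left).
#'
#' @param stack an [ImageStack-class].
#' @param path output TIFF path; the sidecar is written next to it.
#' @return \code{writeImageStack}: the path, invisibly. \code{readImageStack}:
#'   the reconstructed [ImageStack-class].
#' @export
writeImageStack <- function(stack, path) {
  d <- dim(stack@pixels)
  pages <- vector("list", d[1] * d[2])
  i <- 0L
  for (ch in seq_len(d[1])) for (z in seq_len(d[2])) {
    i <- i + 1L
    pages[[i]] <- pmin(pmax(stack@pixels[ch, z, , ], 0), .TIFF_SCALE) / .TIFF_SCALE
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(
    channel_roles = as.list(stack@channelRoles),
    z_planes = d[2], pixel_size_um = stack@pixelSizeUm,
    intensity_scale = .TIFF_SCALE,
    coordinates = "(row, col), 0-based, origin top-left, half-open crop intervals")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeImageStack
#' @param path TIFF path written by [writeImageStack()].
#' @export
readImageStack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  pages <- tiff::readTIFF(path, all = TRUE)
  roles <- vapply(meta$channel_roles, as.integer, integer(1))
  nz <- as.integer(meta$z_planes)
  nch <- length(roles)
  stopifnot(length(pages) == nch * nz)
  d <- dim(pages[[1]])
  px <- array(0, dim = c(nch, nz, d[1], d[2]))
  i <- 0L
  for (ch in seq_len(nch)) for (z in seq_len(nz)) {
    i <- i + 1L
    px[ch, z, , ] <- pages[[i]] * meta$intensity_scale
  }
  ImageStack(px, roles, pixelSizeUm = as.numeric(meta$pixel_size_um))
}

#' Write a label map as 16-bit single-channel TIFF
#'
#' @param map a [LabelMap-class].
#' @param path output path.
#' @export
writeLabelMap <- function(map, path) {
  tiff::writeTIFF(labelMatrix(map) / .TIFF_SCALE, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeLabelMap
#' @export
readLabelMap <- function(path) {
  LabelMap(matrix(as.integer(round(tiff::readTIFF(path) * .TIFF_SCALE)),
                  nrow = dim(tiff::readTIFF(path))[1]))
}

#' Write / read ground truth as JSON plus per-cell CSV
#'
#' @param truth a [GroundTruth-class].
#' @param stem output path stem; writes \code{<stem>.json} (full record) and
#'   \code{<stem>_cells.csv} (per-cell table).
#' @export
writeGroundTruth <- function(truth, stem) {
  jsonlite::write_json(
    list(cells = gtCells(truth), foci = gtFoci(truth),
         micronuclei = gtMicronuclei(truth)),
    paste0(stem, ".json"), digits = NA, pretty = TRUE)
  utils::write.csv(gtCells(truth), paste0(stem, "_cells.csv"),
                   row.names = FALSE)
  invisible(stem)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(stem) {
  x <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  empty <- function(df, cols) {
    if (is.data.frame(df) && nrow(df)) df
    else as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  new("GroundTruth",
      cells = empty(x$cells, c("cell_id", "y", "x", "radius", "fucci_class",
                               "n_foci", "n_micronuclei", "apoptotic",
                               "red_amp", "green_amp", "n_pixels")),
      foci = empty(x$foci, c("cell_id", "y", "x", "radius", "z")),
      micronuclei = empty(x$micronuclei, c("cell_id", "y", "x", "radius")))
}

#' Write / read a log2 abundance matrix as TSV
#'
#' Rows are proteins, columns are samples (header row = sample ids, first
#' column = protein id); missing values are encoded as empty cells. The
#' condition design is written as a second two-column TSV.
#'
#' @param se a \code{SummarizedExperiment} with a log2 assay and
#'   \code{colData(se)$condition}.
#' @param path output TSV path; the design goes to \code{<path>.design.tsv}.
#' @export
writeAbundance <- function(se, path) {
  mat <- .assayLog2(se)
  df <- data.frame(protein_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  design <- data.frame(sample = colnames(mat),
                       condition = SummarizedExperiment::colData(se)$condition)
  utils::write.table(design, paste0(path, ".design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAbundance
#' @param designPath design TSV; defaults to \code{<path>.design.tsv}.
#' @export
readAbundance <- function(path, designPath = paste0(path, ".design.tsv")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          na.strings = "")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  design <- utils::read.table(designPath, sep = "\t", header = TRUE)
  stopifnot(identical(colnames(mat), as.character(design$sample)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = mat),
    colData = S4Vectors::DataFrame(condition = design$condition,
                                   row.names = design$sample))
}

#' Read a pipeline run configuration (YAML or JSON)
#'
#' One file per run covering segmentation, focus, micronucleus, mixture-fit
#' and imputation parameters; recognized top-level keys \code{seg},
#' \code{foci}, \code{micronuclei}, \code{fucci}, \code{imputation} are
#' mapped onto the corresponding parameter constructors (defaults fill in
#' anything unspecified; unknown keys are an error).
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return list with elements \code{seg}, \code{foci}, \code{micronuclei},
#'   \code{fucci} (list with \code{seed}), \code{imputation} (list with
#'   \code{width}, \code{downshift}, \code{seed}).
#' @export
readPipelineConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seg", "foci", "micronuclei", "fucci", "imputation")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  call1 <- function(fun, args) do.call(fun, as.list(args))
  list(
    seg = call1(segParams, raw$seg),
    foci = call1(fociParams, raw$foci),
    micronuclei = call1(micronucleusParams, raw$micronuclei),
    fucci = utils::modifyList(list(seed = 1L), as.list(raw$fucci)),
    imputation = utils::modifyList(list(width = 1.3, downshift = 1.8, seed = 1L),
                                   as.list(raw$imputation)))
}
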