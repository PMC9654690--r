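# Fucci2a cell-cycle classification: per-cell red/green intensities from
# segmented nuclei, three-component Gaussian mixture in log-feature space,
# maximum-posterior class assignment, and cell-cycle distribution summaries.

#' @importFrom mclust Mclust mclustBIC
NULL

#' Per-cell red/green intensity extraction
#'
#' One record per non-border label: mean red and green intensity over the
#' label's pixels on the supplied (background-corrected) channels, plus the
#' label area. Border-touching labels are excluded because partial cells bias
#' intensity statistics.
#'
#' @param stack an [ImageStack-class] with \code{red} and \code{green} roles;
#'   channels should already be background-corrected. For z-stacks the maximum
#'   intensity projection of each channel is used.
#' @param nuclei a [LabelMap-class] aligned to the stack.
#' @return data.frame with columns \code{cell_id, red_mean, green_mean,
#'   area_px}; empty when the label map holds no usable object.
#' @export
extractIntensities <- function(stack, nuclei) {
  lab <- labelMatrix(nuclei)
  red <- mip(stack, "red")
  green <- mip(stack, "green")
  if (!all(dim(lab) == dim(red)))
    stop("label map is not aligned to the image stack")
  n <- nObjects(nuclei)
  keep <- setdiff(seq_len(n), borderLabels(nuclei))
  if (!length(keep))
    return(data.frame(cell_id = integer(0), red_mean = numeric(0),
                      green_mean = numeric(0), area_px = integer(0)))
  idx <- lab > 0L
  labv <- lab[idx]
  area <- tabulate(labv, nbins = n)
  rsum <- as.vector(rowsum(red[idx], labv, reorder = TRUE))
  gsum <- as.vector(rowsum(green[idx], labv, reorder = TRUE))
  present <- sort(unique(labv))
  full <- numeric(n)
  rmean <- gmean <- numeric(n)
  rmean[present] <- rsum / area[present]
  gmean[present] <- gsum / area[present]
  data.frame(cell_id = keep, red_mean = rmean[keep], green_mean = gmean[keep],
             area_px = area[keep])
}

.fucciFeatures <- function(cells) {
  cbind(red = log10(1 + cells$red_mean), green = log10(1 + cells$green_mean))
}

#' Fit the three-component Fucci mixture
#'
#' Fits a full-covariance three-component Gaussian mixture to
#' \code{log10(1 + intensity)} (red, green) features by expectation-
#' maximization (model-based hierarchical initialization, deterministic for a
#' given data set). Components are mapped to biological classes by the ratio
#' rule: highest red-to-green mean ratio = \code{red}, lowest = \code{green},
#' the remaining component = \code{both}. The mapping depends only on the
#' component means, so it is invariant to component relabelling and to global
#' intensity scaling.
#'
#' Cells with zero intensity in both channels are dropped before fitting (they
#' carry no class information); [classifyCells()] reports them as
#' \code{unclassified}.
#'
#' @param cells data.frame as returned by [extractIntensities()].
#' @param seed integer seed (the fit is deterministic; the seed is part of the
#'   interface so pipelines can thread one seed through every stage).
#' @return a [FucciModel-class].
#' @examples
#' sim <- generateFucciIntensities(300, seed = 4)
#' model <- fitFucciModel(sim$cells)
#' model
#' @export
fitFucciModel <- function(cells, seed = 1L) {
  usable <- cells[cells$red_mean > 0 | cells$green_mean > 0, , drop = FALSE]
  if (nrow(usable) < 9L)
    stop("insufficient data: need at least 9 cells with nonzero intensity, got ",
         nrow(usable))
  feats <- .fucciFeatures(usable)
  set.seed(seed)
  fit <- Mclust(feats, G = 3, modelNames = "VVV", verbose = FALSE)
  if (is.null(fit))
    stop("mixture fit failed on ", nrow(usable), " cells")
  means <- t(fit$parameters$mean)             # 3 x 2
  colnames(means) <- c("red", "green")
  covs <- fit$parameters$variance$sigma       # 2 x 2 x 3
  weights <- fit$parameters$pro
  ratio <- means[, "red"] - means[, "green"]  # log-scale red/green ratio
  classes <- character(3)
  classes[which.max(ratio)] <- "red"
  classes[which.min(ratio)] <- "green"
  classes[classes == ""] <- "both"
  new("FucciModel", means = means, covariances = covs,
      weights = weights / sum(weights), classOfComponent = classes,
      transform = "log10(1+x)")
}

# per-component multivariate normal density on the feature matrix (n x 3)
.componentDensity <- function(model, feats) {
  dens <- vapply(seq_len(3), function(k) {
    S <- model@covariances[, , k]
    mu <- model@means[k, ]
    ch <- chol(S)
    z <- forwardsolve(t(ch), t(feats) - mu)
    exp(-0.5 * colSums(z^2)) / (2 * pi * prod(diag(ch)))
  }, numeric(nrow(feats)))
  matrix(dens, nrow = nrow(feats), ncol = 3L)
}

#' Classify cells under a fitted Fucci model
#'
#' Assigns every cell the class of its maximum-posterior component; posterior
#' ties are broken toward the lowest component index. Cells with zero
#' intensity in both channels are assigned \code{unclassified} (reported via a
#' message) and excluded from downstream distributions.
#'
#' @param model a [FucciModel-class].
#' @param cells data.frame as returned by [extractIntensities()].
#' @param posteriors return the posterior matrix as an attribute
#'   (\code{attr(x, "posterior")}).
#' @return factor of length \code{nrow(cells)} with levels
#'   \code{red, green, both, unclassified}, named by \code{cell_id}.
#' @export
classifyCells <- function(model, cells, posteriors = FALSE) {
  lv <- c("red", "green", "both", "unclassified")
  out <- factor(rep("unclassified", nrow(cells)), levels = lv)
  usable <- which(cells$red_mean > 0 | cells$green_mean > 0)
  if (length(usable) < nrow(cells))
    message(nrow(cells) - length(usable),
            " cell(s) with zero intensity in both channels left unclassified")
  post <- NULL
  if (length(usable)) {
    feats <- .fucciFeatures(cells[usable, , drop = FALSE])
    dens <- .componentDensity(model, feats)
    wdens <- sweep(dens, 2, model@weights, "*")
    post <- wdens / pmax(rowSums(wdens), .Machine$double.xmin)
    comp <- max.col(post, ties.method = "first")
    out[usable] <- model@classOfComponent[comp]
  }
  names(out) <- cells$cell_id
  if (posteriors) attr(out, "posterior") <- post
  out
}

#' Summarize a cell-cycle distribution
#'
#' Fractions of red / green / both cells among classified cells for one
#' condition and timepoint; fractions sum to 1.
#'
#' @param assignments factor from [classifyCells()] (or character vector with
#'   values in red/green/both/unclassified).
#' @param condition treatment label.
#' @param timepointH hours after treatment.
#' @return one-row data.frame with columns \code{condition, timepoint_h,
#'   fraction_red, fraction_green, fraction_both, n_cells, n_unclassified}.
#' @examples
#' summarizeDistribution(factor(rep(c("red", "green"), c(3, 7)),
#'   levels = c("red", "green", "both", "unclassified")), "HT", 48)
#' @export
summarizeDistribution <- function(assignments, condition, timepointH) {
  if (!length(assignments)) stop("empty assignment vector")
  a <- as.character(assignments)
  cls <- a[a != "unclassified"]
  if (!length(cls)) stop("no classified cells to summarize")
  n <- length(cls)
  data.frame(condition = condition, timepoint_h = timepointH,
             fraction_red = sum(cls == "red") / n,
             fraction_green = sum(cls == "green") / n,
             fraction_both = sum(cls == "both") / n,
             n_cells = n, n_unclassified = sum(a == "unclassified"))
}
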