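# SILAC proteomics post-processing: downshifted-normal imputation of missing
# values, log2 fold-change calling with the +/-0.5 rule, one-way ANOVA across
# conditions, and Benjamini-Hochberg FDR correction.

.assayLog2 <- function(se) {
  stopifnot(methods::is(se, "SummarizedExperiment"))
  if ("log2" %in% SummarizedExperiment::assayNames(se))
    SummarizedExperiment::assay(se, "log2")
  else SummarizedExperiment::assay(se, 1L)
}

#' Impute missing abundances from a downshifted normal distribution
#'
#' Per sample column, missing entries are drawn from
#' \code{Normal(mean = mu - downshift * sigma, sd = width * sigma)}, where
#' \code{mu} and \code{sigma} are the mean and standard deviation of the
#' column's observed values — the Perseus-style left-censored imputation with
#' default width 1.3 and downshift 1.8. Observed entries are untouched and the
#' result is deterministic for a fixed seed.
#'
#' @param se a \code{SummarizedExperiment} with a log2 assay containing
#'   \code{NA} at missing entries (e.g. from [generateAbundance()] or
#'   [readAbundance()]).
#' @param width imputation width in column-sd units.
#' @param downshift downshift in column-sd units.
#' @param seed integer seed.
#' @return the \code{SummarizedExperiment} with a fully observed
#'   \code{"imputed"} assay added.
#' @examples
#' se <- generateAbundance(synthAbundanceConfig(nProteins = 50, seed = 3))
#' se <- imputeMissing(se, seed = 9)
#' anyNA(SummarizedExperiment::assay(se, "imputed"))
#' @export
imputeMissing <- function(se, width = 1.3, downshift = 1.8, seed = 1L) {
  stopifnot(width > 0, downshift >= 0)
  mat <- .assayLog2(se)
  out <- mat
  set.seed(.substreamSeed(seed, 31L))
  for (j in seq_len(ncol(mat))) {
    obs <- mat[, j][!is.na(mat[, j])]
    if (length(obs) < 2L)
      stop("column '", colnames(mat)[j],
           "' has fewer than 2 observed values; cannot estimate its distribution")
    nm <- sum(is.na(mat[, j]))
    if (nm == 0L) next
    mu <- mean(obs); s <- sd(obs)
    out[is.na(mat[, j]), j] <- rnorm(nm, mu - downshift * s, width * s)
  }
  SummarizedExperiment::assay(se, "imputed") <- out
  se
}

#' Call differentially regulated proteins
#'
#' Per protein: \code{log2fc = mean(condition A) - mean(condition B)} on the
#' imputed assay (set \code{useImputed = FALSE} for observed-only means, a
#' sensitivity analysis); direction from the +/-0.5 log2 fold-change rule
#' (\code{up} iff \code{log2fc > 0.5}, \code{down} iff \code{log2fc < -0.5},
#' otherwise \code{unchanged}); a one-way ANOVA p-value across all conditions
#' in the design; Benjamini-Hochberg adjusted FDR; and a convenience
#' significance flag \code{|log2fc| > 0.5 AND fdr < alpha}. The fold-change
#' filter and the ANOVA are reported separately so either can be used on its
#' own.
#'
#' @param se a \code{SummarizedExperiment} with condition design in
#'   \code{colData(se)$condition}; run [imputeMissing()] first (or pass
#'   \code{useImputed = FALSE}).
#' @param contrast character pair \code{c(A, B)} of condition names.
#' @param alpha FDR level for the significance flag (default 0.05).
#' @param useImputed use the imputed assay (default) or observed-only values.
#' @return data.frame with columns \code{protein_id, log2fc, direction,
#'   p_value, fdr, significant}.
#' @export
callRegulated <- function(se, contrast, alpha = 0.05, useImputed = TRUE) {
  cond <- SummarizedExperiment::colData(se)$condition
  if (is.null(cond)) stop("colData(se)$condition is missing")
  if (length(contrast) != 2L || !all(contrast %in% cond))
    stop("contrast must name two conditions present in the design")
  mat <- if (useImputed) {
    if (!"imputed" %in% SummarizedExperiment::assayNames(se))
      stop("no 'imputed' assay: run imputeMissing() first")
    SummarizedExperiment::assay(se, "imputed")
  } else .assayLog2(se)
  nrep <- table(cond)
  if (any(nrep[unique(cond)] < 2L))
    stop("need at least 2 samples per condition")

  inA <- cond == contrast[1]; inB <- cond == contrast[2]
  log2fc <- rowMeans(mat[, inA, drop = FALSE], na.rm = !useImputed) -
            rowMeans(mat[, inB, drop = FALSE], na.rm = !useImputed)

  f <- factor(cond)
  pv <- apply(mat, 1L, function(x) {
    ok <- !is.na(x)
    if (length(unique(f[ok])) < 2L || sum(ok) < 3L) return(NA_real_)
    stats::oneway.test(x[ok] ~ f[ok], var.equal = TRUE)$p.value
  })
  fdr <- p.adjust(pv, method = "BH")
  direction <- ifelse(log2fc > 0.5, "up",
                      ifelse(log2fc < -0.5, "down", "unchanged"))
  data.frame(protein_id = rownames(mat), log2fc = log2fc,
             direction = direction, p_value = pv, fdr = fdr,
             significant = !is.na(fdr) & abs(log2fc) > 0.5 & fdr < alpha,
             row.names = NULL)
}
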