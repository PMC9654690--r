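# Synthetic SILAC-style protein abundance matrices with known effects and
# missing-not-at-random dropout.

#' Configuration of a synthetic abundance matrix
#'
#' Emulates a log2-transformed quantitative proteomics matrix: per-protein
#' baseline abundances are normal on the log2 scale (i.e. log-normal raw
#' abundances), condition effects are injected into a configurable fraction of
#' proteins, and dropout is missing-not-at-random — the probability that an
#' entry is missing is a logistic function of its abundance, mirroring the
#' left-censoring that justifies downshifted-normal imputation.
#'
#' @param nProteins positive integer.
#' @param nSamplesPerCondition positive integer (replicates).
#' @param conditions character vector of condition names; the first is the
#'   reference and never receives effects.
#' @param effectLog2fc named list (one entry per non-reference condition) of
#'   lists \code{list(prop=, mean=, sd=)}: fraction of proteins affected and
#'   the normal distribution of their log2 effects. Missing conditions get no
#'   effect.
#' @param missingRate overall missingness probability in \[0, 1).
#' @param mnarStrength non-negative logistic slope of dropout vs abundance;
#'   0 gives missing-completely-at-random.
#' @param replicateSd within-condition replicate noise sd (log2 units).
#' @param baselineMean,baselineSd distribution of per-protein baseline log2
#'   abundance.
#' @param seed integer seed.
#' @return classed list for [generateAbundance()].
#' @export
synthAbundanceConfig <- function(nProteins = 4000L,
                                 nSamplesPerCondition = 3L,
                                 conditions = c("control", "HT", "HT_HSP90i"),
                                 effectLog2fc = list(),
                                 missingRate = 0.1,
                                 mnarStrength = 1,
                                 replicateSd = 0.3,
                                 baselineMean = 25,
                                 baselineSd = 2,
                                 seed = 1L) {
  stopifnot(nProteins >= 1, nSamplesPerCondition >= 1,
            length(conditions) >= 1, !anyDuplicated(conditions),
            missingRate >= 0, missingRate < 1, mnarStrength >= 0,
            replicateSd >= 0, baselineSd > 0)
  if (length(effectLog2fc)) {
    stopifnot(!is.null(names(effectLog2fc)),
              all(names(effectLog2fc) %in% conditions[-1]))
  }
  cfg <- list(nProteins = as.integer(nProteins),
              nSamplesPerCondition = as.integer(nSamplesPerCondition),
              conditions = conditions, effectLog2fc = effectLog2fc,
              missingRate = missingRate, mnarStrength = mnarStrength,
              replicateSd = replicateSd, baselineMean = baselineMean,
              baselineSd = baselineSd, seed = as.integer(seed))
  class(cfg) <- "SynthAbundanceConfig"
  cfg
}

#' Generate a synthetic log2 abundance matrix
#'
#' Returns a \linkS4class{SummarizedExperiment} whose \code{"log2"} assay
#' holds log2 abundances with \code{NA} at missing entries. True per-protein
#' effects are recorded in \code{rowData} (one \code{true_log2fc_<condition>}
#' column per non-reference condition) for recovery tests; the sample
#' condition design sits in \code{colData(se)$condition}.
#'
#' @param config a [synthAbundanceConfig()] object.
#' @return a \code{SummarizedExperiment}.
#' @examples
#' se <- generateAbundance(synthAbundanceConfig(nProteins = 100, seed = 2))
#' SummarizedExperiment::assay(se, "log2")[1:3, ]
#' @export
generateAbundance <- function(config) {
  stopifnot(inherits(config, "SynthAbundanceConfig"))
  cfg <- config
  set.seed(.substreamSeed(cfg$seed, 21L))
  p <- cfg$nProteins
  base <- rnorm(p, cfg$baselineMean, cfg$baselineSd)

  eff <- matrix(0, p, length(cfg$conditions),
                dimnames = list(NULL, cfg$conditions))
  for (cond in names(cfg$effectLog2fc)) {
    e <- cfg$effectLog2fc[[cond]]
    hit <- runif(p) < e$prop
    eff[hit, cond] <- rnorm(sum(hit), e$mean, e$sd)
  }

  nrep <- cfg$nSamplesPerCondition
  samples <- paste(rep(cfg$conditions, each = nrep),
                   rep(seq_len(nrep), length(cfg$conditions)), sep = "_")
  condOf <- rep(cfg$conditions, each = nrep)
  set.seed(.substreamSeed(cfg$seed, 22L))
  mat <- matrix(0, p, length(samples), dimnames = list(
    sprintf("P%05d", seq_len(p)), samples))
  for (j in seq_along(samples))
    mat[, j] <- base + eff[, condOf[j]] + rnorm(p, 0, cfg$replicateSd)

  set.seed(.substreamSeed(cfg$seed, 23L))
  miss <- matrix(FALSE, p, length(samples))
  if (cfg$missingRate > 0) {
    a <- as.vector(mat)
    if (cfg$mnarStrength == 0) {
      pm <- rep(cfg$missingRate, length(a))
    } else {
      # calibrate the logistic midpoint so the overall rate matches
      f <- function(q) mean(plogis(cfg$mnarStrength * (q - a))) - cfg$missingRate
      q <- uniroot(f, range(a) + c(-50, 50))$root
      pm <- plogis(cfg$mnarStrength * (q - a))
    }
    miss <- matrix(runif(length(a)) < pm, p, length(samples))
  }
  obs <- mat
  obs[miss] <- NA_real_

  rd <- S4Vectors::DataFrame(row.names = rownames(mat))
  for (cond in cfg$conditions[-1])
    rd[[paste0("true_log2fc_", cond)]] <- eff[, cond]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = obs),
    rowData = rd,
    colData = S4Vectors::DataFrame(condition = condOf, row.names = samples),
    metadata = list(config = cfg, complete = mat))
}
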