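# Clonogenic arithmetic and the SILAC post-processing chain.

test_that("surviving fractions reproduce closed-form values", {
  expect_equal(survivingFraction(colonyCount("t", 500, 50),
                                 colonyCount("c", 500, 100)), 0.5)
  same <- colonyCount("x", 400, 80)
  expect_equal(survivingFraction(same, same), 1.0)
  expect_equal(survivingFraction(colonyCount("t", 1000, 10),
                                 colonyCount("c", 500, 200)), 0.025)
  expect_error(survivingFraction(colonyCount("t", 100, 10),
                                 colonyCount("c", 100, 0)), "zero")
  expect_error(colonyCount("bad", 10, 11), "exceeds")
})

test_that("enhancement ratio is the surviving-fraction fold change", {
  expect_equal(enhancementRatio(0.2, 0.05), 4.0)
  expect_equal(enhancementRatio(0.4, 0.1), 4.0)
  expect_equal(enhancementRatio(0.33, 0.33), 1.0)
  expect_error(enhancementRatio(0.2, 0), "detection limit")
  # no-enhancement identity across magnitudes
  for (a in c(1e-4, 0.01, 0.5, 1)) expect_equal(enhancementRatio(a, a), 1.0)
})

test_that("median survival folds use the even-length median convention", {
  expect_equal(medianSurvivalFold(c(10, 20, 30), c(5, 10, 15)), 2.0)
  expect_equal(medianSurvivalFold(c(3, 9, 27), c(3, 9, 27)), 1.0)
  expect_equal(medianSurvivalFold(c(4, 8), c(2, 4)), 2.0)
  expect_error(medianSurvivalFold(c(1, 2), c(0, 0)), "zero")
})

test_that("imputation draws from the downshifted column distribution", {
  # column whose observed mean and sd are exactly 20 and 2
  nObs <- 30; nMiss <- 1e5
  set.seed(4)
  obs <- rnorm(nObs)
  obs <- (obs - mean(obs)) / sd(obs) * 2 + 20
  col <- c(obs, rep(NA_real_, nMiss))
  mat <- cbind(sample1 = col)
  rownames(mat) <- sprintf("P%06d", seq_along(col))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = mat),
    colData = S4Vectors::DataFrame(condition = "c", row.names = "sample1"))
  out <- imputeMissing(se, width = 1.3, downshift = 1.8, seed = 10)
  imp <- SummarizedExperiment::assay(out, "imputed")[is.na(col), 1]
  expect_lt(abs(mean(imp) - (20 - 1.8 * 2)), 0.05)
  expect_lt(abs(sd(imp) - 1.3 * 2), 0.05)
})

test_that("imputation leaves observed entries bit-identical and is seeded", {
  se <- generateAbundance(synthAbundanceConfig(nProteins = 300,
                                               missingRate = 0.2, seed = 3))
  obs <- SummarizedExperiment::assay(se, "log2")
  a <- SummarizedExperiment::assay(imputeMissing(se, seed = 5), "imputed")
  b <- SummarizedExperiment::assay(imputeMissing(se, seed = 5), "imputed")
  expect_identical(a, b)
  expect_identical(a[!is.na(obs)], obs[!is.na(obs)])

  # fully observed matrices come back unchanged
  se0 <- generateAbundance(synthAbundanceConfig(nProteins = 50,
                                                missingRate = 0, seed = 2))
  out0 <- imputeMissing(se0, seed = 1)
  expect_identical(SummarizedExperiment::assay(out0, "imputed"),
                   SummarizedExperiment::assay(se0, "log2"))

  # a column with fewer than two observed values cannot be imputed
  bad <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = cbind(s1 = c(1, NA, NA), s2 = c(1, 2, 3))),
    colData = S4Vectors::DataFrame(condition = c("a", "b"),
                                   row.names = c("s1", "s2")))
  expect_error(imputeMissing(bad), "fewer than 2 observed")
})

test_that("the +/-0.5 rule assigns directions exactly", {
  # three proteins with exact mean differences 0.6, -0.6, 0.3
  mk <- function(diffs) {
    mat <- rbind(
      t(vapply(diffs, function(d) c(d, d, d, 0, 0, 0), numeric(6))))
    rownames(mat) <- paste0("P", seq_along(diffs))
    colnames(mat) <- paste0("s", 1:6)
    SummarizedExperiment::SummarizedExperiment(
      assays = list(log2 = mat, imputed = mat),
      colData = S4Vectors::DataFrame(condition = rep(c("A", "B"), each = 3),
                                     row.names = colnames(mat)))
  }
  res <- callRegulated(mk(c(0.6, -0.6, 0.3)), c("A", "B"))
  expect_equal(res$direction, c("up", "down", "unchanged"))
  expect_equal(res$log2fc, c(0.6, -0.6, 0.3))
  expect_error(callRegulated(mk(0.5), c("A", "missing")), "conditions present")
})

test_that("BH adjustment agrees with a brute-force step-up on all subsets", {
  bruteBH <- function(p) {
    n <- length(p); o <- order(p)
    adj <- vapply(seq_len(n), function(i) {
      min(1, min(p[o][i:n] * n / (i:n)))  # min over j >= i of (n/j) p_(j)
    }, numeric(1))
    adj[order(o)]
  }
  base <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  for (mask in 1:255) {
    p <- base[bitwAnd(mask, 2^(0:7)) > 0]
    expect_equal(p.adjust(p, "BH"), bruteBH(p))
  }
  # printed-style example: 3 of 4 rejected at FDR 0.05
  expect_equal(sum(p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH") < 0.05), 3)
})

test_that("BH adjusted values are monotone and rejections nest across levels", {
  set.seed(8)
  p <- runif(100)^2
  adj <- p.adjust(p, "BH")
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  for (a2 in c(0.01, 0.02)) {
    expect_true(all(which(adj < a2) %in% which(adj < 0.05)))
  }
})

test_that("null simulations control the false-discovery rate", {
  se <- generateAbundance(synthAbundanceConfig(
    nProteins = 1000, nSamplesPerCondition = 3,
    conditions = c("A", "B", "C"), missingRate = 0, seed = 14))
  se <- imputeMissing(se, seed = 1)
  res <- callRegulated(se, c("B", "A"))
  expect_lte(mean(res$fdr < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("injected effects are recovered by the fold-change rule", {
  se <- generateAbundance(synthAbundanceConfig(
    nProteins = 4000, nSamplesPerCondition = 3,
    conditions = c("control", "HT", "HT_HSP90i"),
    effectLog2fc = list(HT_HSP90i = list(prop = 0.1, mean = 1, sd = 0)),
    missingRate = 0, replicateSd = 0.3, seed = 24))
  se <- imputeMissing(se, seed = 2)
  res <- callRegulated(se, c("HT_HSP90i", "control"))
  truefc <- SummarizedExperiment::rowData(se)$true_log2fc_HT_HSP90i
  hit <- truefc != 0
  # sensitivity of the +/-0.5 fold-change call on true effects of 1.0
  expect_gte(mean(res$direction[hit] == "up"), 0.9)
  # false-discovery proportion among combined significant calls
  calls <- which(res$significant)
  expect_gt(length(calls), 0)
  expect_lte(mean(!hit[calls]), 0.1)
})
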