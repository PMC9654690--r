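# Fucci classification: intensity extraction, mixture fitting, class
# assignment and distribution summaries.

test_that("per-cell means reproduce uniform channel values exactly", {
  lab <- matrix(0L, 20, 20); lab[5:10, 5:10] <- 1L; lab[14:18, 14:18] <- 2L
  lm <- LabelMap(lab)
  stk <- flatStack(20, 20, list(red = 42, green = 11))
  ci <- extractIntensities(stk, lm)
  expect_equal(ci$red_mean, c(42, 42))
  expect_equal(ci$green_mean, c(11, 11))
  expect_equal(ci$area_px, c(36L, 25L))

  zero <- extractIntensities(flatStack(20, 20, list(red = 0, green = 0)), lm)
  expect_true(all(zero$red_mean == 0) && all(zero$green_mean == 0))
  emptyMap <- LabelMap(matrix(0L, 20, 20))
  expect_equal(nrow(extractIntensities(stk, emptyMap)), 0)
})

test_that("extracted red means preserve the painted amplitude ranking", {
  cfg <- synthImageConfig(fieldSize = c(512, 512), nCells = 25,
                          fucciClassProbs = c(1, 0, 0),
                          meanFociPerCell = 0, micronucleusProb = 0, seed = 61)
  fld <- generateField(cfg)
  red <- correctChannel(fld$image, "red")
  green <- correctChannel(fld$image, "green")
  seg <- segmentNuclei(mergeChannels(red, green), segParams())
  ci <- extractIntensities(ImageStack(list(red = red, green = green)), seg)
  al <- alignToTruth(seg, fld$truth, ci$red_mean, ci$cell_id)
  expect_gte(al$matched, 20)
  # mask-edge pixels perturb means by a fraction of a count, so near-tied
  # amplitudes may swap; demand near-perfect rank agreement
  expect_gt(cor(al$det, al$truth$red_amp, method = "spearman"), 0.99)
})

test_that("the mixture recovers well-separated classes and is deterministic", {
  sim <- generateFucciIntensities(600, probs = c(0.4, 0.35, 0.25), seed = 71)
  m1 <- fitFucciModel(sim$cells, seed = 1)
  m2 <- fitFucciModel(sim$cells, seed = 1)
  expect_identical(m1@means, m2@means)
  cls <- classifyCells(m1, sim$cells)
  expect_gte(mean(as.character(cls) == sim$classes), 0.99)

  # sufficiency: duplicating every point leaves the component means in place
  dup <- sim$cells[rep(seq_len(nrow(sim$cells)), 2), ]
  dup$cell_id <- seq_len(nrow(dup))
  m3 <- fitFucciModel(dup, seed = 1)
  reorder <- match(m1@classOfComponent, m3@classOfComponent)
  expect_equal(m3@means[reorder, ], m1@means, tolerance = 1e-3,
               ignore_attr = TRUE)

  expect_error(fitFucciModel(sim$cells[1:5, ]), "insufficient data")
})

test_that("class mapping depends only on component means", {
  sim <- generateFucciIntensities(300, seed = 81)
  m <- fitFucciModel(sim$cells)
  perm <- c(3, 1, 2)
  mp <- new("FucciModel", means = m@means[perm, ],
            covariances = m@covariances[, , perm],
            weights = m@weights[perm],
            classOfComponent = m@classOfComponent[perm],
            transform = m@transform)
  expect_identical(as.character(classifyCells(m, sim$cells)),
                   as.character(classifyCells(mp, sim$cells)))
})

test_that("cells are assigned their maximum-posterior class with tie-breaking", {
  sim <- generateFucciIntensities(300, seed = 91)
  m <- fitFucciModel(sim$cells)
  # a cell sitting exactly at a component mean takes that component's class
  for (k in 1:3) {
    at <- data.frame(cell_id = 1L, red_mean = 10^m@means[k, 1] - 1,
                     green_mean = 10^m@means[k, 2] - 1, area_px = 300L)
    expect_equal(as.character(classifyCells(m, at)), m@classOfComponent[k])
  }
  # posteriors normalize
  cls <- classifyCells(m, sim$cells, posteriors = TRUE)
  expect_true(all(abs(rowSums(attr(cls, "posterior")) - 1) < 1e-9))

  # symmetric two-identical-component model: ties go to the lowest index
  covs <- array(rep(diag(2) * 0.01, 3), dim = c(2, 2, 3))
  tie <- new("FucciModel",
             means = rbind(c(3, 1), c(3, 1), c(2, 2)),
             covariances = covs, weights = rep(1, 3) / 3,
             classOfComponent = c("red", "green", "both"),
             transform = "log10(1+x)")
  pt <- data.frame(cell_id = 1L, red_mean = 10^3 - 1, green_mean = 10^1 - 1,
                   area_px = 10L)
  expect_equal(as.character(classifyCells(tie, pt)), "red")
})

test_that("zero-intensity cells are reported unclassified", {
  sim <- generateFucciIntensities(100, seed = 95)
  cells <- rbind(sim$cells,
                 data.frame(cell_id = 101L, red_mean = 0, green_mean = 0,
                            area_px = 10L))
  m <- fitFucciModel(cells)
  expect_message(cls <- classifyCells(m, cells), "unclassified")
  expect_equal(as.character(cls[101]), "unclassified")
  s <- summarizeDistribution(cls, "ctrl", 48)
  expect_equal(s$n_unclassified, 1)
  expect_equal(s$n_cells, 100)
})

test_that("distribution summaries are exact fractions that sum to one", {
  a <- factor(rep(c("red", "green", "both"), c(30, 50, 20)),
              levels = c("red", "green", "both", "unclassified"))
  s <- summarizeDistribution(a, "HT", 48)
  expect_equal(c(s$fraction_red, s$fraction_green, s$fraction_both),
               c(0.3, 0.5, 0.2))
  allRed <- summarizeDistribution(rep("red", 5), "x", 0)
  expect_equal(allRed$fraction_red, 1)
  expect_error(summarizeDistribution(character(0), "x", 0), "empty")
})

test_that("mixture weights track generator probabilities at scale", {
  sim <- generateFucciIntensities(2000, probs = c(0.5, 0.3, 0.2), seed = 21)
  m <- fitFucciModel(sim$cells)
  w <- stats::setNames(m@weights, m@classOfComponent)
  expect_lt(max(abs(w[c("red", "green", "both")] - c(0.5, 0.3, 0.2))), 0.03)
  cls <- classifyCells(m, sim$cells)
  s <- summarizeDistribution(cls, "sim", 0)
  fr <- c(s$fraction_red, s$fraction_green, s$fraction_both)
  se3 <- 3 * sqrt(c(0.5, 0.3, 0.2) * (1 - c(0.5, 0.3, 0.2)) / 2000)
  expect_true(all(abs(fr - c(0.5, 0.3, 0.2)) < se3))
})
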