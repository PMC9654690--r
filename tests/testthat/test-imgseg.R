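# Segmentation chain: rolling-ball correction, median denoising, channel
# merging, adaptive threshold + watershed + small-mask removal, and the
# maximum intensity projection.

test_that("rolling ball removes flat background and is offset-invariant", {
  img <- matrix(100, 64, 64)
  expect_true(all(rollingBall(img, 10) == 0))
  set.seed(1)
  img2 <- matrix(runif(64 * 64, 0, 500), 64, 64)
  a <- rollingBall(img2, 8)
  b <- rollingBall(img2 + 250, 8)
  expect_lt(max(abs(a - b)), 1e-6)
  expect_true(all(a >= 0))
  expect_true(all(a <= img2 + 1e-9))
  expect_error(rollingBall(img2, -1), "positive")
})

test_that("rolling ball residual on a smooth gradient matches the opening oracle", {
  # brute-force grayscale opening (erosion then dilation over a disc)
  discOffsets <- function(r) {
    d <- expand.grid(dy = -r:r, dx = -r:r)
    d[d$dy^2 + d$dx^2 <= r^2 + r / 2, ]
  }
  bruteOpen <- function(img, r) {
    off <- discOffsets(r)
    H <- nrow(img); W <- ncol(img)
    er <- matrix(Inf, H, W)
    for (k in seq_len(nrow(off))) {
      ys <- pmin(pmax(seq_len(H) + off$dy[k], 1), H)
      xs <- pmin(pmax(seq_len(W) + off$dx[k], 1), W)
      er <- pmin(er, img[ys, xs])
    }
    di <- matrix(-Inf, H, W)
    for (k in seq_len(nrow(off))) {
      ys <- pmin(pmax(seq_len(H) + off$dy[k], 1), H)
      xs <- pmin(pmax(seq_len(W) + off$dx[k], 1), W)
      di <- pmax(di, er[ys, xs])
    }
    di
  }
  g <- 200
  cfg <- synthImageConfig(fieldSize = c(128, 128), nCells = 0,
                          backgroundLevel = 100,
                          backgroundGradientAmplitude = g, seed = 1)
  img <- channelPlane(generateField(cfg)$image, "dna")
  r <- 8   # gradient length scale (~128 px) is ~10x larger than the radius
  resid <- rollingBall(img, r)
  oracle <- pmax(img - bruteOpen(img, r), 0)
  # residual small relative to the gradient amplitude, and near the oracle
  expect_lt(max(resid[r:(128 - r), r:(128 - r)]), 0.05 * g)
  expect_lt(max(abs(resid - oracle)[r:(128 - r), r:(128 - r)]), 0.05 * g)
})

test_that("median filter removes impulses and matches the neighborhood median", {
  img <- matrix(10, 32, 32); img[16, 16] <- 1000
  out <- medianDenoise(img, 3)
  expect_equal(out[16, 16], 10)
  expect_equal(medianDenoise(matrix(7, 16, 16), 5), matrix(7, 16, 16))
  expect_error(medianDenoise(img, 4), "odd")

  # checkerboard of period 1: exhaustive window-median oracle on the interior
  cb <- outer(1:20, 1:20, function(i, j) ifelse((i + j) %% 2 == 0, 0, 1))
  out <- medianDenoise(cb, 3)
  oracle <- cb
  for (i in 2:19) for (j in 2:19)
    oracle[i, j] <- median(cb[(i - 1):(i + 1), (j - 1):(j + 1)])
  expect_equal(out[2:19, 2:19], oracle[2:19, 2:19])
})

test_that("channel merging is the commutative pixelwise sum", {
  set.seed(2)
  A <- matrix(runif(100), 10, 10); B <- matrix(runif(100), 10, 10)
  expect_equal(mergeChannels(A, matrix(0, 10, 10)), A)
  expect_equal(mergeChannels(A, B), mergeChannels(B, A))
  expect_error(mergeChannels(A, matrix(0, 5, 5)), "shapes differ")
})

test_that("cells visible in only one reporter channel survive the merge", {
  cfg <- synthImageConfig(fieldSize = c(512, 512), nCells = 40,
                          fucciClassProbs = c(0.5, 0.5, 0),
                          meanFociPerCell = 0, micronucleusProb = 0, seed = 21)
  fld <- generateField(cfg)
  red <- correctChannel(fld$image, "red")
  green <- correctChannel(fld$image, "green")
  seg <- segmentNuclei(mergeChannels(red, green), segParams())
  m <- matchSegmentation(seg, fld$truth)
  expect_gte(m$recall, 0.95)   # both red-only and green-only cells found
  cls <- gtCells(fld$truth)$fucci_class
  expect_true(all(c("red", "green") %in% cls))
})

test_that("segmentation recovers isolated nuclei and splits touching pairs", {
  expect_equal(nObjects(segmentNuclei(matrix(0, 64, 64))), 0)

  cfg <- synthImageConfig(fieldSize = c(768, 768), nCells = 50,
                          meanFociPerCell = 0, micronucleusProb = 0, seed = 31)
  fld <- generateField(cfg)
  seg <- segmentField(fld)
  expect_equal(nObjects(seg), 50)
  m <- matchSegmentation(seg, fld$truth)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)

  cfgp <- synthImageConfig(fieldSize = c(256, 256), nCells = 0,
                           touchingPairs = 1, meanFociPerCell = 0,
                           micronucleusProb = 0, seed = 41)
  fp <- generateField(cfgp)
  expect_equal(nObjects(segmentField(fp)), 2)
})

test_that("no returned object is smaller than the small-mask cutoff", {
  p <- segParams()
  cfg <- synthImageConfig(fieldSize = c(512, 512), nCells = 30,
                          micronucleusProb = 0.5, meanFociPerCell = 0,
                          seed = 51)
  seg <- segmentField(generateField(cfg), p)
  lab <- labelMatrix(seg)
  areas <- tabulate(lab[lab > 0], nbins = nObjects(seg))
  expect_true(all(areas >= p$minObjectAreaPx))
  expect_equal(max(lab), nObjects(seg))   # compaction
})

test_that("recall degrades monotonically with noise", {
  rec <- vapply(c(0, 300, 1000, 2000, 3500), function(ns) {
    cfg <- synthImageConfig(fieldSize = c(512, 512), nCells = 50,
                            meanFociPerCell = 0, micronucleusProb = 0,
                            noiseSd = ns, seed = 77)
    fld <- generateField(cfg)
    matchSegmentation(segmentField(fld, denoise = ns > 0), fld$truth)$recall
  }, numeric(1))
  expect_true(all(diff(rec) <= 0.02 + 1e-12))
  expect_lt(rec[5], rec[1])   # degradation is real at the extreme level
})

test_that("maximum intensity projection dominates every plane", {
  px <- array(0, dim = c(1, 3, 8, 8))
  px[1, 2, , ] <- matrix(5, 8, 8)
  stk <- ImageStack(px, c("dna"))
  expect_equal(mip(stk, "dna"), matrix(5, 8, 8))
  expect_error(mip(stk, "damage"), "not present")

  set.seed(3)
  px2 <- array(runif(2 * 4 * 8 * 8), dim = c(2, 4, 8, 8))
  stk2 <- ImageStack(px2, c("dna", "damage"))
  proj <- mip(stk2, "damage")
  for (z in 1:4) expect_true(all(proj >= px2[2, z, , ]))
  oneplane <- ImageStack(px2[, 1, , , drop = FALSE], c("dna", "damage"))
  expect_equal(mip(oneplane, "dna"), px2[1, 1, , ])
})

test_that("border-touching objects are flagged and excluded from intensities", {
  lab <- matrix(0L, 16, 16)
  lab[1:4, 1:4] <- 1L      # touches the border
  lab[8:12, 8:12] <- 2L    # interior
  lm <- LabelMap(lab)
  expect_equal(borderLabels(lm), 1L)
  stk <- flatStack(16, 16, list(red = 7, green = 3))
  ci <- extractIntensities(stk, lm)
  expect_equal(ci$cell_id, 2L)
})
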