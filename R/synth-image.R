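# Synthetic fluorescence-field generator with full ground truth.
#
# Nuclei are deformed ellipses (bounded eccentricity, low-order harmonic
# boundary wobble); foci are Gaussian spots in the damage channel; micronuclei
# are small perinuclear discs in the DNA channel. A single integer seed feeds
# one child RNG stream per object class, so enlarging one stage never perturbs
# the draws of another.

.substreamSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * k) %% 2147483629)
}

.withStream <- function(seed, k, expr) {
  set.seed(.substreamSeed(seed, k))
  expr
}

#' Configuration of a synthetic microscopy field
#'
#' Defaults describe the imaging conditions the downstream assays assume:
#' 1024 x 1024 px fields at 0.32 um/px holding ~200 nuclei (10 such fields pool
#' to the >= 2000 cells per condition used for micronucleus scoring), Fucci
#' class probabilities (red, green, both), Poisson-distributed damage foci, and
#' a smooth background with optional signal-dependent noise.
#'
#' @param fieldSize integer pair (height, width) in px.
#' @param nCells non-negative integer, number of isolated nuclei.
#' @param cellRadius positive range (min, max) of nucleus radii in px.
#' @param fucciClassProbs probability triple (red, green, both); must sum to 1.
#' @param meanFociPerCell non-negative Poisson rate of damage foci per cell.
#' @param focusRadius positive range of focus radii in px.
#' @param micronucleusProb per-cell probability of carrying one micronucleus.
#' @param micronucleusRadius positive range of micronucleus radii in px; the
#'   maximum must stay strictly below \code{min(cellRadius)} (size separability
#'   is the classical detector's premise).
#' @param backgroundLevel non-negative constant background (counts).
#' @param backgroundGradientAmplitude amplitude of the smooth background
#'   gradient (counts); the gradient varies on the scale of the whole field.
#' @param noiseSd read-noise standard deviation (counts). 0 disables all noise
#'   (exact-test mode); when positive, signal-dependent shot noise with unit
#'   gain is added on top (per-pixel sd \code{sqrt(noiseSd^2 + signal)}).
#' @param zPlanes positive integer number of z planes.
#' @param touchingPairs number of additional nucleus pairs painted at 1.6 x
#'   radius separation (touching blobs that watershed must split).
#' @param pairedFociCells number of cells that receive exactly one close focus
#'   pair at 1.5 x focus-radius separation instead of Poisson foci.
#' @param pixelSizeUm micrometers per pixel.
#' @param seed integer seed for the hierarchical generator.
#' @return a validated config (classed list) for [generateField()].
#' @examples
#' cfg <- synthImageConfig(nCells = 20, seed = 1)
#' @export
synthImageConfig <- function(fieldSize = c(1024L, 1024L),
                             nCells = 200L,
                             cellRadius = c(8, 13),
                             fucciClassProbs = c(red = 0.5, green = 0.3, both = 0.2),
                             meanFociPerCell = 3,
                             focusRadius = c(1.5, 2.5),
                             micronucleusProb = 0.1,
                             micronucleusRadius = c(1.5, 2.5),
                             backgroundLevel = 200,
                             backgroundGradientAmplitude = 50,
                             noiseSd = 0,
                             zPlanes = 1L,
                             touchingPairs = 0L,
                             pairedFociCells = 0L,
                             pixelSizeUm = 0.32,
                             seed = 1L) {
  stopifnot(length(fieldSize) == 2L, all(fieldSize > 0),
            nCells >= 0, length(cellRadius) == 2L, all(cellRadius > 0),
            cellRadius[1] <= cellRadius[2],
            length(fucciClassProbs) == 3L, all(fucciClassProbs >= 0),
            meanFociPerCell >= 0, all(focusRadius > 0),
            focusRadius[1] <= focusRadius[2],
            micronucleusProb >= 0, micronucleusProb <= 1,
            all(micronucleusRadius > 0),
            micronucleusRadius[1] <= micronucleusRadius[2],
            backgroundLevel >= 0, backgroundGradientAmplitude >= 0,
            noiseSd >= 0, zPlanes >= 1L, touchingPairs >= 0L,
            pairedFociCells >= 0L, pixelSizeUm > 0)
  if (abs(sum(fucciClassProbs) - 1) > 1e-9)
    stop("fucciClassProbs must sum to 1 (within 1e-9)")
  if (max(micronucleusRadius) >= min(cellRadius))
    stop("micronucleusRadius max must be strictly below cellRadius min")
  cfg <- list(
    fieldSize = as.integer(fieldSize), nCells = as.integer(nCells),
    cellRadius = cellRadius,
    fucciClassProbs = setNames(fucciClassProbs, c("red", "green", "both")),
    meanFociPerCell = meanFociPerCell, focusRadius = focusRadius,
    micronucleusProb = micronucleusProb,
    micronucleusRadius = micronucleusRadius,
    backgroundLevel = backgroundLevel,
    backgroundGradientAmplitude = backgroundGradientAmplitude,
    noiseSd = noiseSd, zPlanes = as.integer(zPlanes),
    touchingPairs = as.integer(touchingPairs),
    pairedFociCells = as.integer(pairedFociCells),
    pixelSizeUm = pixelSizeUm, seed = as.integer(seed),
    # painted amplitudes (counts, 16-bit context); foci 5x background
    dnaAmp = 3000, fucciAmp = 3000, fucciLeak = 0.02,
    focusAmp = 5 * max(backgroundLevel, 200), mnAmpFrac = 0.8)
  class(cfg) <- "SynthImageConfig"
  cfg
}

# smooth background varying on the scale of the whole field
.background <- function(H, W, level, amp) {
  level + amp * outer(sin(pi * seq_len(H) / H), sin(pi * seq_len(W) / W))
}

# radial boundary function of a deformed ellipse; returns TRUE/FALSE mask
# pixels for a bounding box, plus the pixel coordinates
.paintBlob <- function(H, W, cy, cx, r, shape) {
  ext <- ceiling(r * 1.35) + 1L
  ys <- max(1L, floor(cy - ext)):min(H, ceiling(cy + ext))
  xs <- max(1L, floor(cx - ext)):min(W, ceiling(cx + ext))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- cos(shape$phi) * dx + sin(shape$phi) * dy
  v <- -sin(shape$phi) * dx + cos(shape$phi) * dy
  a <- r / (1 - shape$ecc^2)^0.25
  b <- a * sqrt(1 - shape$ecc^2)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  theta <- atan2(v, u)
  lim <- 1 + shape$h2 * cos(2 * theta + shape$p2) +
             shape$h3 * cos(3 * theta + shape$p3)
  inside <- rho <= lim
  list(ys = ys, xs = xs, mask = inside)
}

.randomShape <- function() {
  list(phi = runif(1, 0, pi), ecc = runif(1, 0, 0.6),
       h2 = runif(1, 0, 0.06), h3 = runif(1, 0, 0.05),
       p2 = runif(1, 0, 2 * pi), p3 = runif(1, 0, 2 * pi))
}

.circleShape <- function() {
  list(phi = 0, ecc = 0, h2 = 0, h3 = 0, p2 = 0, p3 = 0)
}

# dart-throwing placement; returns data.frame(y, x, r) or errors naming density
.placeCells <- function(cfg) {
  H <- cfg$fieldSize[1]; W <- cfg$fieldSize[2]
  n <- cfg$nCells; npair <- cfg$touchingPairs
  placed <- data.frame(y = numeric(0), x = numeric(0), r = numeric(0),
                       pair = integer(0))
  sep <- function(y, x, r) {
    if (!nrow(placed)) return(TRUE)
    d <- sqrt((placed$y - y)^2 + (placed$x - x)^2)
    all(d >= 1.25 * (placed$r + r) + 2)
  }
  # touching pairs first: two circles at 1.6 x radius separation
  for (p in seq_len(npair)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      r <- runif(1, cfg$cellRadius[1], cfg$cellRadius[2])
      m <- 1.25 * r + 1.6 * r + 2
      y <- runif(1, m, H - m); x <- runif(1, m, W - m)
      ang <- runif(1, 0, 2 * pi)
      y2 <- y + 1.6 * r * sin(ang); x2 <- x + 1.6 * r * cos(ang)
      if (sep(y, x, r) && sep(y2, x2, r)) {
        placed <- rbind(placed,
          data.frame(y = c(y, y2), x = c(x, x2), r = r, pair = p))
        ok <- TRUE; break
      }
    }
    if (!ok) .packingError(placed, cfg)
  }
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      r <- runif(1, cfg$cellRadius[1], cfg$cellRadius[2])
      m <- 1.35 * r + 2
      y <- runif(1, m, H - m); x <- runif(1, m, W - m)
      if (sep(y, x, r)) {
        placed <- rbind(placed, data.frame(y = y, x = x, r = r, pair = 0L))
        ok <- TRUE; break
      }
    }
    if (!ok) .packingError(placed, cfg)
  }
  placed
}

.packingError <- function(placed, cfg) {
  dens <- sum(pi * placed$r^2) / prod(cfg$fieldSize)
  stop(sprintf(
    "infeasible packing: could not place cell %d after 1000 retries (area density already %.1f%%)",
    nrow(placed) + 1L, 100 * dens))
}

#' Generate a synthetic multi-channel field with ground truth
#'
#' Paints non-overlapping nuclear blobs into \code{dna}, \code{red},
#' \code{green} and \code{damage} channels. Red-class cells carry high red /
#' low green signal, green-class the converse, both-class high signal in both
#' channels. Damage foci are Gaussian spots (sd = radius / 2, amplitude 5 x
#' background) painted inside nuclei; micronuclei are small DNA-positive discs
#' placed within 2 cell radii of their parent nucleus. Identical config and
#' seed give bit-identical output.
#'
#' @param config a [synthImageConfig()] object.
#' @return list with elements \code{image} ([ImageStack-class]) and
#'   \code{truth} ([GroundTruth-class]).
#' @examples
#' fld <- generateField(synthImageConfig(fieldSize = c(256, 256), nCells = 10,
#'                                       seed = 3))
#' fld$image
#' nrow(gtCells(fld$truth))
#' @export
generateField <- function(config) {
  .generateFieldInternal(config, apoptoticFraction = NULL)
}

#' Generate a field with apoptosis and phase-contrast channels
#'
#' As [generateField()], adding \code{annexin}, \code{yoyo3} and \code{phase}
#' channels. A Bernoulli draw flags each cell apoptotic; apoptotic cells carry
#' co-localized Annexin V and YOYO-3 signal over their footprint. The phase
#' channel encodes the total cell footprint as high-variance texture on a
#' smooth background, the surrogate used for confluence/growth scoring.
#'
#' @param config a [synthImageConfig()] object.
#' @param apoptoticFraction probability in \[0, 1\] that a cell is apoptotic.
#' @return list with elements \code{image} and \code{truth}; apoptotic cells
#'   are flagged in \code{gtCells(truth)$apoptotic}.
#' @export
generateApoptosisField <- function(config, apoptoticFraction) {
  stopifnot(apoptoticFraction >= 0, apoptoticFraction <= 1)
  .generateFieldInternal(config, apoptoticFraction = apoptoticFraction)
}

.generateFieldInternal <- function(cfg, apoptoticFraction = NULL) {
  stopifnot(inherits(cfg, "SynthImageConfig"))
  H <- cfg$fieldSize[1]; W <- cfg$fieldSize[2]
  nz <- cfg$zPlanes
  apo <- !is.null(apoptoticFraction)
  roles <- c("dna", "red", "green", "damage")
  if (apo) roles <- c(roles, "annexin", "yoyo3", "phase")
  nch <- length(roles)

  placed <- .withStream(cfg$seed, 1L, .placeCells(cfg))
  ncell <- nrow(placed)

  classes <- .withStream(cfg$seed, 2L, {
    if (ncell)
      sample(c("red", "green", "both"), ncell, replace = TRUE,
             prob = cfg$fucciClassProbs)
    else character(0)
  })

  amps <- .withStream(cfg$seed, 3L, {
    list(dna = cfg$dnaAmp * rlnorm(ncell, 0, 0.1),
         hi = cfg$fucciAmp * rlnorm(ncell, 0, 0.15),
         hi2 = cfg$fucciAmp * rlnorm(ncell, 0, 0.15),
         shapes = lapply(seq_len(ncell), function(i)
           if (placed$pair[i] > 0L) .circleShape() else .randomShape()))
  })

  # z intensity profile: brightest mid-plane, symmetric fall-off
  zprof <- if (nz == 1L) 1 else {
    mid <- (nz + 1) / 2
    exp(-((seq_len(nz) - mid) / (0.6 * nz))^2)
  }

  px <- array(0, dim = c(nch, nz, H, W))
  bg <- .background(H, W, cfg$backgroundLevel, cfg$backgroundGradientAmplitude)
  for (ch in seq_len(4L)) for (z in seq_len(nz)) px[ch, z, , ] <- bg
  if (apo) {
    for (ch in 5:6) for (z in seq_len(nz)) px[ch, z, , ] <- bg
    for (z in seq_len(nz)) px[7, z, , ] <- .background(H, W, 500, 100)
  }

  redAmp <- greenAmp <- numeric(ncell)
  nPix <- integer(ncell)
  masks <- vector("list", ncell)
  for (i in seq_len(ncell)) {
    blob <- .paintBlob(H, W, placed$y[i], placed$x[i], placed$r[i],
                       amps$shapes[[i]])
    masks[[i]] <- blob
    nPix[i] <- sum(blob$mask)
    redAmp[i] <- switch(classes[i], red = amps$hi[i],
                        green = cfg$fucciLeak * amps$hi[i], both = amps$hi[i])
    greenAmp[i] <- switch(classes[i], red = cfg$fucciLeak * amps$hi2[i],
                          green = amps$hi2[i], both = amps$hi2[i])
    for (z in seq_len(nz)) {
      f <- zprof[z]
      add <- function(ch, amp) {
        sub <- px[ch, z, blob$ys, blob$xs]
        sub[blob$mask] <- sub[blob$mask] + amp * f
        px[ch, z, blob$ys, blob$xs] <<- sub
      }
      add(1L, amps$dna[i])
      add(2L, redAmp[i])
      add(3L, greenAmp[i])
    }
  }

  # damage foci
  fociRec <- .withStream(cfg$seed, 4L,
    .paintFoci(px, placed, masks, cfg, zprof))
  px <- fociRec$px

  # micronuclei
  mnRec <- .withStream(cfg$seed, 5L,
    .paintMicronuclei(px, placed, cfg, zprof, nz, H, W))
  px <- mnRec$px

  apoFlag <- rep(FALSE, ncell)
  if (apo && ncell) {
    apoFlag <- .withStream(cfg$seed, 7L,
      runif(ncell) < apoptoticFraction)
    px <- .withStream(cfg$seed, 8L,
      .paintApoptosis(px, placed, masks, apoFlag, cfg, nz))
  }

  if (cfg$noiseSd > 0) {
    px <- .withStream(cfg$seed, 6L, {
      for (ch in seq_len(nch)) for (z in seq_len(nz)) {
        sig <- px[ch, z, , ]
        px[ch, z, , ] <- pmax(0, sig + rnorm(length(sig),
                              sd = sqrt(cfg$noiseSd^2 + sig)))
      }
      px
    })
  }

  cells <- data.frame(
    cell_id = seq_len(ncell), y = placed$y, x = placed$x, r = placed$r,
    pair = placed$pair,
    fucci_class = if (ncell) classes else character(0),
    n_foci = fociRec$nFoci, n_micronuclei = mnRec$nMn,
    apoptotic = apoFlag, red_amp = redAmp, green_amp = greenAmp,
    n_pixels = nPix, stringsAsFactors = FALSE)
  names(cells)[names(cells) == "r"] <- "radius"

  truth <- new("GroundTruth", cells = cells, foci = fociRec$rec,
               micronuclei = mnRec$rec)
  img <- ImageStack(px, setNames(seq_len(nch), roles),
                    pixelSizeUm = cfg$pixelSizeUm)
  list(image = img, truth = truth)
}

# Gaussian spots, sd = radius/2, painted on one z plane each; per-cell focus
# centers kept >= 2 x (r_i + r_j) apart so noiseless counts are exact, except
# for explicit close pairs at 1.5 x radius separation (watershed-split tests).
.paintFoci <- function(px, placed, masks, cfg, zprof) {
  ncell <- nrow(placed)
  nz <- cfg$zPlanes
  rec <- data.frame(cell_id = integer(0), y = numeric(0), x = numeric(0),
                    radius = numeric(0), z = integer(0))
  nFoci <- integer(ncell)
  if (!ncell) return(list(px = px, rec = rec, nFoci = nFoci))
  counts <- rpois(ncell, cfg$meanFociPerCell)
  paired <- seq_len(min(cfg$pairedFociCells, ncell))
  counts[paired] <- 2L
  H <- dim(px)[3]; W <- dim(px)[4]
  for (i in seq_len(ncell)) {
    pts <- data.frame(y = numeric(0), x = numeric(0), r = numeric(0))
    if (i %in% paired) {
      rf <- runif(1, cfg$focusRadius[1], cfg$focusRadius[2])
      ang <- runif(1, 0, 2 * pi)
      off <- 0.75 * rf
      pts <- data.frame(
        y = placed$y[i] + c(-off, off) * sin(ang),
        x = placed$x[i] + c(-off, off) * cos(ang), r = rf)
    } else {
      for (k in seq_len(counts[i])) {
        for (try in seq_len(200L)) {
          rf <- runif(1, cfg$focusRadius[1], cfg$focusRadius[2])
          rr <- runif(1, 0, 0.6 * placed$r[i])
          th <- runif(1, 0, 2 * pi)
          fy <- placed$y[i] + rr * sin(th); fx <- placed$x[i] + rr * cos(th)
          if (!nrow(pts) ||
              all(sqrt((pts$y - fy)^2 + (pts$x - fx)^2) >= 2 * (pts$r + rf))) {
            pts <- rbind(pts, data.frame(y = fy, x = fx, r = rf))
            break
          }
        }
      }
    }
    nFoci[i] <- nrow(pts)
    if (!nrow(pts)) next
    zs <- sample.int(nz, nrow(pts), replace = TRUE)
    for (k in seq_len(nrow(pts))) {
      sdv <- pts$r[k] / 2
      ext <- ceiling(3.5 * sdv)
      ys <- max(1L, floor(pts$y[k] - ext)):min(H, ceiling(pts$y[k] + ext))
      xs <- max(1L, floor(pts$x[k] - ext)):min(W, ceiling(pts$x[k] + ext))
      g <- cfg$focusAmp * exp(-(outer((ys - pts$y[k])^2, (xs - pts$x[k])^2, "+")) /
                                (2 * sdv^2))
      px[4L, zs[k], ys, xs] <- px[4L, zs[k], ys, xs] + g
      rec <- rbind(rec, data.frame(cell_id = i, y = pts$y[k], x = pts$x[k],
                                   radius = pts$r[k], z = zs[k]))
    }
  }
  list(px = px, rec = rec, nFoci = nFoci)
}

.paintMicronuclei <- function(px, placed, cfg, zprof, nz, H, W) {
  ncell <- nrow(placed)
  rec <- data.frame(cell_id = integer(0), y = numeric(0), x = numeric(0),
                    radius = numeric(0))
  nMn <- integer(ncell)
  if (!ncell || cfg$micronucleusProb == 0)
    return(list(px = px, rec = rec, nMn = nMn))
  carry <- runif(ncell) < cfg$micronucleusProb
  for (i in which(carry)) {
    rp <- placed$r[i]
    for (try in seq_len(100L)) {
      mr <- runif(1, cfg$micronucleusRadius[1], cfg$micronucleusRadius[2])
      lo <- 1.35 * rp + mr + 1
      if (lo >= 2 * rp) lo <- 2 * rp - 0.5
      dd <- runif(1, lo, 2 * rp)
      th <- runif(1, 0, 2 * pi)
      my <- placed$y[i] + dd * sin(th); mx <- placed$x[i] + dd * cos(th)
      if (my < mr + 2 || my > H - mr - 2 || mx < mr + 2 || mx > W - mr - 2)
        next
      dall <- sqrt((placed$y - my)^2 + (placed$x - mx)^2)
      if (any(dall < 1.3 * placed$r + mr + 1)) next
      if (nrow(rec) &&
          any(sqrt((rec$y - my)^2 + (rec$x - mx)^2) < rec$radius + mr + 2))
        next
      blob <- .paintBlob(H, W, my, mx, mr, .circleShape())
      amp <- cfg$mnAmpFrac * cfg$dnaAmp
      for (z in seq_len(nz)) {
        f <- if (length(zprof) > 1) zprof[z] else 1
        sub <- px[1L, z, blob$ys, blob$xs]
        sub[blob$mask] <- sub[blob$mask] + amp * f
        px[1L, z, blob$ys, blob$xs] <- sub
      }
      rec <- rbind(rec, data.frame(cell_id = i, y = my, x = mx, radius = mr))
      nMn[i] <- nMn[i] + 1L
      break
    }
  }
  list(px = px, rec = rec, nMn = nMn)
}

# co-localized annexin/yoyo3 over apoptotic footprints; textured phase channel
.paintApoptosis <- function(px, placed, masks, apoFlag, cfg, nz) {
  ncell <- nrow(placed)
  for (i in seq_len(ncell)) {
    blob <- masks[[i]]
    # phase texture over every cell footprint
    tex <- 800 * runif(sum(blob$mask), 0.4, 1.6)
    for (z in seq_len(nz)) {
      sub <- px[7L, z, blob$ys, blob$xs]
      sub[blob$mask] <- sub[blob$mask] + tex
      px[7L, z, blob$ys, blob$xs] <- sub
    }
    if (apoFlag[i]) {
      ampA <- 2000 * rlnorm(1, 0, 0.1)
      ampY <- 2000 * rlnorm(1, 0, 0.1)
      for (z in seq_len(nz)) {
        for (champ in list(c(5L, ampA), c(6L, ampY))) {
          sub <- px[champ[1], z, blob$ys, blob$xs]
          sub[blob$mask] <- sub[blob$mask] + champ[2]
          px[champ[1], z, blob$ys, blob$xs] <- sub
        }
      }
    }
  }
  px
}

#' Sample per-cell Fucci intensities directly from the class model
#'
#' Draws \code{(red, green)} per-cell mean intensities from the same
#' three-class lognormal model the field painter uses, without rasterizing an
#' image — classifier-scale tests (thousands of cells) stay fast. Class
#' centers are separated by \code{separationSd} component standard deviations
#' in \code{log10(1 + intensity)} space.
#'
#' @param n number of cells.
#' @param probs probability triple (red, green, both).
#' @param separationSd separation of high and low class centers in units of the
#'   within-class sd (default 6).
#' @param sdLog10 within-class standard deviation in log10 feature space.
#' @param seed integer seed.
#' @return list with \code{cells} (data.frame \code{cell_id, red_mean,
#'   green_mean, area_px}) and \code{classes} (character ground truth).
#' @export
generateFucciIntensities <- function(n, probs = c(0.5, 0.3, 0.2),
                                     separationSd = 6, sdLog10 = 0.12,
                                     seed = 1L) {
  stopifnot(n >= 1, length(probs) == 3L, abs(sum(probs) - 1) < 1e-9,
            separationSd > 0, sdLog10 > 0)
  set.seed(.substreamSeed(seed, 11L))
  cls <- sample(c("red", "green", "both"), n, TRUE, probs)
  hi <- 3.4                       # log10 feature of a bright channel
  lo <- hi - separationSd * sdLog10
  fr <- ifelse(cls == "green", lo, hi) + rnorm(n, 0, sdLog10)
  fg <- ifelse(cls == "red", lo, hi) + rnorm(n, 0, sdLog10)
  cells <- data.frame(cell_id = seq_len(n),
                      red_mean = pmax(0, 10^fr - 1),
                      green_mean = pmax(0, 10^fg - 1),
                      area_px = 300L)
  list(cells = cells, classes = cls)
}
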