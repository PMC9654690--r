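---
title: "Quantification methods for hyperthermia sensitization assays"
author: "thermoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for hyperthermia sensitization assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoquant)
```

# Scope

Studies of thermo-sensitizers (for example HSP90 inhibitors combined with
42 °C hyperthermia) quantify their cellular effects through a recurring set
of assay readouts: nuclei segmented from fluorescence microscopy fields,
Fucci2a cell-cycle classes from per-cell red/green reporter intensities,
γH2AX/53BP1 damage foci and micronuclei counted per nucleus, growth and
apoptosis scores from live-cell imaging, clonogenic surviving fractions with
sensitizer enhancement ratios, and differential protein abundance from SILAC
proteomics. `thermoquant` implements each of these stages as a tested,
parameterized pipeline and pairs them with a synthetic-data generator that
paints images and abundance matrices with fully known ground truth, so that
every stage can be validated quantitatively without access to microscope or
mass-spectrometer output.

# The synthetic-data generator

`generateField()` paints a multi-channel field (`dna`, `red`, `green`,
`damage`, optionally `annexin`, `yoyo3`, `phase`) and records every painted
object in a `GroundTruth` container. Its defaults are the package's model of
the study conditions:

* **Field geometry.** 1024 × 1024 px at 0.32 µm/px (a 10× widefield
  objective context), 16-bit intensity scale, ~200 nuclei per field; ten
  such fields pool to the ≥ 2000 cells per condition used for micronucleus
  scoring. Nuclei are deformed ellipses — eccentricity up to 0.6, boundary
  perturbed by 2nd/3rd-order harmonics of a few percent — which is enough
  shape irregularity to exercise adaptive thresholding and watershed
  splitting without modelling chromatin texture.
* **Placement.** Dart throwing with 1000 retries per cell and a hard
  non-overlap margin; an infeasible density raises an error that names the
  achieved packing fraction. Touching pairs for watershed tests are placed
  explicitly at 1.6 × radius separation (`touchingPairs`), the same objects
  that drive the multinucleated-exclusion tests.
* **Fucci classes.** Each cell is red, green, or both with configurable
  probabilities (default 0.5/0.3/0.2). A bright channel carries a lognormal
  amplitude around 3000 counts (sdlog 0.15); the opposite channel leaks 2 %.
  On the `log10(1 + x)` feature scale the classes separate by roughly six
  within-class standard deviations, matching a clean reporter line.
* **Damage foci.** Per-cell Poisson counts (default mean 3), painted as
  Gaussian spots with sd = radius/2 and amplitude 5 × background, each on
  one z-plane. Focus centers are kept ≥ 2 × the summed radii apart so that
  noiseless counts are exact by construction; `pairedFociCells` instead
  paints one close pair per cell at 1.5 × radius separation for the
  watershed-splitting test.
* **Micronuclei.** With per-cell probability (default 0.1) a single small
  DNA-positive disc (radius 1.5–2.5 px, strictly below the minimum nucleus
  radius — the size separability the classical detector relies on) is
  placed within two cell radii of its parent.
* **Background and noise.** A smooth background (level 200, gradient
  amplitude 50 varying on the scale of the whole field) plus, when
  `noiseSd > 0`, Gaussian read noise and signal-dependent shot noise with
  unit gain (per-pixel sd `sqrt(noiseSd^2 + signal)`). `noiseSd = 0`
  disables all noise so that exactness tests are meaningful.
* **Seeding.** One integer seed feeds one child stream per object class
  (placement, classes, amplitudes, foci, micronuclei, noise), so enlarging
  one stage never perturbs the draws of another, and identical configs give
  bit-identical fields.

What the generator does **not** emulate: optical point-spread functions,
depth-dependent blur, chromatin texture, out-of-focus debris, or stain
bleed-through beyond the constant 2 % leak. Passing tests therefore
demonstrate correctness of the measurement logic under controlled imaging
physics, not robustness to every real-microscope artifact.

`generateAbundance()` produces a `SummarizedExperiment` of log2 protein
abundances: per-protein baselines ~ N(25, 2²), replicate noise sd 0.3,
condition effects injected into a configurable fraction of proteins, and
missing-not-at-random dropout whose probability is a logistic function of
abundance (slope `mnarStrength`, midpoint calibrated by root finding so the
overall missing rate is exact). This left-censoring is precisely the
assumption that justifies downshifted-normal imputation.
`generateFucciIntensities()` samples the per-cell intensity model directly
(no rasterization) so classifier-scale tests with thousands of cells run in
seconds; the full image route is exercised end-to-end at smaller n.

# Nuclei segmentation

The chain is rolling-ball background correction → median denoising →
red/green channel merging → locally adaptive thresholding →
distance-transform watershed → small-mask removal.

* **Rolling ball** is implemented as grayscale opening with a disc
  structuring element (the classical flat-disc form of the rolling-ball
  background): the output is non-negative, pointwise below the input, maps
  constant images to zero, and is invariant to constant offsets. The
  residual on a pure smooth gradient of amplitude *g* scales like
  *g·(R/L)²* for ball radius *R* and gradient length scale *L*, so the ball
  radius must be small against the background variation but large against
  the objects; the default is 4 × the maximum expected nucleus radius.
* **Adaptive threshold**: local mean over a block of 1/8 of the smaller
  image dimension, plus an offset. A zero offset marks roughly half of all
  flat-background pixels (they sit marginally above their local mean), and
  those speckles can aggregate into components larger than the small-mask
  cutoff; the default offset is therefore 5 % of the image maximum, exposed
  in `segParams()`.
* **Watershed**: Euclidean distance transform, seeds = local maxima with a
  minimum separation (default 0.7 × the median expected radius; the
  implementation's suppression half-width is half that separation) and a
  0.5 px depth tolerance, calibrated on the generator's stated geometry
  (pairs at 1.6 × radius, radii 8–13 px, eccentricity ≤ 0.6). The watershed
  is restricted to within-component splits by re-keying labels on
  (connected component, basin) pairs; without this, a small object near a
  larger one can lose its seed to the suppression neighborhood and be
  flooded with the neighbor's label across background — which would swallow
  micronuclei into nucleus masks.
* **Small masks** below 25 % of the area of a circle at the minimum
  expected radius are removed and labels compacted to `1..nObjects`. This
  cutoff also keeps micronuclei (area ≲ 20 px) out of the nucleus map.
* **Conventions**: (row, col) coordinates, 0-based origin top-left in all
  file output; 4-connected labelling; border-touching objects are flagged,
  kept for counting, and excluded from per-cell intensity statistics
  because partial cells bias intensity-based classification.

With `doWatershed = FALSE` the chain reproduces pipelines whose masks may
contain several nuclei (tissue-section imaging); `excludeMultinucleated()`
then removes any mask holding ≥ 2 distance-transform seed maxima under the
same seeding rule, mirroring the rule that DNA-stain masks containing
multiple nuclei are excluded from per-cell quantification.

# Fucci classification

Per-cell mean red/green intensities (background-corrected, border cells
excluded) are transformed to `log10(1 + x)` — fluorescence amplitudes are
right-skewed and raw-scale mixtures are initialization-sensitive — and
fitted with a three-component full-covariance Gaussian mixture
(`fitFucciModel()`, EM with deterministic model-based hierarchical
initialization). Components map to biological classes by the ratio rule:
highest red-to-green mean ratio → red, lowest → green, remainder → both.
The rule depends only on component means, so it is invariant to component
relabelling and global intensity scaling. Cells with zero intensity in both
channels carry no class information; they are reported `unclassified`,
counted separately, and excluded from distributions. Posterior ties break
toward the lowest component index. One model is fitted per field collection
(condition × timepoint) by default — imaging-day intensity drift makes a
pooled fit a deliberate choice rather than a default — but nothing prevents
pooling the cell tables before fitting.

# Damage readouts

`countFoci()` projects the damage channel by maximum intensity across z,
smooths lightly (Gaussian sd 0.75 px), and thresholds per nucleus with
Otsu's method restricted to the nucleus mask. Connected components within
the area bounds (default 4–200 px at 0.32 µm/px) are split by an intensity
watershed (tolerance 8 % of the above-threshold dynamic range) and counted
for the nucleus containing each component's peak pixel, so boundary-
overlapping foci are attributed by their peak and foci outside any nucleus
are ignored. Two guards suppress spurious detections in focus-free nuclei:
the intensity range inside the nucleus must exceed `minContrast` (50
counts), and a candidate's peak must rise ≥ 5 MADs above the median nucleus
intensity. An Otsu split of pure noise or of the smooth background fails one
of the two; these defaults hold counting exact on noiseless stacks while
keeping the mean absolute error ≤ 0.5 foci/cell at per-focus SNR 5. The
smoothing sd and watershed tolerance trade off close-pair resolution against
noise-induced fragmentation; sd 0.75 px with tolerance 0.08 resolves pairs
at 1.5 × radius separation for focus radii ≳ 2 px while leaving the SNR-5
error budget intact. The pipeline operates on projections directly — no
deconvolution — so the acceptance of its numbers rests on synthetic ground
truth rather than on reproducing any proprietary restoration step.

`detectMicronuclei()` is a rule-based detector (a deliberate, classical
replacement for trained-network detectors): DNA-positive components (global
Otsu) outside every nucleus mask (plus a 1 px guard ring), with area between
`mnMinAreaPx` and `mnMaxAreaFrac` × the parent nucleus area, assigned to the
nearest nucleus centroid within `maxDistancePx` (30 px default); distance
ties go to the lower cell id, unassignable candidates are dropped and
logged. `percentWithMicronucleus()` pools counts over fields and returns
`100 × #(cells with ≥ 1)/#cells`.

# Growth and apoptosis scoring

Phase-contrast footprints are textured while free background is smooth, so
`cellArea()` thresholds a local-standard-deviation image (7 px box window)
with Otsu's method, closes small gaps, and erodes back the half-window the
box filter dilated the support by — without that erosion the area is
overestimated by the perimeter band (~70 % for 10 px objects). The
apoptosis statistic is the integrated Annexin V + YOYO-3 intensity over the
double-positive region (AND of the per-channel thresholds, following the
"Annexin V⁺/YOYO-3⁺" convention; an OR mode exists for sensitivity
analysis) divided by the cell area: 0 when the region is empty, an error
when signal exists but the area is zero. Multiplying both fluorescence
channels and thresholds by a constant scales the statistic by that constant.

# Clonogenic and survival arithmetic

`survivingFraction()` is the treated plating efficiency over the control
plating efficiency (a colony being ≥ 50 cells); `enhancementRatio()` is the
fold reduction in surviving fraction attributable to adding the sensitizer,
with 1 marking no enhancement; `medianSurvivalFold()` uses the standard
even-length median convention. Zero denominators are errors, not silent
infinities — a zero surviving fraction with sensitizer means the enhancement
exceeded the assay's detection limit.

# Proteomics post-processing

`imputeMissing()` replaces missing log2 abundances per sample column with
draws from `Normal(μ − 1.8 σ, (1.3 σ)²)`, where μ and σ are the column's
observed mean and standard deviation — the Perseus-style left-censored
imputation with its published width and downshift. Imputation is per column
because label channels differ in their abundance distributions. Observed
values are never touched and a fixed seed reproduces the matrix exactly.

`callRegulated()` reports, per protein: the log2 fold change between two
conditions (means on the imputed matrix by default; observed-only means via
`useImputed = FALSE` as a sensitivity analysis), the direction from the
±0.5 rule, a one-way ANOVA p-value across all conditions, and the
Benjamini–Hochberg FDR. The fold-change filter and the test are reported
separately because they serve different purposes: the ±0.5 rule selects
input for overrepresentation analysis, while the FDR flags confident calls.
The convenience flag `significant = |log2fc| > 0.5 AND fdr < 0.05` combines
them. At three replicates with 0.3 log2 replicate noise, the combined flag
is power-limited (the F(2,6) non-centrality at a one-unit effect gives
roughly 20–40 % sensitivity at the BH-effective threshold — a property of
the design, not of the implementation), whereas the fold-change rule alone
recovers ~98 % of one-unit effects; the recovery tests assert each
component at what it can deliver.

# Numerical choices and degenerate inputs

* Morphological and median operations run on max-normalized copies (the
  underlying kernels clamp to [0, 1]); both are exactly scale-equivariant,
  so results are returned on the original intensity scale.
* All-zero images segment to zero objects; empty label maps produce empty
  tables; an empty assignment vector or a zero-cell percentage is an error.
* The median window is an odd width in px; even widths are rejected rather
  than silently grown.
* 16-bit TIFF output quantizes intensities to one count; the sidecar JSON
  records channel order, z-planes, pixel size and coordinate convention.
* Tie rules are fixed and documented: posterior ties to the lowest mixture
  component, micronucleus distance ties to the lower cell id.

# Validation scales

The test suite and the acceptance script exercise the package at the scales
the assays use while staying desk-sized: 200-cell fields (plus 100 seeded
touching pairs) for segmentation, 2000 cells for Fucci classification and
for the pooled micronucleus percentage (10 fields × 200 cells), 50-cell
z-stacks at Poisson mean 3 for focus counting (noiseless and at SNR 5),
10⁵ imputation draws, all 255 subsets of eight p-values against a
brute-force Benjamini–Hochberg oracle, and a 1000-protein null simulation.

# Known limitations

* The micronucleus and focus detectors are classical rule-based methods;
  they are validated against the generator's geometry and will not match a
  trained detector on heavily textured real images.
* Phase-contrast area is a texture surrogate for confluence; cell types
  with smooth appearance would need different parameters.
* The generator's noise model (Gaussian read + Gaussian-approximated shot
  noise) omits camera fixed-pattern noise and saturation.
* Enhancement ratios and survival folds are point estimates; interval
  estimation across biological replicates is left to the surrounding
  analysis.
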