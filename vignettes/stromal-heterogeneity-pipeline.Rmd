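---
title: "Quantifying stromal-cell heterogeneity: models, parameters and design choices"
author: "StromaQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stromal-cell heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StromaQuant)
```

Bone marrow stromal cell (BMSC) cultures are heterogeneous: they mix
multipotent, spindle-shaped, motile cells with nullipotent, flat and
spread cells, and the two subsets differ in the extracellular matrix they
secrete. StromaQuant implements the quantitative workflow used to
characterise such cultures: label-free quantitative phase imaging (QPI)
morphometry, cell tracking with debris gates, automated CFU-F colony
measurement from flatbed scans, reference-based subtype classification,
and secretome statistics. Every stage is paired with a seeded synthetic
generator that produces data of the same statistical structure together
with exact ground truth, which is how the package validates itself.

This vignette explains the models behind each stage, the parameters that
matter, the numerical choices, and what the synthetic validation does and
does not establish about real data.

## Phase-image morphometry

A phase image assigns each pixel the optical phase delay (radians)
accumulated through the specimen. Because phase is proportional to the
local dry (non-aqueous) mass density, QPI yields per-cell dry mass without
labels via

$$ m = \frac{\lambda}{2\pi\alpha} \int \varphi \, dA, $$

where $\lambda$ is the illumination wavelength and $\alpha$ the specific
refractive increment of cellular material, approximately
0.18–0.21 µm³/pg; the package default is `dryMassAlpha = 0.2` and the
value is configurable because reported increments vary with cell type and
medium.

The per-frame chain is:

1. **Rolling-ball background removal.** The background is the grayscale
   opening of the frame with a ball structuring element used in its
   flat-disc limit. A ball whose vertical curvature is expressed in raw
   phase units (fractions of a radian over tens of pixels) is *sharper*
   than cell-scale bumps, so it would track the cells themselves and
   carve their interiors — we observed exactly this, as spurious double
   seed points on large flat cells. At the dynamic range of phase images
   the classic implementations are effectively flat, and the flat-disc
   limit is the default (`zScale = 0` internally). The ball radius
   (default 50 px) must exceed the half-width of the largest cell; this
   is a documented contract, not a checked invariant. Large radii are
   computed on a block-minimum-shrunken copy and resized back bilinearly,
   the standard speed-up.
2. **Gaussian smoothing** (`smoothSigma`, default 2 px) with a unit-sum
   kernel and replicated boundary, to suppress pixel noise before local
   maxima are sought.
3. **Seed detection**: local maxima of the smoothed frame above the
   segmentation threshold, separated by at least `minSeedDistance`
   (default 10 px), thinned greedily brightest-first.
4. **Seed consolidation**: two seeds whose connecting straight-line
   intensity profile never dips more than `consolidationDelta` below the
   dimmer seed lie on one intensity plateau — one cell — and only the
   brighter survives. Vendor pipelines describe such a
   consolidation step without stating the exact rule; the along-path
   interpretation implemented here is this package's own specification,
   not a claim about any proprietary implementation. The default
   tolerance is 10% of the frame maximum.
5. **Seeded watershed**: the above-threshold foreground is partitioned by
   ordered flooding from the brightest intensity level down, so label
   boundaries form along intensity valleys. We implemented the flooding
   directly (tests compare it against a brute-force steepest-ascent
   oracle) after finding that regularised geodesic region growing, the
   common library alternative, places boundaries measurably differently
   on touching cells.
6. **Measurement**: area is pixel count times pixel area; length and
   width are $4\sigma$ along the major/minor axes of the
   intensity-weighted second-moment ellipse (for a uniform ellipse with
   semi-axes $a \ge b$ this gives $2a$ and $2b$); the aspect ratio is
   their quotient. Since the measured frame is the smoothed frame, the
   smoothing variance $(\sigma_s \cdot \text{pixel size})^2$ is
   subtracted from the second moments before the axes are formed —
   Gaussian convolution adds exactly that variance, and without the
   correction aspect ratios of elongated cells are biased low by several
   percent.

**Thresholding.** The automatic threshold is a robust background
threshold: the histogram mode of the preprocessed frame plus six robust
standard deviations (1.4826 × MAD). We initially used Otsu's method, but
on fields mixing bright spindle cells with faint flat cells the global
Otsu threshold settles *above* the peak phase of the faint cells and
clips or misses them entirely; the background-anchored threshold does
not, because the mode and MAD are dominated by the (majority) background
pixels regardless of how bright the brightest cells are. An explicit
threshold in radians can always be supplied.

Dry mass is integrated over the thresholded cell mask, so the
sub-threshold tails of a cell's phase profile are excluded; measured
masses therefore sit systematically below the whole-blob integral (about
25% for the synthetic profile shape). This mirrors any mask-based QPI
measurement and is why the generator's dry-mass encoding invariant is
defined on the whole rendered blob, not the mask.

## Tracking and migration

Detections are linked frame-to-frame by greedy mutual nearest neighbours
under a distance cap (`maxLinkDistance`, default 50 µm): pairs that are
each other's nearest neighbour and within the cap are linked, iterating
until none remain; unmatched detections open new tracks and unmatched
tracks end (optional single-frame gap closing via `maxGap = 1`). Commercial
live-cell tracking algorithms are proprietary; mutual-nearest-neighbour
linking is the standard minimal open formulation. Identity swaps when
two cells pass within a step length of each other are inherent to any
nearest-neighbour linker; on the synthetic ensembles about 5% of tracks
contain a swap, which leaves ensemble speed and displacement statistics
unaffected.

Exclusion gates (`gateParams()`) remove small debris — objects below
250 pg dry mass and/or below 1000 µm² — and large doublets/debris above
25,000 µm², and drop tracks observed for fewer than 20 frames. Stated as a joint
condition, such a gate is ambiguous between requiring both floors or
either one; the default removes on *either* floor (the stricter and more
conventional debris gate) and `combine = "and"` switches to the
conjunctive reading. Every removal is written to an audit log with its
reason, so gating is idempotent and accountable
(`|input| = |kept| + |audit|`).

Per track, the migration metrics are: path length (sum of stepwise
Euclidean distances), mean speed (path length over elapsed time — not the
mean instantaneous frame speed; the two differ under irregular frame
intervals), and displacement (straight-line distance from first to last
position). Rose-plot data are the tracks translated to a common origin.

## The synthetic time-lapse generator

The generator emulates the acquisition regime the analysis assumes:
frames every 24 min (acquisitions are typically taken every 20–26 min)
for up to 96 h, cells from one or more populations with log-normally
distributed aspect ratio, area and dry mass (median equal to the
population mean, log-sd equal to `sd/mean`, respecting positivity and the
ratio floor of 1).

*Rendering.* Each cell is an elliptical super-Gaussian phase blob
($\varphi = \varphi_0 e^{-q^2}$ with
$q = (x'/a)^2 + (y'/b)^2$, support truncated at $q \le 3$), with
$\varphi_0$ set so the integrated phase encodes the cell's dry mass under
the same $\alpha = 0.2$ µm³/pg as the measurement default. The profile is
smooth with a single well-defined maximum, which is what seed detection
assumes.

*Motion.* A persistent random walk: Ornstein–Uhlenbeck velocity with
persistence time `persistenceTime` (default 60 min, a typical fibroblast
value) and stationary speed distribution scaled so the mean
frame-to-frame speed equals `meanSpeed`. Velocities are held constant
within a frame interval, so the generator's nominal speed is exactly the
expected measured path-length rate; positions reflect at the field
boundary. Point estimates of BMSC migration speed
vary widely across substrates and media, so the generator's speed
defaults (20 µm/h for the spindle phenotype, 10 µm/h for the flat
phenotype, reflecting the roughly twofold difference between the two
morphotypes) are free, realistic parameters, not calibrated values.

*Placement.* Initial positions are rejection-sampled with centre
separations of at least 1.2 times the sum of the major semi-axes. Tighter
packing lets the truncated tails of two same-brightness cells form a
near-plateau along the line between their maxima, which the consolidation
rule then (correctly, given its definition) merges; real confluent fields
have the same failure mode. Cells may still overlap transiently while
moving. An overfull field raises an error rather than degrading silently.

*Reference phenotypes.* `referencePopulations()` encodes the two
reference morphotypes used throughout the validation suite: a spindle
phenotype at aspect ratio 3.59 and a flat phenotype at 2.016 — the two
reference means the classifier is built around — with spread areas of
2500 and 4000 µm² (the flat phenotype is larger), dry masses of 400 and
480 pg, and relative spreads of 10–15%, values chosen once as realistic
for cultured BMSCs.

## CFU-F plate analysis

Plates are scanned RGB images (1200 dpi convention; 1 px = 21.17 µm).
The pipeline reproduces a scanner-image colony workflow stage by stage:

1. **Well location.** Rims are near-black objects on the blue channel
   (`1 − blue ≥ 0.99`) whose outer diameter lies in 1000–2000 px. A
   regular 2 × 3 lattice is least-squares fitted to the rim centroids
   (at least 4 rims required; missing rims are reconstructed from the
   lattice), perfect circles are placed at the nodes, and the analysis
   circle is the fitted inner radius minus 5 px — the rim circle shrunk
   by 10 px in diameter so measurements never run over the well edge.
   The fitted radius is the 2nd percentile of rim-pixel radial distances,
   i.e. the inner rim edge.
2. **Unmixing.** Per-channel optical density $-\log_{10}(I)$ projected
   onto the crystal-violet absorbance direction $(1, 1, 0)/\sqrt{2}$ —
   red and green absorb, blue does not. Zero-intensity pixels are clipped
   to $10^{-3}$ with a warning.
3. **Illumination correction.** Per-20-px-block medians of the stain
   image (in-well pixels only), median-filtered at the 80-px object
   scale, then summarised by a robust (bisquare `rlm`) quadratic surface
   that is subtracted within the wells. The robust surface fit is the
   deliberate departure from a pure block-filter design: a median filter
   at the stated sizes would treat any colony larger than ~100 px as
   illumination and erase it, whereas colonies of any size are outliers
   to the quadratic trend and cannot enter the surface. Detection is
   invariant to smooth illumination gradients up to at least 20% by this
   construction (exercised in the test suite at 15%).
4. **Detection.** Sobel gradient magnitude, scaled to the stain image's
   dynamic range, is added to the stain image (edge enhancement picks up
   cells dispersed away from a tight colony); a per-well robust
   background threshold (background mode + 3 × 1.4826 MAD, with the
   spread floored at 5% of the dynamic range so noise-free backgrounds
   cannot collapse the threshold) produces the binary mask; a
   diamond-shaped closing with reach 10 px merges dispersed-cell halos
   (gaps up to 20 px) into their colony; components are kept when their
   *half-maximum core* equivalent diameter lies in 60–800 px.
5. **Measurement.** The detected footprint includes the edge-enhancement
   ring and closed gaps, so colony area is refined to the stained core:
   pixels whose stain reaches half the colony's plateau intensity (95th
   percentile) — the full-width-at-half-maximum convention, which
   recovers a stained disc's area irrespective of edge softness. Reported
   per colony: area (px² and mm²), equivalent diameter, second-moment
   eccentricity, centroid, integrated optical density, plus per-well
   counts and mean areas. Interactive manual correction is replaced by an
   `exclude` argument taking colony labels.

The plate generator renders colonies as soft-edged discs in optical
density space with red+green absorbance (so the unmixing step is
analytically checkable: a blue-only absorber maps to stain 0), optional
dispersed-cell halos just outside the rim, sub-60-px debris, near-black
rims at known centres, a smooth illumination gradient and pixel noise.
Colony placement keeps edge gaps above the closing reach plus halo
extent, so distinct planted colonies are never artificially bridged —
the merging behaviour itself is tested on purpose-built fixtures instead.

## Subtype classification

Reference profiles are the mean and covariance of
$(\log \text{aspect ratio}, \log \text{area})$ over at least 30 reference
cells per phenotype (both features are right-skewed, hence the log). A
query cell is assigned to the nearer profile by Mahalanobis distance only
when the assignment is unambiguous: $|d_1 - d_2| \ge$ `margin` (default
1.0) and the nearer distance is at most `dMax` (default 3.0); otherwise
it is between categories and reported as unclassified. There is no canonical
decision rule for this kind of morphometric gating, so the rule above is
the package's own specification; the margin and cap are exposed. The
decision rule is deterministic, label-swap symmetric, and increasing the
margin can only grow the unclassified fraction.

`betweenPopulation()` constructs the intermediate, "between categories"
population used in validation: the geometric midpoint of two references
with spread reduced to 25% of theirs. The width matters: intermediate
cells drawn as broadly as the references themselves would straddle the
margin boundary and leak into both classes, which is a statement about
that mixture, not about the classifier. With the default references the
midpoint sits about 3 Mahalanobis units from either profile, so both the
margin rule and the distance cap declare it unclassified.

The synthetic 50/25/25 mixture is recovered within a few percentage
points per class. This validates the decision rule's geometry, not the
biological split of any real culture: real primary-culture fractions
depend on the withheld imaging data and on how far real morphologies
match the two-Gaussian feature model.

## Secretome statistics

- **Normalisation**: each sample column is scaled so its total matches
  the across-sample mean total (total-ion-intensity normalisation).
  Idempotent; rescaling a single sample leaves its normalised profile
  unchanged (the common scale is, by construction, the mean of the
  observed totals, so the absolute level of the whole table may shift).
- **Differential abundance**: per protein, one-way ANOVA across groups
  (with two groups, F equals the squared pooled-variance t, an identity
  the tests exercise) and fold change as the ratio of arithmetic group
  means with zero means floored at one tenth of the smallest positive
  abundance. Proteins constant across all samples get p = 1 with a
  warning. Whether the original quantification used ratio-of-means or
  mean-of-ratios is unstated; ratio-of-means is the declared choice.
- **Matrisome annotation** against a protein → division/category list;
  proteins absent from the list are non-matrisome; conflicting duplicate
  entries are an error. The summary reports counts per division and the
  annotated percentage.
- **Enrichment of matrisome among significant proteins**: two-category
  Pearson goodness-of-fit (df = 1) of the observed matrisome count
  against the background expectation, *without* continuity correction:
  for the worked-example counts (28 matrisome among 44 significant,
  background 175 of 861) the uncorrected statistic is 50.97, while a
  Yates correction would give ≈ 48.3.
- **Over-representation**: hypergeometric upper-tail p for the overlap of
  the query with each set (sets restricted to the detected-protein
  universe), sets larger than 500 members excluded *before* testing,
  Benjamini–Hochberg q over the tested sets, q ≤ 0.05 kept, ranked by p
  with ties broken by the k/K ratio descending.

The abundance generator plants known fold changes on chosen proteins in
log-normal tables (baselines with log-sd 1.5 around 10⁶, per-sample
multiplicative noise of coefficient of variation `cv`, default 0.1,
chosen as a realistic replicate CV for label-free quantification). At
`cv = 0` planted ratios are exact by construction. With three replicates
per group the fold estimator itself has ~8% log-scale standard error, so
the validation suite checks recovery within 10% at a fixed seed, and the
acceptance script averages the estimator over five simulated experiments.

## Problem sizes and determinism

All randomness flows through per-spec integer seeds
(`withr::with_seed`); identical specs give bit-identical outputs, and no
generator touches the global RNG state. The validation suite uses: 200
cells per population (10 per 560 × 560 px field at 1.4 µm/px) for
morphometric recovery; a 100-track, 96-h ensemble for tracking; two
six-well plates (~2200 × 3400 px) for colony detection; 1000 cells for
the classifier mixture; and 861-protein tables with three replicates per
group for the secretome stage — sizes chosen to give stable estimates at
interactive runtimes.

## Limitations

- The synthetic cells are rigid ellipses: no shape dynamics, division,
  apoptosis or crawling-induced shape change, so tracking is not
  stressed by morphology changes, only by motion.
- Phase rendering is a forward cartoon (smooth blob plus ramp and
  Gaussian noise), not a ptychographic forward model; halo and shot-noise
  artefacts of real reconstructions are absent.
- Mask-based dry mass underestimates whole-cell mass (tail truncation),
  consistently across populations.
- Colony detection is validated on disc-like colonies with halos; highly
  irregular or overlapping real colonies will exercise the closing and
  size filters differently, which is what the `exclude` hook is for.
- The classifier's two-Gaussian feature model and the 50/25/25 recovery
  say nothing about the true composition of real donor cultures.
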