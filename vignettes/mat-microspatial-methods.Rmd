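---
title: "Quantifying SRM microspatial organization in mat micrographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying SRM microspatial organization in mat micrographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
set.seed(1)
```

```{r}
library(matmicrospat)
```

## The scientific problem

Marine stromatolite surface mats cycle between a non-lithifying,
accreting state (Type-1) and a lithifying state (Type-2) in which a thin
(30–50 µm) crust of CaCO~3~ precipitates at the surface. Sulfate-reducing
microorganisms (SRM) are implicated in that transition: in lithifying
mats they become more abundant, concentrate in a dense layer within
roughly the top 130 µm, organize into clusters, and sit in close
proximity to the carbonate precipitates. Testing these statements
requires *microspatial* quantification of fluorescence micrographs:
which pixels are SRM, what share of the microbial community they occupy
near the surface, whether their arrangement is random or clustered, and
how close they sit to mineral phases.

This package implements that measurement pipeline, together with a
synthetic scene generator that plays the role of the field samples. The
generator plants a known truth (object lists, noiseless class masks, a
known surface line), so every stage of the pipeline — classification,
counting, abundance, cluster detection, pair correlation, proximity —
can be checked against ground truth rather than against another
implementation.

## Image model and calibration

Images are multi-channel rasters with square pixels
([CalibratedImage-class]): a `probe` channel (FISH probe fluorescence,
i.e. SRM), a `counterstain` channel (general DNA stain plus
autofluorescence: all bacteria including cyanobacteria and the SRM
themselves), and a `reflectance` channel (ooids and CaCO~3~
precipitates). The default calibration is the map standard used
throughout: a 512 × 512 px frame covering 682.67 × 682.67 µm, i.e.
1.33333 µm per pixel. All geometry is handled internally in micrometres
with the origin at the top-left corner, *x* rightward and *y* (depth)
downward; the mat surface lies near *y* = 0.

One consequence of the map calibration deserves emphasis: a ~1 µm
bacterium is *smaller than one pixel*. The generator therefore always
marks the pixel containing an object's centroid, and area-based
quantities at this calibration are pixel-quantized. Analyses that need
resolved cell footprints (e.g. the area-estimate accuracy checks) use a
finer pixel size, which `imageWindow()` makes explicit.

## The synthetic scene generator

`sceneSpec()` fixes the study conditions; `buildScene()` realizes them.

* **Type-1** (non-lithifying): SRM are completely spatially random (CSR)
  through the upper 500 µm (350 cells by default), cyanobacterial
  filaments occur near the surface, small precipitate patches are
  scattered, and the planted SRM share of total cell area inside the
  130 µm surface layer is **20.7%**.
* **Type-2** (lithifying): SRM follow a Thomas cluster process (parents
  at κ = 7 × 10⁻⁴ µm⁻² of layer area, a Poisson number of offspring with
  mean 12 per parent, isotropic Gaussian dispersion σ = 2 µm) confined
  to the 130 µm surface layer, with 8% of cells seeded deeper so that
  ~92% of SRM lie in the layer (the study condition is "over 85%"). A
  near-continuous crust of precipitate grains 30–50 µm thick underlies
  the surface, and the planted in-layer SRM area share is **88.0%**.
* **Microsphere fields**: flat calibration slides of 1.0 µm diameter
  spheres, used by the ground-truthing experiment.

Absolute cell densities are not published quantities; they were chosen
once on two grounds. First, Type-1 buffer-zone SRM density must keep the
10 µm concentric-region link graph *subcritical* (mean degree ≈ 0.3), so
that random scenes essentially never produce chains of more than five
linked cells — matching the observation of little-to-no Type-1
clustering. Second, Type-2 densities must produce the dense, almost
contiguous surface layer the lithifying state exhibits. The Thomas
parameters themselves are not published either; they are calibrated only
to reproduce the qualitative contrast (g(r) ≈ 1 versus strong small-r
clustering).

Three generator behaviours are deliberate design choices rather than
emulations of a published protocol:

* **Area-fraction calibration.** The planted SRM share is defined in
  *rasterized truth-mask area* — the same units the analysis measures.
  Other (non-SRM) bacteria are added one at a time until the in-layer
  mask-area ratio reaches the target. A count-based calibration would
  not reproduce an area-based percentage at the map calibration, because
  clustered sub-pixel cells share pixels.
* **Near-precipitate SRM.** A configurable fraction of layer SRM is
  relocated to within ~0.2–2.2 µm of a precipitate grain, producing the
  strong SRM enrichment observed near precipitates. In Type-1 scenes
  each relocated cell anchors to a grain of a *distinct* patch, so the
  relocation enriches proximity without creating same-patch cell pairs —
  the pattern stays CSR-like, which is exactly the published Type-1
  phenotype (random arrangement *and* precipitate association).
* **Filament budget.** Filaments whose in-layer area would make the
  planted SRM share unattainable are placed below the analysis layer
  before calibration. In Type-2 this is also the ecology: the
  cyanobacterial layer underlies the surface SRM/crust layer.

### Rendering and the noise model

`renderScene()` composites objects at unit amplitude (maximum-intensity)
into their channels, blurs with a Gaussian of σ = 0.35 px, adds a
constant background (0.05), and applies **shot-noise-like Gaussian
noise**: the standard deviation at a pixel is its mean intensity divided
by `snr` (default 10). A unit-amplitude object therefore carries noise
sd 0.1 while the dark background stays comparatively quiet, as in
photon-limited fluorescence imaging. A purely additive noise floor of
sd 0.1 everywhere would be unrealistic for confocal data and, more
importantly, makes any two-class intensity segmentation of sparse
sub-pixel objects impossible in principle (the foreground is ~0.2% of
pixels; every balanced intensity split then lands inside the background
mode). A stated fraction of objects (10% by default) is rendered at a
dimming factor (0.4), emulating items below the focal plane; as in real
classification practice, some of these fall below threshold and are
counted as background. Intensities saturate at 1 (detector range), and a
fixed seed reproduces scenes and renders bit-identically.

## Classification

`classifySupervised()` is a minimum-distance-to-class-means classifier
in channel space, the smallest supervised model consistent with
"training pixels per feature": deterministic, scale-invariant, and exact
on noiseless renders. Background is an ordinary trained class, so
sub-threshold pixels lose to it rather than being thresholded ad hoc.

`classifyTwoClass()` is the iterative two-class intensity clustering
used for microsphere fields: centres initialized at the intensity
extremes (Isodata-style; a quantile initialization provably collapses
onto the background mode when bright objects are sparse), pixels
reassigned to the nearer centre, stopping at 20 iterations or when 95%
of pixels are stable — the published protocol's two constants. On a
balanced two-Gaussian mixture its threshold converges to the midpoint,
i.e. the Bayes rule for equal variances.

`subtractFilaments()` recognizes cyanobacteria by shape, since their
fluorescence signature is inseparable from other bacteria: fragments are
grouped by dilation with a disk of radius `maxGapUm/2` (bridging breaks,
so discontinuous filaments are identified), and a group is a filament
when its principal-axis extent is ≥ 10 µm with elongation ≥ 5. The
extent measure is exact for straight and dashed filaments (what the
generator plants) and underestimates strongly curved ones — a skeleton
length would handle those, at the cost of a hand-rolled skeletonizer.
The filament/residual masks partition the input exactly, mirroring the
change-detection subtraction.

`colocalize()` implements probe/counterstain gating: a probe object is
accepted as SRM when at least half of its area (default) also carries
the counterstain signature, and accepted objects are kept whole.

`segmentAndCount()` applies the counting rule for partial objects:
8-connected components of at least half the typical object area that do
not touch the border count one each; border-touching and sub-size
fragments are pooled and their summed area divided by the typical
object area, rounded to an integer — so two half-cells cut at opposite
borders sum to one. A border component at least as large as a whole
object counts as full-size, which keeps the rule from ever exceeding
the naive component count.

## Microspatial statistics

**Buffer zone.** `bufferZone()` spans, per image column, from the
surface line down 133 µm — exactly 100 map pixels at the default
calibration (the same quantity that is often quoted rounded to 130 µm).
`detectSurface()` takes the topmost foreground pixel per column,
median-smooths, and interpolates empty columns; on sparse scenes the
interpolation error is material, so truth-based analyses use the
generator's own surface line (`trueSurface()`).

**Abundance.** `areaFractionSRM()` is an area-based measure: 100 × (SRM
area in zone) / (union of SRM, other-bacteria and filament area in
zone). A zone without any cell area yields `NA`, not 0.

**Clusters.** `detectClusters()` reproduces the buffer-dissolve
workflow: a 10 µm diameter concentric region around each cell, links
where regions overlap (centroid distance strictly below the diameter),
clusters as connected components, and *selection* of clusters with
strictly more than five members. Cluster area is the dissolved union of
the member disks, measured on a 0.2 µm raster (resolution configurable);
the summed cell-footprint area is recorded alongside when radii are
known.

**Pair correlation.** `pairCorrelation()` estimates g(r) by ring
counting with translation edge correction
c~ij~ = (W−|dx|)(H−|dy|)/(WH), on the grid 0.1–6.44 µm (step 0.1, ring
width 0.25 µm). The ring denominator is the exact annulus area
π((r+w/2)² − max(0, r−w/2)²), which equals 2πrw everywhere except the
first grid radius, where the conventional form would bias the estimate
upward on a truncated ring. Envelopes are pointwise min/max over CSR
resimulations with matched counts. Values near 1 indicate randomness,
above 1 clustering, below 1 avoidance.

Two numerical caveats shape how curves should be read. First, for
sparse patterns a ring that contains a single pair produces a very
large spike (the estimator is unbiased but heavy-tailed); summaries over
many radii and replicates are stable, individual radii are not. Second,
g(r) assumes a homogeneous pattern over its window: buffer-zone cells
live in a band, so `bufferZonePoints()` converts them to (x, depth)
coordinates with a window matching the band. Against the full square
window, the band restriction itself would read as ~5× clustering.

**Mat-type signature.** `matTypeSignature()` bundles the three
discriminating measurements (buffer-zone SRM share, selected-cluster
count, small-distance pair-correlation exceedance). The exceedance
compares the integral of g(r) over 1–3 µm with the integral of the
pointwise envelope roof. The lower limit excludes sub-cell-diameter
radii, where a single touching pair of ~1 µm cells dominates the
integral without carrying arrangement information; the comparison
against the integrated roof (rather than any pointwise crossing) gives
the decision a margin of several-fold in both directions. A pointwise
α-level envelope test cannot make this discrimination reliably, because
a CSR scene is exchangeable with its own null simulations and will
cross a pointwise envelope at rate α somewhere on the grid.

**Proximity.** `proximityFractions()` computes the exact Euclidean
distance transform from the precipitate mask and asks, per threshold
(1.1, 2.2, 4.4 µm by default — the published doubling series, taken as
authoritative over the equivalent pixel radii), what percentage of
near-precipitate bacteria are SRM. Cells are near when their minimum
pixel distance is within the threshold; thresholds with no near
bacteria are flagged undefined rather than reported as 0.

**Vertical distribution.** `verticalProfile()` bins cell depths below
the per-column surface (10 µm bins, top 500 µm by default) and reports
per-bin and cumulative fractions; `topLayerFraction()` is the cumulative
share within a stated depth, e.g. the top-130 µm share that separates
the two mat types.

## Microsphere ground-truthing

`makeMicrosphereSeries()` emulates the calibration experiment: five
serial dilutions c, c/2, c/4, c/8, c/16 with five replicate fields each
and Poisson per-field counts. `calibrateSeries()` runs every field
through two-class classification, the counting rule, and the
area-derived estimate (total foreground area over the area of one 1.0 µm
sphere), then reports the three Pearson associations: area vs known,
direct vs known, area vs direct. Area-derived counts are deliberately
real-valued and labelled *relative* estimates — areas from complex
matrices support relative, not absolute, abundances. Associations with
the *known* concentration are bounded by the Poisson field-to-field
sampling itself (r_max = sqrt(V/(V+mean)) over the dilution design),
which is worth remembering when judging them against the
area-vs-direct association.

## Group statistics

`compareGroups()` uses a Welch t-test for two groups (the unequal-
variance form, chosen deliberately where the published analysis says
only "t-test") and one-way ANOVA with Bonferroni and Scheffé pairwise
decisions at α = 0.05 for more. Percent data can be arcsine-square-root
transformed (the default recommendation for the abundance percentages;
configurable) and positive data log-transformed; group means and
standard errors are always reported on the original scale. The Scheffé
decision uses the standard criterion F_pair > (k−1)·F_{α,k−1,N−k} on the
pooled mean square. `pearsonCor()` provides the product-moment
correlation with its t-distributed p-value on n−2 degrees of freedom.
The Welch p-value is only asymptotically uniform under the null; at very
small group sizes strict uniformity checks fail by construction, which
is a property of the approximation, not a defect.

## A worked contrast

```{r, fig.alt = "Pair correlation of type-2 buffer-zone SRM with CSR envelope"}
type2 <- buildScene(sceneSpec("type2", seed = 42))
sig2 <- matTypeSignature(type2, seed = 1)
type1 <- buildScene(sceneSpec("type1", seed = 42))
sig1 <- matTypeSignature(type1, seed = 1)

round(c(type1 = sig1$srmAreaFraction, type2 = sig2$srmAreaFraction), 1)
c(type1 = sig1$nSelectedClusters, type2 = sig2$nSelectedClusters)
c(type1 = sig1$exceeds, type2 = sig2$exceeds)
plot(sig2$pcf, main = "Type-2 buffer-zone SRM vs CSR envelope")
```

## Problem sizes and determinism

The package's own validation uses desk-scale problem sizes chosen once:
20 replicate scenes per mat type for parameter recovery; 20 CSR patterns
of 300 points for the pair-correlation calibration; 19–39 envelope
simulations; a dilution series of 25 fields at base count 200; 2000
replicates for the type-I-error calibration; 30 replicates for the
Thomas closed-form comparison. Every stochastic routine takes an
explicit seed, and fixed seeds reproduce scenes, renders and envelopes
bit-identically.

## What passing tests do and do not show

The generator emulates the *statistical structure* the analysis assumes:
disk-shaped cells with a narrow size distribution, flat-or-sinusoidal
surfaces, class-pure channels, isotropic Gaussian blur, shot-noise-like
intensity noise, and cleanly separable mineral signal. Real micrographs
violate most of these at some rate: EPS autofluorescence, spectral
bleed-through, out-of-focus light from a 3D community, touching and
overlapping cells, irregular cell shapes, and surfaces defined by gel
rather than by objects. Recovery of planted parameters here therefore
validates the *computational pipeline* — that the estimators measure
what they claim on data satisfying their assumptions — and not the
field accuracy of FISH quantification. Known limitations: no 3D point
statistics (cross-sections are treated as 2D), no optical PSF model, no
spectral unmixing, filament length via principal-axis extent, and
cluster areas measured on a finite dissolve raster.
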