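## S4 class definitions. Conventions used throughout the package:
##  - all physical geometry is in micrometres (um); rasters are base R
##    matrices indexed [row = y (depth, downward), col = x (rightward)],
##    with the centre of pixel (i, j) at ((j - 0.5) * px, (i - 0.5) * px);
##  - the mat surface lies near y = 0 and depth increases downward.

#' Physical observation window of an image
#'
#' Describes the physical extent and square-pixel calibration of a raster
#' field of view. The default constructor [imageWindow()] reproduces the
#' standard map calibration of a 512 x 512 pixel confocal frame spanning
#' 682.67 x 682.67 um (1.33333 um per pixel).
#'
#' @slot widthUm,heightUm physical extent in micrometres.
#' @slot pixelSizeUm edge length of the square pixels, micrometres.
#' @exportClass Window
setClass("Window", representation(
  widthUm = "numeric", heightUm = "numeric", pixelSizeUm = "numeric"
))

setValidity("Window", function(object) {
  msg <- character()
  if (length(object@pixelSizeUm) != 1 || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (any(!is.finite(c(object@widthUm, object@heightUm))) ||
      object@widthUm <= 0 || object@heightUm <= 0)
    msg <- c(msg, "window extent must be positive")
  if (length(msg)) msg else TRUE
})

#' Specification of a planar point process
#'
#' Either complete spatial randomness (CSR; homogeneous Poisson, optionally
#' with the total count held fixed) or a Thomas cluster process (Poisson
#' parents, Poisson numbers of Gaussian-displaced offspring).
#'
#' @slot kind `"csr"` or `"thomas"`.
#' @slot nPoints fixed CSR count (`NA` to draw from `intensity`).
#' @slot intensity CSR intensity, points per um^2 (`NA` if `nPoints` fixed).
#' @slot kappa Thomas parent intensity, parents per um^2.
#' @slot mu Thomas mean offspring per parent.
#' @slot sigmaUm Thomas isotropic Gaussian offspring dispersion, um.
#' @slot window a [Window-class].
#' @slot seed integer seed; a fixed seed yields an identical pattern.
#' @exportClass PointPatternSpec
setClass("PointPatternSpec", representation(
  kind = "character", nPoints = "numeric", intensity = "numeric",
  kappa = "numeric", mu = "numeric", sigmaUm = "numeric",
  window = "Window", seed = "numeric"
))

setValidity("PointPatternSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("csr", "thomas"))
    msg <- c(msg, "kind must be 'csr' or 'thomas'")
  if (object@kind == "csr") {
    if (is.na(object@nPoints) && is.na(object@intensity))
      msg <- c(msg, "csr needs nPoints or intensity")
    if (!is.na(object@nPoints) && (object@nPoints < 0 ||
        object@nPoints != round(object@nPoints)))
      msg <- c(msg, "nPoints must be a non-negative integer")
    if (!is.na(object@intensity) && object@intensity <= 0)
      msg <- c(msg, "intensity must be positive")
  } else {
    if (is.na(object@kappa) || object@kappa <= 0)
      msg <- c(msg, "kappa must be positive")
    if (is.na(object@mu) || object@mu <= 0)
      msg <- c(msg, "mu must be positive")
    if (is.na(object@sigmaUm) || object@sigmaUm <= 0)
      msg <- c(msg, "sigmaUm must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Generative specification of a synthetic mat scene
#'
#' Holds every parameter of the ground-truthed scene generator: mat type
#' (`"type1"` non-lithifying, `"type2"` lithifying, or `"microsphere"`
#' calibration field), target SRM area fraction, SRM surface-layer depth,
#' crust geometry, cell-size distribution, filament/precipitate/ooid
#' abundances, surface profile, and the rendering noise model. See
#' [sceneSpec()] for defaults and units.
#'
#' @exportClass SceneSpec
setClass("SceneSpec", representation(
  matType = "character", window = "Window",
  srmAreaFractionTarget = "numeric", srmLayerDepthUm = "numeric",
  srmDeepFraction = "numeric", crustDepthRangeUm = "numeric",
  cellRadiusMeanUm = "numeric", cellRadiusSdUm = "numeric",
  nSrm = "numeric", thomasKappa = "numeric", thomasMu = "numeric",
  thomasSigmaUm = "numeric", maxDepthUm = "numeric",
  nFilaments = "numeric", filamentLengthUm = "numeric",
  filamentWidthPx = "numeric", filamentGapFraction = "numeric",
  nPrecipPatches = "numeric", precipPatchRadiusUm = "numeric",
  nOoids = "numeric", ooidRadiusRangeUm = "numeric",
  nSpheres = "numeric", srmNearPrecipFraction = "numeric",
  surfaceProfile = "list", noise = "list", seed = "numeric"
))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (!object@matType %in% c("type1", "type2", "microsphere"))
    msg <- c(msg, "matType must be 'type1', 'type2' or 'microsphere'")
  if (!is.na(object@srmAreaFractionTarget) &&
      (object@srmAreaFractionTarget < 0 || object@srmAreaFractionTarget > 100))
    msg <- c(msg, "srmAreaFractionTarget must lie in [0, 100] percent")
  dens <- c(object@nSrm, object@nFilaments, object@nPrecipPatches,
            object@nOoids, object@nSpheres)
  if (any(dens[!is.na(dens)] < 0))
    msg <- c(msg, "object counts must be non-negative")
  if (object@srmNearPrecipFraction < 0 || object@srmNearPrecipFraction > 1)
    msg <- c(msg, "srmNearPrecipFraction must lie in [0, 1]")
  cr <- object@crustDepthRangeUm
  if (length(cr) != 2 || any(cr < 0) || cr[1] > cr[2])
    msg <- c(msg, "crustDepthRangeUm must be an ordered non-negative pair")
  if (length(msg)) msg else TRUE
})

#' Ground-truthed synthetic scene
#'
#' The full generative truth for one simulated field: per-object records,
#' filament polylines, noiseless per-class truth masks, and the true mat
#' surface line.
#'
#' @slot spec the [SceneSpec-class] that produced the scene.
#' @slot objects data.frame of disk-like objects: `class` (one of `srm`,
#'   `other`, `precipitate`, `ooid`, `microsphere`), `xUm`, `yUm`,
#'   `radiusUm`, `dimmed` (rendered below the focal plane), and `patch`
#'   (precipitate patch id, `NA` elsewhere).
#' @slot filaments list of data.frames of polyline vertices (`xUm`, `yUm`)
#'   for cyanobacterial filaments, with attributes `widthPx` and `dimmed`.
#' @slot masks named list of logical truth rasters, one per class
#'   (`srm`, `other`, `filament`, `precipitate`, `ooid`, `microsphere`).
#' @slot surfaceUm true surface depth (um) for each pixel column.
#' @slot window the scene [Window-class].
#' @exportClass GroundTruthScene
setClass("GroundTruthScene", representation(
  spec = "SceneSpec", objects = "data.frame", filaments = "list",
  masks = "list", surfaceUm = "numeric", window = "Window"
))

setValidity("GroundTruthScene", function(object) {
  msg <- character()
  if (nrow(object@objects)) {
    w <- object@window
    ok <- object@objects$xUm >= 0 & object@objects$xUm <= w@widthUm &
      object@objects$yUm >= 0 & object@objects$yUm <= w@heightUm
    if (!all(ok)) msg <- c(msg, "all object centroids must lie in the window")
    if (anyNA(object@objects$class))
      msg <- c(msg, "every object must carry a class")
  }
  shp <- unique(lapply(object@masks, dim))
  if (length(shp) > 1) msg <- c(msg, "truth masks must share one shape")
  if (length(msg)) msg else TRUE
})

#' Calibrated multi-channel raster image
#'
#' A confocal-style field with named channels (`probe` = FISH probe
#' fluorescence, `counterstain` = general DNA stain / autofluorescence,
#' `reflectance` = mineral reflectance) and a physical pixel size.
#'
#' @slot channels named list of numeric matrices, identical shape.
#' @slot pixelSizeUm pixel edge length, micrometres.
#' @exportClass CalibratedImage
setClass("CalibratedImage", representation(
  channels = "list", pixelSizeUm = "numeric"
))

setValidity("CalibratedImage", function(object) {
  msg <- character()
  if (!length(object@channels) || is.null(names(object@channels)) ||
      any(!nzchar(names(object@channels))))
    msg <- c(msg, "channels must be a non-empty named list")
  shp <- unique(lapply(object@channels, dim))
  if (length(shp) > 1) msg <- c(msg, "channels must share one shape")
  vals <- unlist(lapply(object@channels, range), use.names = FALSE)
  if (any(!is.finite(vals)) || any(vals < 0))
    msg <- c(msg, "intensities must be finite and non-negative")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-column mat surface line
#'
#' @slot rowPx topmost foreground row index (1-based, may be fractional
#'   after smoothing/interpolation), one value per image column.
#' @slot smoothWindowPx width of the running-median smoother applied.
#' @slot nRow image height in pixels, for range checking.
#' @exportClass SurfaceLine
setClass("SurfaceLine", representation(
  rowPx = "numeric", smoothWindowPx = "numeric", nRow = "numeric"
))

setValidity("SurfaceLine", function(object) {
  msg <- character()
  if (anyNA(object@rowPx))
    msg <- c(msg, "surface must be defined (interpolated) for every column")
  if (length(object@rowPx) &&
      (min(object@rowPx) < 1 || max(object@rowPx) > object@nRow))
    msg <- c(msg, "surface rows must lie within the image")
  if (length(msg)) msg else TRUE
})

#' Per-class binary masks of a classified image
#'
#' @slot masks named list of logical matrices (typically `srm`, `other`,
#'   `filament`, `precipitate`, `background`), identical shape.
#' @slot pixelSizeUm pixel size, micrometres.
#' @exportClass ClassMasks
setClass("ClassMasks", representation(
  masks = "list", pixelSizeUm = "numeric"
))

setValidity("ClassMasks", function(object) {
  msg <- character()
  shp <- unique(lapply(object@masks, dim))
  if (length(shp) > 1) msg <- c(msg, "masks must share one shape")
  if (!is.null(object@masks$srm) && !is.null(object@masks$background) &&
      any(object@masks$srm & object@masks$background))
    msg <- c(msg, "srm and background masks must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Labelled objects of a binary mask, with counting-rule count
#'
#' @slot labels integer raster of 8-connected component labels (0 = background).
#' @slot table per-object data.frame: `label`, `areaUm2`, `xUm`, `yUm`,
#'   `borderFlag`, `fullSize`.
#' @slot count counting-rule object count (full-size components counted
#'   individually; border/sub-size fragments pooled by area).
#' @slot typicalObjectAreaUm2 reference area of one whole object.
#' @slot pixelSizeUm pixel size, micrometres.
#' @exportClass LabeledObjects
setClass("LabeledObjects", representation(
  labels = "matrix", table = "data.frame", count = "numeric",
  typicalObjectAreaUm2 = "numeric", pixelSizeUm = "numeric"
))

setValidity("LabeledObjects", function(object) {
  msg <- character()
  n <- nrow(object@table)
  if (n && !identical(sort(object@table$label), seq_len(n)))
    msg <- c(msg, "labels must be contiguous positive integers")
  if (n && any(object@table$areaUm2 <= 0))
    msg <- c(msg, "object areas must be positive")
  if (length(msg)) msg else TRUE
})

#' Buffer-dissolve cluster set
#'
#' Clusters of cells whose concentric regions (disks of a fixed diameter
#' centred on each cell) overlap; connected chains of overlaps form one
#' cluster, and a cluster is *selected* when it holds strictly more than
#' `minCells` members.
#'
#' @slot points the analysed cell centroids (`xUm`, `yUm`).
#' @slot membership cluster id per cell (every cell belongs to exactly one).
#' @slot clusters per-cluster data.frame: `cluster`, `nCells`, `areaUm2`
#'   (dissolved union of the concentric disks), `footprintAreaUm2` (sum of
#'   member cell footprints, when radii were supplied), `xUm`, `yUm`
#'   (centroid of members), `selected`.
#' @slot regionDiameterUm,minCells the detection parameters.
#' @exportClass ClusterSet
setClass("ClusterSet", representation(
  points = "data.frame", membership = "integer", clusters = "data.frame",
  regionDiameterUm = "numeric", minCells = "numeric"
))

setValidity("ClusterSet", function(object) {
  msg <- character()
  if (length(object@membership) != nrow(object@points))
    msg <- c(msg, "each cell must belong to exactly one cluster")
  if (nrow(object@clusters) &&
      sum(object@clusters$nCells) != nrow(object@points))
    msg <- c(msg, "cluster sizes must partition the cells")
  if (length(msg)) msg else TRUE
})

#' Pair correlation curve with optional CSR envelope
#'
#' @slot r radial grid, micrometres (strictly increasing, positive).
#' @slot g estimates of the pair (cross-)correlation on the grid; `NA`
#'   where a ring admits no pairs.
#' @slot ringWidthUm width of the distance rings.
#' @slot edgeCorrection `"translation"` or `"none"`.
#' @slot envelope two-row matrix (`lo`, `hi`) of the pointwise min/max of
#'   the estimator over CSR resimulations, or a 0-row matrix when no
#'   envelope was requested.
#' @slot envelopeSims number of CSR simulations behind the envelope.
#' @slot nA,nB sizes of the two point sets (equal for auto-correlation).
#' @exportClass PairCorrelationCurve
setClass("PairCorrelationCurve", representation(
  r = "numeric", g = "numeric", ringWidthUm = "numeric",
  edgeCorrection = "character", envelope = "matrix",
  envelopeSims = "numeric", nA = "numeric", nB = "numeric"
))

setValidity("PairCorrelationCurve", function(object) {
  msg <- character()
  if (any(object@r <= 0) || is.unsorted(object@r, strictly = TRUE))
    msg <- c(msg, "r must be strictly increasing and positive")
  if (any(object@g[!is.na(object@g)] < 0))
    msg <- c(msg, "g estimates must be non-negative")
  if (nrow(object@envelope) == 2 &&
      any(object@envelope[1, ] > object@envelope[2, ], na.rm = TRUE))
    msg <- c(msg, "envelope bounds must be ordered")
  if (length(msg)) msg else TRUE
})

#' SRM-precipitate proximity fractions
#'
#' @slot table one row per distance threshold: `thresholdUm`, `srmNear`,
#'   `otherNear`, `percentSrm` (`NA` when no bacteria are near at that
#'   threshold), `defined`.
#' @slot pixelSizeUm pixel size, micrometres.
#' @exportClass ProximityResult
setClass("ProximityResult", representation(
  table = "data.frame", pixelSizeUm = "numeric"
))

setValidity("ProximityResult", function(object) {
  tb <- object@table
  msg <- character()
  p <- tb$percentSrm[!is.na(tb$percentSrm)]
  if (any(p < 0 | p > 100)) msg <- c(msg, "percents must lie in [0, 100]")
  if (nrow(tb) > 1 && !is.unsorted(tb$thresholdUm) &&
      (is.unsorted(tb$srmNear, na.rm = TRUE) ||
       is.unsorted(tb$otherNear, na.rm = TRUE)))
    msg <- c(msg, "near counts must be non-decreasing in threshold")
  if (length(msg)) msg else TRUE
})

#' Microsphere calibration result
#'
#' @slot table per-image records: `image`, `dilution`, `knownCount`,
#'   `directCount`, `areaUm2`, `areaCount` (area-derived *relative*
#'   abundance estimate).
#' @slot correlations data.frame of the three Pearson associations
#'   (`area_vs_known`, `direct_vs_known`, `area_vs_direct`): `r`, `p`,
#'   `degenerate`.
#' @slot unitObjectAreaUm2 area of one whole reference object.
#' @exportClass CalibrationResult
setClass("CalibrationResult", representation(
  table = "data.frame", correlations = "data.frame",
  unitObjectAreaUm2 = "numeric"
))

setValidity("CalibrationResult", function(object) {
  r <- object@correlations$r
  ok <- all(abs(r[!is.na(r)]) <= 1 + 1e-12)
  if (ok) TRUE else "correlations must lie in [-1, 1]"
})

#' Group comparison result
#'
#' Welch two-sample t-test or one-way ANOVA with Bonferroni and Scheffe
#' post-hoc decisions, computed on optionally transformed values while
#' group summaries stay on the original scale.
#'
#' @slot design `"two-group"` or `"multi-group"`.
#' @slot transform `"none"`, `"arcsine-sqrt"` or `"log"`.
#' @slot groups data.frame: `group`, `n`, `mean`, `se` (original scale).
#' @slot statistic t or F statistic.
#' @slot df degrees of freedom (length 1 for t, 2 for F).
#' @slot pValue two-sided p-value of the omnibus test.
#' @slot postHoc pairwise decisions (multi-group only): `group1`, `group2`,
#'   `pBonferroni`, `rejectBonferroni`, `rejectScheffe`.
#' @slot alpha significance level used for decisions.
#' @exportClass GroupComparison
setClass("GroupComparison", representation(
  design = "character", transform = "character", groups = "data.frame",
  statistic = "numeric", df = "numeric", pValue = "numeric",
  postHoc = "data.frame", alpha = "numeric"
))

setValidity("GroupComparison", function(object) {
  msg <- character()
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "p must lie in [0, 1]")
  if (any(object@groups$n < 2))
    msg <- c(msg, "each group needs n >= 2")
  if (length(msg)) msg else TRUE
})
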