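#' Buffer-zone coordinates of scene cells
#'
#' Extracts the cells of one class, converts them to (x, depth-below-
#' surface) band coordinates, and keeps those within `depthUm` of the
#' surface. Buffer-zone point patterns are analysed in band coordinates
#' so that the complete-spatial-randomness null is homogeneous over the
#' band window (`width x depthUm`); against the full image window the
#' zone restriction itself would masquerade as clustering.
#'
#' @param scene a [GroundTruthScene-class].
#' @param class object class to extract (default `"srm"`).
#' @param surface a [SurfaceLine-class]; defaults to the scene's true
#'   surface.
#' @param depthUm buffer depth, micrometres.
#' @return list with `points` (data.frame `xUm`, `yUm` = depth) and
#'   `window` (the band [Window-class]).
#' @export
bufferZonePoints <- function(scene, class = "srm",
                             surface = trueSurface(scene),
                             depthUm = 133) {
  stopifnot(is(scene, "GroundTruthScene"))
  px <- pixelSize(scene)
  o <- sceneObjects(scene)
  o <- o[o$class == class, ]
  top <- surfaceRow(surface)
  col <- .pixOfX(o$xUm, px, length(top))
  depth <- o$yUm - (top[col] - 0.5) * px
  keep <- depth >= 0 & depth <= depthUm
  list(points = data.frame(xUm = o$xUm[keep], yUm = depth[keep]),
       window = imageWindow(scene@window@widthUm, depthUm, px))
}

#' Microspatial signature of a mat scene
#'
#' Runs the three discriminating measurements of the buffer-zone
#' analysis on a ground-truthed scene:
#'
#' 1. the SRM percent of total cell area in the buffer zone
#'    ([areaFractionSRM()]);
#' 2. the number of selected clusters (strictly more than `minCells`
#'    members) among buffer-zone SRM ([detectClusters()]);
#' 3. a small-distance pair-correlation exceedance: the integral of
#'    \eqn{\hat g(r)} over `exceedRangeUm` compared against the integral
#'    of the pointwise upper CSR envelope from `envelopeSims`
#'    simulations in the band window. The lower bound of the default
#'    range (1 um) excludes sub-cell-diameter radii, where a single
#'    touching pair of ~1 um cells dominates the estimate without
#'    carrying arrangement information.
#'
#' Lithifying (type-2) scenes show a high SRM fraction, selected
#' clusters, and an exceedance; non-lithifying (type-1) scenes show a
#' low fraction, no selected clusters, and containment.
#'
#' @param scene a [GroundTruthScene-class].
#' @param depthUm buffer depth, micrometres.
#' @param regionDiameterUm,minCells cluster-detection parameters.
#' @param envelopeSims CSR simulations for the envelope.
#' @param exceedRangeUm radial range of the exceedance integral.
#' @param seed integer seed for the envelope.
#' @return list: `srmAreaFraction`, `nSelectedClusters`, `clusters`
#'   (the [ClusterSet-class]), `pcf` (the [PairCorrelationCurve-class]),
#'   `gIntegral`, `envIntegral`, `exceeds`.
#' @export
matTypeSignature <- function(scene, depthUm = 133, regionDiameterUm = 10,
                             minCells = 5, envelopeSims = 19,
                             exceedRangeUm = c(1, 3), seed = 1L) {
  stopifnot(is(scene, "GroundTruthScene"))
  px <- pixelSize(scene)
  sf <- trueSurface(scene)
  zone <- bufferZone(sf, depthUm, px)
  cm <- classMasks(truthMasks(scene)[c("srm", "other", "filament")], px)
  frac <- areaFractionSRM(cm, zone)
  bp <- bufferZonePoints(scene, "srm", sf, depthUm)
  cl <- detectClusters(bp$points, regionDiameterUm, minCells)
  pc <- pairCorrelation(bp$points, window = bp$window,
                        envelopeSims = envelopeSims, seed = seed)
  tb <- pcfTable(pc)
  sel <- tb$rUm >= exceedRangeUm[1] & tb$rUm <= exceedRangeUm[2]
  gInt <- sum(tb$g[sel], na.rm = TRUE)
  eInt <- sum(tb$envHi[sel], na.rm = TRUE)
  list(srmAreaFraction = frac,
       nSelectedClusters = sum(clusterTable(cl)$selected),
       clusters = cl, pcf = pc,
       gIntegral = gInt, envIntegral = eInt,
       exceeds = gInt > eInt)
}
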