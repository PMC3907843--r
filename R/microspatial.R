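#' Buffer zone below the mat surface
#'
#' Builds the binary region spanning, per image column, from the surface
#' line down a fixed depth. The default depth of 133 um equals 100 map
#' pixels at the 1.33333 um/px calibration (commonly reported rounded to
#' 130 um); the zone is clipped at the image bottom.
#'
#' @param surface a [SurfaceLine-class].
#' @param depthUm zone depth below the surface, micrometres.
#' @param pixelSizeUm pixel size, micrometres.
#' @param nCol image width in pixels (defaults to the surface length).
#' @return logical zone mask.
#' @export
bufferZone <- function(surface, depthUm = 133, pixelSizeUm = 682.67 / 512,
                       nCol = length(surfaceRow(surface))) {
  stopifnot(is(surface, "SurfaceLine"), depthUm > 0)
  depthPx <- round(depthUm / pixelSizeUm)
  top <- surfaceRow(surface)
  nr <- surface@nRow
  rows <- matrix(seq_len(nr), nr, nCol)
  topM <- matrix(round(top), nr, nCol, byrow = TRUE)
  rows >= topM & rows <= pmin(topM + depthPx - 1L, nr)
}

#' SRM share of total cell area within a zone
#'
#' 100 x (SRM area inside the zone) / (total cell area inside the zone),
#' with total cell area the union of the SRM, other-bacteria and filament
#' masks. Abundance is thus an area-based ("fluorescence area") measure,
#' not a cell count.
#'
#' @param masks a [ClassMasks-class] with masks `srm`, `other` and
#'   optionally `filament`.
#' @param zone logical zone mask of the same shape.
#' @return percent in `[0, 100]`, or `NA` (with a warning) when the zone
#'   contains no cell area at all.
#' @export
areaFractionSRM <- function(masks, zone) {
  stopifnot(is(masks, "ClassMasks"))
  zone <- .asBinary(zone)
  srm <- getMask(masks, "srm")
  stopifnot(identical(dim(srm), dim(zone)))
  total <- srm
  for (nm in intersect(c("other", "filament"), names(maskList(masks))))
    total <- total | getMask(masks, nm)
  denom <- sum(total & zone)
  if (denom == 0) {
    warning("no cell area inside the zone: SRM fraction undefined")
    return(NA_real_)
  }
  100 * sum(srm & zone) / denom
}

#' Vertical depth profile of cells below the surface
#'
#' Bins cell depths below the per-column surface line and reports per-bin
#' and cumulative fractions; cells deeper than `maxDepthUm` are excluded
#' from the denominator.
#'
#' @param cells data.frame with `xUm`, `yUm` (um coordinates).
#' @param surface a [SurfaceLine-class].
#' @param pixelSizeUm pixel size, micrometres.
#' @param binUm bin width, micrometres.
#' @param maxDepthUm maximum depth considered.
#' @return data.frame: `depthLo`, `depthHi`, `n`, `fraction`,
#'   `cumulative`.
#' @export
verticalProfile <- function(cells, surface, pixelSizeUm, binUm = 10,
                            maxDepthUm = 500) {
  stopifnot(binUm > 0)
  top <- surfaceRow(surface)
  col <- .pixOfX(cells$xUm, pixelSizeUm, length(top))
  surfUm <- (top[col] - 0.5) * pixelSizeUm
  depth <- cells$yUm - surfUm
  depth <- depth[depth >= 0 & depth <= maxDepthUm]
  if (!length(depth))
    stop("no cells above maxDepthUm: profile undefined")
  breaks <- seq(0, maxDepthUm + binUm, by = binUm)
  n <- tabulate(findInterval(depth, breaks), nbins = length(breaks) - 1)
  data.frame(depthLo = head(breaks, -1), depthHi = breaks[-1],
             n = n, fraction = n / sum(n),
             cumulative = cumsum(n) / sum(n))
}

#' Fraction of cells within a given depth of the surface
#'
#' Convenience wrapper around [verticalProfile()]: the cumulative fraction
#' of cells (above `maxDepthUm`) lying within `topDepthUm` of the surface.
#'
#' @inheritParams verticalProfile
#' @param topDepthUm the surface-layer depth of interest.
#' @export
topLayerFraction <- function(cells, surface, pixelSizeUm,
                             topDepthUm = 130, maxDepthUm = 500) {
  prof <- verticalProfile(cells, surface, pixelSizeUm,
                          binUm = topDepthUm / 13, maxDepthUm = maxDepthUm)
  sum(prof$fraction[prof$depthHi <= topDepthUm + 1e-9])
}
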