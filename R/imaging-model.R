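#' Create an observation window
#'
#' Defaults reproduce the standard map calibration used throughout: a
#' 512 x 512 pixel frame covering 682.67 x 682.67 um, i.e. 682.67/512 =
#' 1.33333 um per pixel.
#'
#' @param widthUm,heightUm physical extent, micrometres.
#' @param pixelSizeUm square pixel edge, micrometres.
#' @return a [Window-class].
#' @examples
#' w <- imageWindow()
#' windowDim(w)   # 512 512
#' @export
imageWindow <- function(widthUm = 682.67, heightUm = 682.67,
                        pixelSizeUm = 682.67 / 512) {
  new("Window", widthUm = widthUm, heightUm = heightUm,
      pixelSizeUm = pixelSizeUm)
}

#' Assemble a calibrated multi-channel image
#'
#' @param channels named list of non-negative numeric matrices of one shape;
#'   conventional names are `probe`, `counterstain`, `reflectance`.
#' @param pixelSizeUm pixel size, micrometres.
#' @return a [CalibratedImage-class].
#' @export
calibratedImage <- function(channels, pixelSizeUm) {
  channels <- lapply(channels, function(ch) {
    if (is(ch, "Image")) ch <- EBImage::imageData(ch)
    storage.mode(ch) <- "double"
    ch
  })
  new("CalibratedImage", channels = channels, pixelSizeUm = pixelSizeUm)
}

#' Bundle per-class binary masks
#'
#' @param masks named list of logical matrices of one shape.
#' @param pixelSizeUm pixel size, micrometres.
#' @return a [ClassMasks-class].
#' @export
classMasks <- function(masks, pixelSizeUm) {
  new("ClassMasks", masks = lapply(masks, .asBinary),
      pixelSizeUm = pixelSizeUm)
}

#' True surface line of a synthetic scene
#'
#' Converts the generator's per-column surface depths into a
#' [SurfaceLine-class], for truth-based analyses that should not inherit
#' surface-detection error (sparse scenes can leave columns without
#' foreground, where [detectSurface()] must interpolate).
#'
#' @param scene a [GroundTruthScene-class].
#' @return a [SurfaceLine-class].
#' @export
trueSurface <- function(scene) {
  stopifnot(is(scene, "GroundTruthScene"))
  px <- scene@window@pixelSizeUm
  nr <- windowDim(scene@window)[1]
  rows <- pmin(pmax(scene@surfaceUm / px + 0.5, 1), nr)
  new("SurfaceLine", rowPx = rows, smoothWindowPx = 1, nRow = nr)
}

#' Delineate the mat surface in a foreground mask
#'
#' For every image column the topmost foreground pixel is taken as the
#' surface, the per-column values are smoothed with a running median, and
#' columns without any foreground are filled by linear interpolation from
#' the nearest defined columns (constant extrapolation at the ends). The
#' mask should be the union of all foreground classes (cells, precipitates,
#' ooids): non-lithifying surfaces are cell/EPS-bound while lithifying
#' surfaces are crust-bound.
#'
#' @param mask logical foreground matrix.
#' @param smoothWindowPx odd width of the running median (values are
#'   rounded up to the next odd integer); `1` disables smoothing.
#' @return a [SurfaceLine-class].
#' @export
detectSurface <- function(mask, smoothWindowPx = 5) {
  mask <- .asBinary(mask)
  if (!any(mask)) stop("mask is empty: no surface to detect")
  top <- apply(mask, 2, function(col) {
    w <- which(col)
    if (length(w)) w[1] else NA_real_
  })
  ok <- !is.na(top)
  if (!all(ok)) {
    idx <- seq_along(top)
    top <- stats::approx(idx[ok], top[ok], xout = idx, rule = 2)$y
  }
  k <- max(1L, as.integer(smoothWindowPx))
  if (k %% 2 == 0) k <- k + 1L
  if (k > 1 && length(top) >= k) top <- stats::runmed(top, k)
  new("SurfaceLine", rowPx = as.numeric(top), smoothWindowPx = k,
      nRow = nrow(mask))
}
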