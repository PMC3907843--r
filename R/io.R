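#' Image, mask, point-table and spec I/O
#'
#' Images travel as multi-page TIFF (one 32-bit float page per channel, in
#' the recorded channel order), binary masks as single-page TIFF, object
#' and result tables as CSV with micrometre coordinates at 4 decimals, and
#' scene specifications as YAML.
#'
#' @param image a [CalibratedImage-class].
#' @param path file path.
#' @param pixelSizeUm pixel size of the image on disk (TIFF pages do not
#'   carry the map calibration).
#' @param channelNames channel names, in page order.
#' @name imageIO
NULL

#' @rdname imageIO
#' @export
writeCalibratedImage <- function(image, path) {
  stopifnot(is(image, "CalibratedImage"))
  ## TIFF float pages are defined on [0, 1]; rendered images already are,
  ## foreign data is clamped
  pages <- lapply(image@channels, function(ch) pmin(pmax(ch, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname imageIO
#' @export
readCalibratedImage <- function(path, pixelSizeUm = 682.67 / 512,
                                channelNames = c("probe", "counterstain",
                                                 "reflectance")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(channelNames) != length(pages))
    channelNames <- paste0("channel", seq_along(pages))
  names(pages) <- channelNames
  calibratedImage(pages, pixelSizeUm)
}

#' @rdname imageIO
#' @param mask logical matrix.
#' @export
writeMask <- function(mask, path) {
  m <- .asBinary(mask)
  storage.mode(m) <- "double"
  tiff::writeTIFF(m, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname imageIO
#' @export
readMask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}

#' Write / read the object records of a scene as CSV
#'
#' Coordinates and radii are written in micrometres with 4 decimals.
#'
#' @param scene a [GroundTruthScene-class] (or a compatible data.frame).
#' @param path file path.
#' @export
writeSceneObjects <- function(scene, path) {
  obj <- if (is(scene, "GroundTruthScene")) sceneObjects(scene) else scene
  out <- data.frame(class = obj$class,
                    x_um = round(obj$xUm, 4), y_um = round(obj$yUm, 4),
                    radius_um = round(obj$radiusUm, 4))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSceneObjects
#' @export
readSceneObjects <- function(path) {
  tb <- utils::read.csv(path)
  data.frame(class = tb$class, xUm = tb$x_um, yUm = tb$y_um,
             radiusUm = tb$radius_um)
}

#' Write / read a scene specification as YAML
#'
#' @param spec a [SceneSpec-class].
#' @param path file path.
#' @export
writeSceneSpec <- function(spec, path) {
  stopifnot(is(spec, "SceneSpec"))
  slots <- slotNames("SceneSpec")
  vals <- lapply(slots, function(s) slot(spec, s))
  names(vals) <- slots
  vals$window <- list(widthUm = spec@window@widthUm,
                      heightUm = spec@window@heightUm,
                      pixelSizeUm = spec@window@pixelSizeUm)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writeSceneSpec
#' @export
readSceneSpec <- function(path) {
  vals <- yaml::read_yaml(path)
  w <- imageWindow(vals$window$widthUm, vals$window$heightUm,
                   vals$window$pixelSizeUm)
  do.call(sceneSpec, c(list(matType = vals$matType, window = w),
    vals[setdiff(names(vals), c("matType", "window"))]))
}
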