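#' Render a scene to a noisy multi-channel image
#'
#' Objects are composited (maximum-intensity) into class-appropriate
#' channels — SRM and microspheres into `probe`, all bacteria including
#' filaments into `counterstain` (SRM carry the general DNA stain too),
#' minerals into `reflectance` — at unit amplitude, or at the dimming
#' factor for objects flagged as lying below the focal plane. The canvas
#' is then Gaussian-blurred, a constant background is added, and
#' shot-noise-like Gaussian noise is applied whose standard deviation is
#' proportional to the local mean intensity (`intensity / snr`, so a
#' unit-amplitude object carries noise sd `1/snr` while the dark
#' background stays comparatively quiet, as in photon-limited imaging).
#' Values are clipped to the detector range `[0, 1]`.
#'
#' @param scene a [GroundTruthScene-class].
#' @param seed integer seed for the noise draw; defaults to the scene seed
#'   plus 1000, so a rerun of the same scene is bit-identical.
#' @return a [CalibratedImage-class] with channels `probe`, `counterstain`,
#'   `reflectance`.
#' @export
renderScene <- function(scene, seed = NULL) {
  stopifnot(is(scene, "GroundTruthScene"))
  spec <- scene@spec
  if (is.null(seed)) seed <- as.integer(spec@seed) + 1000L
  w <- scene@window
  px <- w@pixelSizeUm
  dims <- windowDim(w)
  noise <- spec@noise
  obj <- scene@objects

  paintDisks <- function(canvas, o, amp) {
    if (!nrow(o)) return(canvas)
    m <- .rasterizeDisks(o$xUm, o$yUm, o$radiusUm, dims, px)
    pmax(canvas, amp * m)
  }
  paintClass <- function(canvas, classes) {
    o <- obj[obj$class %in% classes, ]
    canvas <- paintDisks(canvas, o[!o$dimmed, ], 1)
    paintDisks(canvas, o[o$dimmed, ], noise$dimFactor)
  }

  probe <- paintClass(matrix(0, dims[1], dims[2]), c("srm", "microsphere"))
  counter <- paintClass(matrix(0, dims[1], dims[2]), c("srm", "other"))
  for (df in scene@filaments) {
    amp <- if (isTRUE(attr(df, "dimmed"))) noise$dimFactor else 1
    for (s in unique(df$seg)) {
      part <- df[df$seg == s, , drop = FALSE]
      if (nrow(part) >= 2)
        counter <- pmax(counter, amp * .rasterizePolyline(
          part, attr(df, "widthPx"), dims, px))
    }
  }
  refl <- paintClass(matrix(0, dims[1], dims[2]), c("precipitate", "ooid"))

  channels <- list(probe = probe, counterstain = counter,
                   reflectance = refl)
  if (noise$blurSigmaPx > 0)
    channels <- lapply(channels, function(ch)
      EBImage::imageData(EBImage::gblur(EBImage::Image(ch),
                                        sigma = noise$blurSigmaPx)))
  withr::with_seed(as.integer(seed), {
    channels <- lapply(channels, function(ch) {
      ch <- ch + noise$background
      if (is.finite(noise$snr) && noise$snr > 0)
        ch <- ch + stats::rnorm(length(ch)) * pmax(ch, 0) / noise$snr
      ## detector range: negatives floored, saturation at 1
      pmin(pmax(matrix(ch, dims[1], dims[2]), 0), 1)
    })
  })
  calibratedImage(channels, px)
}
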