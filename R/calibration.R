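#' Area-derived object count
#'
#' Total foreground area divided by the area of one whole object. The
#' estimate is real-valued and deliberately not rounded: it is a
#' *relative* abundance estimate (areas from complex matrices support
#' relative, not absolute, cell abundances).
#'
#' @param mask logical foreground mask.
#' @param unitObjectAreaUm2 area of one whole object, um^2; the default
#'   is the footprint of a 1.0 um diameter microsphere.
#' @param pixelSizeUm pixel size, micrometres.
#' @export
areaCountEstimate <- function(mask, unitObjectAreaUm2 = pi * 0.5^2,
                              pixelSizeUm) {
  stopifnot(unitObjectAreaUm2 > 0)
  sum(.asBinary(mask)) * pixelSizeUm^2 / unitObjectAreaUm2
}

#' Microsphere ground-truthing of area-based counting
#'
#' Runs the calibration pipeline on a dilution series: each image is
#' segmented with [classifyTwoClass()], objects are counted directly with
#' [segmentAndCount()] (the counting rule), the foreground area is
#' converted to an area-derived count with [areaCountEstimate()], and the
#' three Pearson product-moment associations (area vs known, direct vs
#' known, area vs direct) are computed across all images. A series with
#' zero variance yields a degenerate flag instead of a coefficient.
#'
#' @param images list of [CalibratedImage-class] (or single-channel
#'   matrices) for the dilution fields.
#' @param knownCounts expected object count per image (the dilution
#'   means).
#' @param unitObjectAreaUm2 area of one whole object, um^2.
#' @param pixelSizeUm pixel size; taken from the first CalibratedImage
#'   when omitted.
#' @param channel channel holding the sphere fluorescence.
#' @param dilution optional dilution labels for the output table.
#' @return a [CalibrationResult-class].
#' @export
calibrateSeries <- function(images, knownCounts,
                            unitObjectAreaUm2 = pi * 0.5^2,
                            pixelSizeUm = NULL, channel = "probe",
                            dilution = NULL) {
  stopifnot(length(images) == length(knownCounts))
  if (length(unique(knownCounts)) < 3)
    warning("fewer than 3 distinct dilution levels")
  rows <- lapply(seq_along(images), function(k) {
    img <- images[[k]]
    if (is(img, "CalibratedImage")) {
      ch <- getChannel(img, channel)
      px <- pixelSize(img)
    } else {
      ch <- img
      px <- pixelSizeUm
    }
    if (is.null(px)) stop("pixelSizeUm required for matrix input")
    fg <- classifyTwoClass(ch)
    seg <- segmentAndCount(fg, unitObjectAreaUm2, px)
    data.frame(image = k,
               dilution = if (is.null(dilution)) NA else dilution[k],
               knownCount = knownCounts[k],
               directCount = countEstimate(seg),
               areaUm2 = sum(fg) * px^2,
               areaCount = areaCountEstimate(fg, unitObjectAreaUm2, px))
  })
  tb <- do.call(rbind, rows)
  assoc <- function(x, y, label) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(pair = label, r = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    ct <- stats::cor.test(x, y)
    data.frame(pair = label, r = unname(ct$estimate),
               p = ct$p.value, degenerate = FALSE)
  }
  cors <- rbind(
    assoc(tb$areaCount, tb$knownCount, "area_vs_known"),
    assoc(tb$directCount, tb$knownCount, "direct_vs_known"),
    assoc(tb$areaCount, tb$directCount, "area_vs_direct"))
  new("CalibrationResult", table = tb, correlations = cors,
      unitObjectAreaUm2 = unitObjectAreaUm2)
}
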