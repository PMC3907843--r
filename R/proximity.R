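#' SRM share of bacteria near precipitates
#'
#' Computes, for each distance threshold, the percentage of near-
#' precipitate bacteria that are SRM. The exact Euclidean distance
#' transform from the precipitate mask assigns every pixel its distance
#' (in pixels, converted to um) to the nearest precipitate pixel; a cell
#' object (8-connected component of its class mask) is *near* at
#' threshold `t` when its minimum pixel distance is at most `t`. The
#' default thresholds 1.1, 2.2 and 4.4 um form a doubling series.
#'
#' @param srmMask,otherBacteriaMask,precipitateMask logical masks of one
#'   shape.
#' @param pixelSizeUm pixel size, micrometres.
#' @param thresholdsUm distance thresholds, micrometres.
#' @return a [ProximityResult-class]; thresholds with no near bacteria
#'   (or an empty precipitate mask) are flagged undefined.
#' @export
proximityFractions <- function(srmMask, otherBacteriaMask, precipitateMask,
                               pixelSizeUm,
                               thresholdsUm = c(1.1, 2.2, 4.4)) {
  stopifnot(all(thresholdsUm > 0))
  srm <- .asBinary(srmMask)
  other <- .asBinary(otherBacteriaMask)
  precip <- .asBinary(precipitateMask)
  stopifnot(identical(dim(srm), dim(other)),
            identical(dim(srm), dim(precip)))
  thresholdsUm <- sort(thresholdsUm)
  if (!any(precip)) {
    tb <- data.frame(thresholdUm = thresholdsUm, srmNear = NA_integer_,
                     otherNear = NA_integer_, percentSrm = NA_real_,
                     defined = FALSE)
    return(new("ProximityResult", table = tb, pixelSizeUm = pixelSizeUm))
  }
  ## distance (um) of every pixel to the nearest precipitate pixel
  dmap <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - precip))) *
    pixelSizeUm
  minDist <- function(mask) {
    lab <- .label8(mask)
    if (!max(lab)) return(numeric())
    as.numeric(tapply(dmap[lab > 0], lab[lab > 0], min))
  }
  dSrm <- minDist(srm)
  dOther <- minDist(other)
  tb <- do.call(rbind, lapply(thresholdsUm, function(t) {
    ns <- sum(dSrm <= t); no <- sum(dOther <= t)
    data.frame(thresholdUm = t, srmNear = ns, otherNear = no,
               percentSrm = if (ns + no > 0) 100 * ns / (ns + no)
                            else NA_real_,
               defined = ns + no > 0)
  }))
  new("ProximityResult", table = tb, pixelSizeUm = pixelSizeUm)
}

#' Per-object minimum distances to precipitates
#'
#' Lower-level companion to [proximityFractions()]: the minimum
#' pixel-centre distance (um) from each 8-connected object of `mask` to
#' the precipitate mask.
#'
#' @param mask logical object mask.
#' @param precipitateMask logical precipitate mask.
#' @param pixelSizeUm pixel size, micrometres.
#' @return numeric vector, one value per labelled object.
#' @export
objectMinDistances <- function(mask, precipitateMask, pixelSizeUm) {
  mask <- .asBinary(mask); precip <- .asBinary(precipitateMask)
  if (!any(precip)) stop("precipitate mask is empty")
  dmap <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - precip))) *
    pixelSizeUm
  lab <- .label8(mask)
  if (!max(lab)) return(numeric())
  as.numeric(tapply(dmap[lab > 0], lab[lab > 0], min))
}
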