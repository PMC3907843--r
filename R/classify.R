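#' Supervised minimum-distance pixel classification
#'
#' Each pixel is assigned to the class whose mean training intensity
#' vector is nearest in channel space (Euclidean minimum-distance rule).
#' Background is an ordinary class and must be represented among the
#' training pixels, so sub-threshold pixels fall to background by losing
#' the distance comparison. The rule is invariant to a common rescaling
#' of all channels and training pixels.
#'
#' @param image a [CalibratedImage-class].
#' @param trainingPixels named list (one entry per class, `background`
#'   required) of matrices/data.frames with one column per channel of
#'   `image` and one row per training pixel.
#' @return a [ClassMasks-class], one mask per trained class.
#' @seealso [sampleTrainingPixels()] to draw training pixels from truth
#'   masks of a rendered scene.
#' @export
classifySupervised <- function(image, trainingPixels) {
  stopifnot(is(image, "CalibratedImage"))
  if (!"background" %in% names(trainingPixels))
    stop("training pixels must include a 'background' class")
  if (any(!vapply(trainingPixels, NROW, 1L) >= 1))
    stop("every class needs at least one training pixel")
  chn <- channelNames(image)
  centers <- t(vapply(trainingPixels, function(tp) {
    tp <- as.matrix(as.data.frame(tp))
    if (ncol(tp) != length(chn))
      stop("training pixels must have one column per image channel")
    colMeans(tp)
  }, numeric(length(chn))))
  X <- vapply(image@channels, as.vector,
              numeric(length(image@channels[[1]])))
  ## squared distance to each class centre
  d2 <- X^2 %*% rep(1, ncol(X)) %*% t(rep(1, nrow(centers))) -
    2 * X %*% t(centers)
  d2 <- sweep(d2, 2, rowSums(centers^2), `+`)
  assign <- max.col(-d2, ties.method = "first")
  dims <- dim(image@channels[[1]])
  masks <- lapply(seq_len(nrow(centers)), function(k)
    matrix(assign == k, dims[1], dims[2]))
  names(masks) <- names(trainingPixels)
  classMasks(masks, image@pixelSizeUm)
}

#' Draw training pixels from truth masks
#'
#' Convenience for supervised classification of rendered synthetic
#' scenes: samples pixel intensity vectors from each truth mask (and from
#' the complement of all masks for `background`).
#'
#' @param image a rendered [CalibratedImage-class].
#' @param masks named list of logical truth masks.
#' @param nPerClass pixels per class.
#' @param seed integer seed.
#' @return named list of per-class intensity matrices, including
#'   `background`.
#' @export
sampleTrainingPixels <- function(image, masks, nPerClass = 50, seed = 1L) {
  stopifnot(is(image, "CalibratedImage"))
  X <- vapply(image@channels, as.vector,
              numeric(length(image@channels[[1]])))
  colnames(X) <- channelNames(image)
  fgAny <- Reduce(`|`, lapply(masks, .asBinary))
  pools <- c(lapply(masks, function(m) which(.asBinary(m))),
             list(background = which(!fgAny)))
  pools <- pools[vapply(pools, length, 1L) > 0]
  withr::with_seed(as.integer(seed), {
    lapply(pools, function(idx) {
      take <- idx[sample.int(length(idx), min(nPerClass, length(idx)))]
      X[take, , drop = FALSE]
    })
  })
}

#' Unsupervised two-class intensity classification
#'
#' Iterative 2-means clustering of a single channel: class centres start
#' at the intensity extremes (Isodata-style initialization, which keeps
#' the bright centre anchored on sparse bright objects), pixels are
#' reassigned to the nearer centre and centres recomputed, stopping when
#' the fraction of
#' pixels unchanged between iterations reaches `convergenceThreshold` or
#' after `maxIterations` reassignment passes. The brighter cluster is
#' foreground. Defaults follow the standard calibration protocol
#' (20 iterations, 0.95 convergence).
#'
#' @param channel numeric matrix.
#' @param maxIterations maximum reassignment iterations.
#' @param convergenceThreshold fraction of unchanged pixels at which to
#'   stop.
#' @return logical foreground mask.
#' @export
classifyTwoClass <- function(channel, maxIterations = 20,
                             convergenceThreshold = 0.95) {
  if (is(channel, "Image")) channel <- EBImage::imageData(channel)
  v <- as.vector(channel)
  if (!is.finite(stats::var(v)) || stats::var(v) == 0)
    stop("channel is constant: two-class classification is degenerate")
  ctr <- range(v)
  assign <- abs(v - ctr[1]) > abs(v - ctr[2])  # TRUE = bright cluster
  for (it in seq_len(maxIterations)) {
    ctr <- c(if (any(!assign)) mean(v[!assign]) else ctr[1],
             if (any(assign)) mean(v[assign]) else ctr[2])
    newAssign <- abs(v - ctr[1]) > abs(v - ctr[2])
    unchanged <- mean(newAssign == assign)
    assign <- newAssign
    if (unchanged >= convergenceThreshold) break
  }
  matrix(assign, nrow(channel), ncol(channel))
}

#' Identify and subtract filamentous shapes
#'
#' Cyanobacteria and other bacteria share a fluorescence signature, so
#' filaments are recognized by shape. Fragments are first grouped by
#' dilating the mask with a disk of radius `maxGapUm / 2` (bridging
#' breaks up to `maxGapUm`, so linear features are identified even when
#' discontinuous); each group is then measured on its original pixels,
#' and classified as filament when its extent along its principal axis
#' is at least `minLengthUm` and its elongation (principal over
#' secondary extent) at least `minElongation`. The filament and residual
#' masks partition the input exactly.
#'
#' @param combinedMask logical mask of all bacteria/cyanobacteria pixels.
#' @param pixelSizeUm pixel size, micrometres.
#' @param minLengthUm minimum filament length.
#' @param maxGapUm largest break to bridge.
#' @param minElongation minimum major/minor extent ratio.
#' @return list with logical `filament` and `residual` masks.
#' @export
subtractFilaments <- function(combinedMask, pixelSizeUm,
                              minLengthUm = 10, maxGapUm = 3,
                              minElongation = 5) {
  mask <- .asBinary(combinedMask)
  if (!any(mask))
    return(list(filament = mask, residual = mask))
  px <- pixelSizeUm
  brushD <- 2L * as.integer(ceiling(maxGapUm / px / 2)) + 1L
  grouped <- if (brushD >= 3) {
    EBImage::imageData(EBImage::dilate(
      EBImage::Image(mask * 1), EBImage::makeBrush(brushD, "disc"))) > 0.5
  } else mask
  grouped <- grouped | mask
  lab <- .label8(grouped)
  nr <- nrow(mask)
  isFil <- logical(max(lab))
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l & mask)
    i <- ((idx - 1L) %% nr) + 1L
    j <- ((idx - 1L) %/% nr) + 1L
    if (length(idx) < 3) next
    P <- cbind(j, i) * px
    P <- sweep(P, 2, colMeans(P))
    ev <- eigen(stats::cov(P), symmetric = TRUE)
    proj1 <- P %*% ev$vectors[, 1]
    proj2 <- P %*% ev$vectors[, 2]
    len <- diff(range(proj1)) + px
    wid <- diff(range(proj2)) + px
    isFil[l] <- len >= minLengthUm && (len / wid) >= minElongation
  }
  filament <- mask & matrix(isFil[pmax(lab, 1)] & lab > 0,
                            nrow(mask), ncol(mask))
  list(filament = filament, residual = mask & !filament)
}

#' Co-localization gating of probe objects
#'
#' Retains a probe-mask object (8-connected component) when the fraction
#' of its area overlapping the counterstain mask is at least
#' `minOverlapFraction`; retained objects are kept whole. Cell areas
#' carrying both fluorescence signatures are thereby counted as SRM.
#'
#' @param probeMask,counterstainMask logical masks of one shape.
#' @param minOverlapFraction minimum overlap fraction.
#' @return logical SRM mask.
#' @export
colocalize <- function(probeMask, counterstainMask,
                       minOverlapFraction = 0.5) {
  probe <- .asBinary(probeMask)
  counter <- .asBinary(counterstainMask)
  stopifnot(identical(dim(probe), dim(counter)))
  if (!any(probe)) return(probe)
  lab <- .label8(probe)
  tot <- tabulate(lab[lab > 0])
  ov <- tabulate(lab[lab > 0 & counter], nbins = length(tot))
  keep <- (ov / tot) >= minOverlapFraction
  probe & matrix(keep[pmax(lab, 1)] & lab > 0, nrow(probe), ncol(probe))
}

#' Segment a mask and count objects with the counting rule
#'
#' Labels the 8-connected components of a binary mask and applies the
#' counting rule for partial objects: components of at least half the
#' typical object area that do not touch the image border count one each,
#' while border-touching and sub-size fragments are pooled and their
#' total area divided by the typical object area, rounded to an integer.
#' Two half-objects cut at opposite borders thus sum to one.
#'
#' @param mask logical mask.
#' @param typicalObjectAreaUm2 area of one whole object, um^2.
#' @param pixelSizeUm pixel size, micrometres.
#' @return a [LabeledObjects-class]; the counting-rule count is available
#'   via [countEstimate()].
#' @export
segmentAndCount <- function(mask, typicalObjectAreaUm2, pixelSizeUm) {
  stopifnot(typicalObjectAreaUm2 > 0)
  mask <- .asBinary(mask)
  lab <- .label8(mask)
  tb <- .labelStats(lab, pixelSizeUm)
  tb$fullSize <- (tb$areaUm2 >= typicalObjectAreaUm2 / 2 & !tb$borderFlag) |
    tb$areaUm2 >= typicalObjectAreaUm2
  fragments <- sum(tb$areaUm2[!tb$fullSize])
  count <- sum(tb$fullSize) + round(fragments / typicalObjectAreaUm2)
  new("LabeledObjects", labels = lab, table = tb, count = as.numeric(count),
      typicalObjectAreaUm2 = typicalObjectAreaUm2,
      pixelSizeUm = pixelSizeUm)
}
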