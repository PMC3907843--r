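#' Accessors
#'
#' Small accessor generics used across the package's S4 containers, so that
#' downstream code never reaches into slots directly.
#'
#' @param x an object of one of the package's S4 classes.
#' @param name channel or mask name.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' @rdname accessors
#' @export
setGeneric("maskList", function(x) standardGeneric("maskList"))

#' @rdname accessors
#' @export
setGeneric("getMask", function(x, name) standardGeneric("getMask"))

#' @rdname accessors
#' @export
setGeneric("sceneObjects", function(x) standardGeneric("sceneObjects"))

#' @rdname accessors
#' @export
setGeneric("truthMasks", function(x) standardGeneric("truthMasks"))

#' @rdname accessors
#' @export
setGeneric("surfaceRow", function(x) standardGeneric("surfaceRow"))

#' @rdname accessors
#' @export
setGeneric("objectTable", function(x) standardGeneric("objectTable"))

#' @rdname accessors
#' @export
setGeneric("countEstimate", function(x) standardGeneric("countEstimate"))

#' @rdname accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname accessors
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))

#' @rdname accessors
#' @export
setGeneric("pcfTable", function(x) standardGeneric("pcfTable"))

#' @rdname accessors
#' @export
setGeneric("proximityTable", function(x) standardGeneric("proximityTable"))

#' @rdname accessors
#' @export
setGeneric("calibrationTable", function(x) standardGeneric("calibrationTable"))

#' @rdname accessors
#' @export
setGeneric("calibrationCorrelations",
           function(x) standardGeneric("calibrationCorrelations"))

## ---- Window ----

#' @rdname accessors
#' @export
setMethod("pixelSize", "Window", function(x) x@pixelSizeUm)

#' Pixel dimensions of a window
#'
#' @param x a [Window-class].
#' @return integer `c(nrow, ncol)` (rows = y/depth, cols = x).
#' @export
windowDim <- function(x) {
  stopifnot(is(x, "Window"))
  c(round(x@heightUm / x@pixelSizeUm), round(x@widthUm / x@pixelSizeUm))
}

#' Physical area of a window in square micrometres
#' @param x a [Window-class].
#' @export
windowArea <- function(x) {
  stopifnot(is(x, "Window"))
  x@widthUm * x@heightUm
}

setMethod("show", "Window", function(object) {
  d <- windowDim(object)
  cat(sprintf("Window: %.2f x %.2f um (%d x %d px @ %.5f um/px)\n",
              object@widthUm, object@heightUm, d[2], d[1],
              object@pixelSizeUm))
})

## ---- CalibratedImage ----

#' @rdname accessors
#' @export
setMethod("pixelSize", "CalibratedImage", function(x) x@pixelSizeUm)

#' @rdname accessors
#' @export
setMethod("channelNames", "CalibratedImage", function(x) names(x@channels))

#' @rdname accessors
#' @export
setMethod("getChannel", "CalibratedImage", function(x, name) {
  if (!name %in% names(x@channels))
    stop("no channel named '", name, "'")
  x@channels[[name]]
})

setMethod("show", "CalibratedImage", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("CalibratedImage: %d x %d px, %.5f um/px\n  channels: %s\n",
              d[1], d[2], object@pixelSizeUm,
              paste(names(object@channels), collapse = ", ")))
})

## ---- GroundTruthScene ----

#' @rdname accessors
#' @export
setMethod("sceneObjects", "GroundTruthScene", function(x) x@objects)

#' @rdname accessors
#' @export
setMethod("truthMasks", "GroundTruthScene", function(x) x@masks)

#' @rdname accessors
#' @export
setMethod("pixelSize", "GroundTruthScene", function(x) x@window@pixelSizeUm)

setMethod("show", "GroundTruthScene", function(object) {
  cat(sprintf("GroundTruthScene (%s): %d objects, %d filaments\n",
              object@spec@matType, nrow(object@objects),
              length(object@filaments)))
  if (nrow(object@objects))
    print(table(object@objects$class))
})

## ---- SurfaceLine ----

#' @rdname accessors
#' @export
setMethod("surfaceRow", "SurfaceLine", function(x) x@rowPx)

setMethod("show", "SurfaceLine", function(object) {
  cat(sprintf("SurfaceLine over %d columns, rows %.1f-%.1f (median smooth %d px)\n",
              length(object@rowPx), min(object@rowPx), max(object@rowPx),
              as.integer(object@smoothWindowPx)))
})

## ---- ClassMasks ----

#' @rdname accessors
#' @export
setMethod("maskList", "ClassMasks", function(x) x@masks)

#' @rdname accessors
#' @export
setMethod("getMask", "ClassMasks", function(x, name) {
  if (!name %in% names(x@masks)) stop("no mask named '", name, "'")
  x@masks[[name]]
})

#' @rdname accessors
#' @export
setMethod("pixelSize", "ClassMasks", function(x) x@pixelSizeUm)

setMethod("show", "ClassMasks", function(object) {
  px <- vapply(object@masks, sum, numeric(1))
  cat("ClassMasks:\n")
  for (nm in names(px))
    cat(sprintf("  %-12s %d px\n", nm, as.integer(px[[nm]])))
})

## ---- LabeledObjects ----

#' @rdname accessors
#' @export
setMethod("objectTable", "LabeledObjects", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("countEstimate", "LabeledObjects", function(x) x@count)

setMethod("show", "LabeledObjects", function(object) {
  cat(sprintf(
    "LabeledObjects: %d components, counting-rule count %.0f\n",
    nrow(object@table), object@count))
})

## ---- ClusterSet ----

#' @rdname accessors
#' @export
setMethod("clusterTable", "ClusterSet", function(x) x@clusters)

#' @rdname accessors
#' @export
setMethod("memberships", "ClusterSet", function(x) x@membership)

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf(
    "ClusterSet: %d cells in %d clusters (%d selected; region %.1f um, > %d cells)\n",
    nrow(object@points), nrow(object@clusters),
    sum(object@clusters$selected), object@regionDiameterUm,
    as.integer(object@minCells)))
})

## ---- PairCorrelationCurve ----

#' @rdname accessors
#' @export
setMethod("pcfTable", "PairCorrelationCurve", function(x) {
  out <- data.frame(rUm = x@r, g = x@g)
  if (nrow(x@envelope) == 2) {
    out$envLo <- x@envelope[1, ]
    out$envHi <- x@envelope[2, ]
  }
  out
})

setMethod("show", "PairCorrelationCurve", function(object) {
  cat(sprintf(
    "PairCorrelationCurve: r in [%.2f, %.2f] um (%d radii), ring %.2f um, %s edge correction\n",
    min(object@r), max(object@r), length(object@r), object@ringWidthUm,
    object@edgeCorrection))
  cat(sprintf("  mean g = %.3f over %d x %d points",
              mean(object@g, na.rm = TRUE), object@nA, object@nB))
  if (object@envelopeSims > 0)
    cat(sprintf("; CSR envelope from %d simulations", object@envelopeSims))
  cat("\n")
})

#' Plot a pair correlation curve
#'
#' Draws the estimated g(r), the CSR reference line g = 1, and (when
#' present) the Monte Carlo envelope band.
#'
#' @param x a [PairCorrelationCurve-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @export
setMethod("plot", signature("PairCorrelationCurve", "missing"),
  function(x, y, ...) {
    tb <- pcfTable(x)
    ylim <- range(c(tb$g, tb$envLo, tb$envHi, 1), na.rm = TRUE)
    graphics::plot(tb$rUm, tb$g, type = "l", xlab = "r (um)",
                   ylab = "g(r)", ylim = ylim, ...)
    if (!is.null(tb$envLo)) {
      ok <- stats::complete.cases(tb$envLo, tb$envHi)
      graphics::polygon(c(tb$rUm[ok], rev(tb$rUm[ok])),
                        c(tb$envLo[ok], rev(tb$envHi[ok])),
                        col = grDevices::adjustcolor("grey", 0.5), border = NA)
      graphics::lines(tb$rUm, tb$g)
    }
    graphics::abline(h = 1, lty = 2)
    invisible(x)
  })

## ---- ProximityResult ----

#' @rdname accessors
#' @export
setMethod("proximityTable", "ProximityResult", function(x) x@table)

setMethod("show", "ProximityResult", function(object) {
  cat("ProximityResult (% of near-precipitate bacteria that are SRM):\n")
  print(object@table, row.names = FALSE)
})

## ---- CalibrationResult ----

#' @rdname accessors
#' @export
setMethod("calibrationTable", "CalibrationResult", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("calibrationCorrelations", "CalibrationResult",
          function(x) x@correlations)

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf(
    "CalibrationResult: %d images; area-derived counts are relative estimates\n",
    nrow(object@table)))
  print(object@correlations, row.names = FALSE)
})

## ---- GroupComparison ----

setMethod("show", "GroupComparison", function(object) {
  lab <- if (object@design == "two-group") {
    sprintf("Welch t = %.3f, df = %.1f", object@statistic, object@df[1])
  } else {
    sprintf("ANOVA F = %.3f, df = (%d, %d)", object@statistic,
            as.integer(object@df[1]), as.integer(object@df[2]))
  }
  cat(sprintf("GroupComparison (%s, transform = %s): %s, p = %.4g\n",
              object@design, object@transform, lab, object@pValue))
  print(object@groups, row.names = FALSE)
  if (nrow(object@postHoc)) {
    cat(sprintf("Post-hoc decisions at alpha = %.2f:\n", object@alpha))
    print(object@postHoc, row.names = FALSE)
  }
})
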