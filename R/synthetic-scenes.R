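#' Specify a synthetic mat scene
#'
#' Builds the parameter set for one ground-truthed scene. Defaults depend on
#' `matType` and encode the study conditions the generator emulates:
#'
#' * `"type1"` (non-lithifying): sparse SRM placed by complete spatial
#'   randomness through the upper 500 um, a planted SRM share of 20.7% of
#'   total cell area inside the 130 um surface layer, scattered small
#'   carbonate patches, surface-associated cyanobacterial filaments, and an
#'   irregular (sinusoidal) surface.
#' * `"type2"` (lithifying): SRM placed by a Thomas cluster process
#'   restricted to the 130 um surface layer (with a small fraction seeded
#'   deeper), a planted SRM share of 88.0% of cell area in that layer, a
#'   near-continuous carbonate crust 30-50 um thick at the surface, and
#'   filaments underlying the SRM layer.
#' * `"microsphere"`: a flat calibration field of 1.0 um diameter spheres.
#'
#' Planted area-fraction targets are expressed (and calibrated) in
#' rasterized truth-mask area, the same units in which the analysis
#' measures them.
#'
#' @param matType `"type1"`, `"type2"` or `"microsphere"`.
#' @param window a [Window-class]; default is the 512 px / 682.67 um map
#'   calibration.
#' @param srmAreaFractionTarget planted SRM percent of total cell area in
#'   the surface layer.
#' @param srmLayerDepthUm depth of the SRM surface layer, um.
#' @param srmDeepFraction fraction of SRM seeded below the surface layer
#'   (type2).
#' @param crustDepthRangeUm crust thickness bounds, um (type2).
#' @param cellRadiusMeanUm,cellRadiusSdUm truncated-normal cell radius
#'   distribution, um (microspheres are exactly 0.5 um).
#' @param nSrm number of SRM cells (type1).
#' @param thomasKappa,thomasMu,thomasSigmaUm Thomas parameters for the
#'   type2 SRM layer (parents per um^2 of layer, mean offspring per parent,
#'   offspring dispersion in um).
#' @param maxDepthUm deepest cell placement below the surface, um.
#' @param nFilaments,filamentLengthUm,filamentWidthPx,filamentGapFraction
#'   cyanobacterial filament count, mean length (um), stroke width (px) and
#'   probability that an internal segment is omitted (discontinuous
#'   filaments).
#' @param nPrecipPatches,precipPatchRadiusUm scattered precipitate patches
#'   and their grain radius scale, um.
#' @param nOoids,ooidRadiusRangeUm large carbonate grains at the surface.
#' @param nSpheres microsphere count (microsphere fields).
#' @param srmNearPrecipFraction fraction of (layer) SRM relocated to within
#'   a couple of micrometres of a precipitate.
#' @param surfaceProfile list: `kind` (`"flat"` or `"sinusoid"`),
#'   `offsetUm`, `amplitudeUm`, `periodUm`.
#' @param noise list: `background` level, `snr` (object amplitude over
#'   Gaussian noise sd; `Inf` disables noise), `dimFraction` and
#'   `dimFactor` (share of objects rendered below the focal plane and
#'   their intensity factor), `blurSigmaPx`.
#' @param seed integer seed; a fixed seed yields a byte-identical scene.
#' @return a [SceneSpec-class].
#' @export
sceneSpec <- function(matType = c("type1", "type2", "microsphere"),
                      window = imageWindow(),
                      srmAreaFractionTarget = NULL,
                      srmLayerDepthUm = 130,
                      srmDeepFraction = NULL,
                      crustDepthRangeUm = c(30, 50),
                      cellRadiusMeanUm = 0.5, cellRadiusSdUm = 0.1,
                      nSrm = NULL,
                      thomasKappa = 7e-4, thomasMu = 12, thomasSigmaUm = 2,
                      maxDepthUm = 500,
                      nFilaments = NULL, filamentLengthUm = 100,
                      filamentWidthPx = 2, filamentGapFraction = 0.2,
                      nPrecipPatches = NULL, precipPatchRadiusUm = 2.5,
                      nOoids = 2, ooidRadiusRangeUm = c(25, 50),
                      nSpheres = 200,
                      srmNearPrecipFraction = NULL,
                      surfaceProfile = NULL,
                      noise = list(),
                      seed = 1L) {
  matType <- match.arg(matType)
  pick <- function(x, t1, t2, ms) if (!is.null(x)) x else
    switch(matType, type1 = t1, type2 = t2, microsphere = ms)
  srmAreaFractionTarget <- pick(srmAreaFractionTarget, 20.7, 88.0, NA)
  srmDeepFraction <- pick(srmDeepFraction, NA, 0.08, NA)
  nSrm <- pick(nSrm, 350, NA, NA)
  nFilaments <- pick(nFilaments, 4, 5, 0)
  nPrecipPatches <- pick(nPrecipPatches, 25, 10, 0)
  srmNearPrecipFraction <- pick(srmNearPrecipFraction, 0.12, 0.5, 0)
  if (matType == "microsphere") nOoids <- 0
  if (is.null(surfaceProfile))
    surfaceProfile <- switch(matType,
      type1 = list(kind = "sinusoid", offsetUm = 25, amplitudeUm = 10,
                   periodUm = 170),
      type2 = list(kind = "sinusoid", offsetUm = 25, amplitudeUm = 5,
                   periodUm = 200),
      microsphere = list(kind = "flat", offsetUm = 0, amplitudeUm = 0,
                         periodUm = 1))
  noiseDefaults <- list(background = 0.05, snr = 10,
                        dimFraction = if (matType == "microsphere") 0 else 0.1,
                        dimFactor = 0.4, blurSigmaPx = 0.35)
  noise <- utils::modifyList(noiseDefaults, noise)
  new("SceneSpec", matType = matType, window = window,
      srmAreaFractionTarget = as.numeric(srmAreaFractionTarget),
      srmLayerDepthUm = srmLayerDepthUm,
      srmDeepFraction = as.numeric(srmDeepFraction),
      crustDepthRangeUm = crustDepthRangeUm,
      cellRadiusMeanUm = cellRadiusMeanUm, cellRadiusSdUm = cellRadiusSdUm,
      nSrm = as.numeric(nSrm), thomasKappa = thomasKappa,
      thomasMu = thomasMu, thomasSigmaUm = thomasSigmaUm,
      maxDepthUm = maxDepthUm, nFilaments = nFilaments,
      filamentLengthUm = filamentLengthUm,
      filamentWidthPx = filamentWidthPx,
      filamentGapFraction = filamentGapFraction,
      nPrecipPatches = as.numeric(nPrecipPatches),
      precipPatchRadiusUm = precipPatchRadiusUm,
      nOoids = nOoids, ooidRadiusRangeUm = ooidRadiusRangeUm,
      nSpheres = as.numeric(nSpheres),
      srmNearPrecipFraction = srmNearPrecipFraction,
      surfaceProfile = surfaceProfile, noise = noise,
      seed = as.numeric(seed))
}

## surface depth (um) at arbitrary x positions
.surfaceAt <- function(profile, xUm) {
  if (identical(profile$kind, "flat")) {
    rep(profile$offsetUm, length(xUm))
  } else {
    ph <- if (is.null(profile$phase)) 0 else profile$phase
    profile$offsetUm +
      profile$amplitudeUm * sin(2 * pi * xUm / profile$periodUm + ph)
  }
}

.reflectInto <- function(x, lo, hi) {
  span <- hi - lo
  x <- abs(x - lo) %% (2 * span)
  lo + ifelse(x > span, 2 * span - x, x)
}

.drawRadii <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  .rtruncnorm(n, mean, sd, max(0.1, mean - 2.5 * sd), mean + 5 * sd)
}

## linear pixel indices of a disk footprint (centroid pixel always included)
.diskPixels <- function(xUm, yUm, r, dimPx, px) {
  i0 <- max(1L, floor((yUm - r) / px - 0.5) + 1L)
  i1 <- min(dimPx[1], ceiling((yUm + r) / px + 0.5))
  j0 <- max(1L, floor((xUm - r) / px - 0.5) + 1L)
  j1 <- min(dimPx[2], ceiling((xUm + r) / px + 0.5))
  idx <- integer()
  if (i0 <= i1 && j0 <= j1) {
    ii <- i0:i1; jj <- j0:j1
    dy <- (ii - 0.5) * px - yUm
    dx <- (jj - 0.5) * px - xUm
    hit <- which(outer(dy^2, dx^2, `+`) <= r^2)
    idx <- (rep(jj, each = length(ii))[hit] - 1L) * dimPx[1] +
      rep(ii, length(jj))[hit]
  }
  ic <- .pixOfX(yUm, px, dimPx[1]); jc <- .pixOfX(xUm, px, dimPx[2])
  unique(c(idx, (jc - 1L) * dimPx[1] + ic))
}

## mask of the region from the (true) surface down `depthUm`, per column
.depthBandMask <- function(surfaceUm, depthUm, dimPx, px) {
  yc <- (seq_len(dimPx[1]) - 0.5) * px
  lower <- outer(yc, surfaceUm, `>=`)
  upper <- outer(yc, surfaceUm + depthUm, `<=`)
  lower & upper
}

#' Build a ground-truthed synthetic scene
#'
#' Realizes a [SceneSpec-class] into planted object records, filament
#' polylines, noiseless per-class truth masks and a true surface line.
#' Type-1 SRM are completely spatially random; type-2 SRM follow a Thomas
#' cluster process confined to the surface layer, with over 85% of SRM
#' centroids within `srmLayerDepthUm` of the surface under the defaults.
#' A configurable fraction of SRM is planted within a couple of
#' micrometres of precipitate material. Other (non-SRM) bacteria are added
#' until the SRM share of total cell mask area inside the surface layer
#' matches `srmAreaFractionTarget`.
#'
#' @param spec a [SceneSpec-class].
#' @return a [GroundTruthScene-class].
#' @export
buildScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  withr::with_seed(as.integer(spec@seed), .buildSceneImpl(spec))
}

.buildSceneImpl <- function(spec) {
  w <- spec@window
  px <- w@pixelSizeUm
  dims <- windowDim(w)
  W <- w@widthUm; H <- w@heightUm
  xc <- (seq_len(dims[2]) - 0.5) * px

  profile <- spec@surfaceProfile
  if (identical(profile$kind, "sinusoid") && is.null(profile$phase))
    profile$phase <- stats::runif(1, 0, 2 * pi)
  surfaceUm <- .surfaceAt(profile, xc)
  surfFun <- function(x) .surfaceAt(profile, x)

  emptyObjects <- data.frame(class = character(), xUm = numeric(),
                             yUm = numeric(), radiusUm = numeric(),
                             dimmed = logical(), patch = numeric())
  objects <- emptyObjects
  addObjects <- function(objects, class, x, y, r, patch = NA_real_) {
    if (!length(x)) return(objects)
    rbind(objects, data.frame(class = class, xUm = x, yUm = y,
                              radiusUm = r, dimmed = FALSE, patch = patch))
  }
  clampDepth <- function(x, d, dmax) {
    x <- .reflectInto(x, 0, W)
    avail <- pmax(0.5, H - surfFun(x) - 0.5)
    list(x = x, y = surfFun(x) + pmin(.reflectInto(d, 0, dmax), avail))
  }

  layer <- spec@srmLayerDepthUm
  maxD <- min(spec@maxDepthUm, H - max(surfaceUm) - 1)

  ## ---- mineral phase ----
  if (spec@matType != "microsphere") {
    if (spec@matType == "type2") {
      crustT <- stats::runif(1, spec@crustDepthRangeUm[1],
                             spec@crustDepthRangeUm[2])
      gx <- seq(1, W - 1, by = 2.5)
      gd <- seq(2.5, max(3, crustT - 2.5), by = 4)
      cx <- rep(gx, each = length(gd)) + stats::rnorm(length(gx) * length(gd), 0, 0.8)
      cd <- rep(gd, length(gx)) + stats::rnorm(length(gx) * length(gd), 0, 0.8)
      cx <- .reflectInto(cx, 0, W)
      cd <- .reflectInto(cd, 0.5, crustT)
      cr <- .drawRadii(length(cx), 3, 0.6)
      objects <- addObjects(objects, "precipitate", cx, surfFun(cx) + cd, cr)
    }
    nP <- spec@nPrecipPatches
    if (nP > 0) {
      pcx <- stats::runif(nP, 0, W)
      pcd <- stats::runif(nP, 0, min(200, maxD))
      nG <- stats::rpois(nP, 3) + 2L
      gxy <- clampDepth(rep(pcx, nG) + stats::rnorm(sum(nG), 0, 2),
                        rep(pcd, nG) + stats::rnorm(sum(nG), 0, 2), maxD)
      gr <- .drawRadii(sum(nG), spec@precipPatchRadiusUm,
                       spec@precipPatchRadiusUm * 0.25)
      objects <- addObjects(objects, "precipitate", gxy$x, gxy$y, gr,
                            patch = rep.int(seq_len(nP), nG))
    }
    if (spec@nOoids > 0) {
      orad <- stats::runif(spec@nOoids, spec@ooidRadiusRangeUm[1],
                           spec@ooidRadiusRangeUm[2])
      ox <- stats::runif(spec@nOoids, 0, W)
      oy <- pmin(surfFun(ox) + orad * 0.8, H - 1)
      objects <- addObjects(objects, "ooid", ox, oy, orad)
    }
  }

  ## ---- SRM ----
  if (spec@matType == "type1" && spec@nSrm > 0) {
    n <- as.integer(spec@nSrm)
    sx <- stats::runif(n, 0, W)
    sd_ <- stats::runif(n, 0, maxD)
    sxy <- clampDepth(sx, sd_, maxD)
    objects <- addObjects(objects, "srm", sxy$x, sxy$y,
                          .drawRadii(n, spec@cellRadiusMeanUm,
                                     spec@cellRadiusSdUm))
  } else if (spec@matType == "type2") {
    nPar <- stats::rpois(1, spec@thomasKappa * W * layer)
    ppx <- stats::runif(nPar, 0, W)
    ppd <- stats::runif(nPar, 0, layer)
    nOff <- stats::rpois(nPar, spec@thomasMu)
    S <- sum(nOff)
    sx <- rep.int(ppx, nOff) + stats::rnorm(S, 0, spec@thomasSigmaUm)
    sd_ <- rep.int(ppd, nOff) + stats::rnorm(S, 0, spec@thomasSigmaUm)
    sxy <- clampDepth(sx, sd_, layer)
    objects <- addObjects(objects, "srm", sxy$x, sxy$y,
                          .drawRadii(S, spec@cellRadiusMeanUm,
                                     spec@cellRadiusSdUm))
    dfrac <- spec@srmDeepFraction
    if (!is.na(dfrac) && dfrac > 0 && S > 0) {
      nDeep <- round(S * dfrac / (1 - dfrac))
      dx <- stats::runif(nDeep, 0, W)
      dd <- stats::runif(nDeep, layer, max(maxD, layer + 1))
      dxy <- clampDepth(dx, dd, maxD)
      ## deep seeds must stay below the layer
      dxy$y <- pmax(dxy$y, surfFun(dxy$x) + layer + 0.5)
      dxy$y <- pmin(dxy$y, H - 0.5)
      objects <- addObjects(objects, "srm", dxy$x, dxy$y,
                            .drawRadii(nDeep, spec@cellRadiusMeanUm,
                                       spec@cellRadiusSdUm))
    }
  }

  ## relocate a fraction of layer SRM next to precipitate grains
  precip <- objects[objects$class == "precipitate", ]
  isSrm <- which(objects$class == "srm")
  if (nrow(precip) && length(isSrm) && spec@srmNearPrecipFraction > 0) {
    depth <- objects$yUm[isSrm] - surfFun(objects$xUm[isSrm])
    inLayer <- isSrm[depth <= layer]
    nMove <- round(length(inLayer) * spec@srmNearPrecipFraction)
    if (nMove > 0) {
      mv <- sample(inLayer, nMove)
      ## In sparse (type1) mats, anchor each relocated cell to a grain of a
      ## *distinct* patch: SRM sit near the scattered precipitates without
      ## forming same-patch pairs, so the pattern stays CSR-like. In type2
      ## anchors are drawn freely (clustering along the crust is intended).
      anchor <- if (spec@matType == "type1" && !all(is.na(precip$patch))) {
        pid <- unique(precip$patch[!is.na(precip$patch)])
        take <- if (nMove <= length(pid)) sample(pid, nMove)
                else sample(pid, nMove, replace = TRUE)
        vapply(take, function(p) {
          g <- which(precip$patch %in% p)
          if (length(g) == 1) g else sample(g, 1)
        }, 1L)
      } else sample.int(nrow(precip), nMove, replace = TRUE)
      ang <- stats::runif(nMove, 0, 2 * pi)
      gap <- stats::runif(nMove, 0.2, 2.2)
      nx <- precip$xUm[anchor] + cos(ang) * (precip$radiusUm[anchor] + gap)
      ny <- precip$yUm[anchor] + sin(ang) * (precip$radiusUm[anchor] + gap)
      nx <- .reflectInto(nx, 0.5, W - 0.5)
      nd <- .reflectInto(ny - surfFun(nx), 0, layer)
      objects$xUm[mv] <- nx
      objects$yUm[mv] <- pmin(surfFun(nx) + nd, H - 0.5)
    }
  }

  ## ---- filaments ----
  filaments <- list()
  if (spec@nFilaments > 0) {
    depthRange <- if (spec@matType == "type2") c(140, 280) else c(5, 250)
    depthRange[2] <- min(depthRange[2], maxD)
    for (f in seq_len(as.integer(spec@nFilaments))) {
      L <- .rtruncnorm(1, spec@filamentLengthUm, 25, 40, 250)
      x0 <- stats::runif(1, 0, W)
      d0 <- stats::runif(1, depthRange[1], max(depthRange))
      y0 <- min(surfFun(x0) + d0, H - 2)
      th <- stats::rnorm(1, 0, 0.15) + sample(c(0, pi), 1)
      step <- 8
      nV <- max(2L, ceiling(L / step) + 1L)
      xs <- numeric(nV); ys <- numeric(nV)
      xs[1] <- x0; ys[1] <- y0
      for (v in 2:nV) {
        th <- th + stats::rnorm(1, 0, 0.08)
        xs[v] <- xs[v - 1] + step * cos(th)
        ys[v] <- ys[v - 1] + step * sin(th)
      }
      keep <- xs > 0.5 & xs < W - 0.5 & ys > 0.5 & ys < H - 0.5
      if (sum(keep) < 2) next
      xs <- xs[keep]; ys <- ys[keep]
      seg <- cumsum(c(TRUE, stats::runif(length(xs) - 1) <
                        spec@filamentGapFraction))
      gapSeg <- unique(seg)[c(FALSE, TRUE)[(seq_along(unique(seg)) %% 2) + 1]]
      df <- data.frame(xUm = xs, yUm = ys, seg = seg)
      attr(df, "widthPx") <- spec@filamentWidthPx
      attr(df, "dimmed") <- FALSE
      filaments[[length(filaments) + 1]] <- df
    }
  }

  ## ---- truth masks (pre-calibration classes) ----
  rasterClass <- function(cls) {
    o <- objects[objects$class == cls, ]
    .rasterizeDisks(o$xUm, o$yUm, o$radiusUm, dims, px)
  }
  rastFil <- function(df) {
    m <- matrix(FALSE, dims[1], dims[2])
    for (s in unique(df$seg)) {
      part <- df[df$seg == s, , drop = FALSE]
      if (nrow(part) >= 2)
        m <- m | .rasterizePolyline(part, attr(df, "widthPx"), dims, px)
    }
    m
  }
  filMasks <- lapply(filaments, rastFil)
  filMask <- Reduce(`|`, filMasks, matrix(FALSE, dims[1], dims[2]))

  ## ---- microspheres ----
  if (spec@matType == "microsphere" && spec@nSpheres > 0) {
    n <- as.integer(spec@nSpheres)
    objects <- addObjects(objects, "microsphere",
                          stats::runif(n, 0, W), stats::runif(n, 0, H),
                          rep(0.5, n))
  }

  ## ---- other bacteria, calibrated to the planted SRM area fraction ----
  f <- spec@srmAreaFractionTarget
  if (spec@matType != "microsphere" && !is.na(f) && f > 0) {
    srmMask <- rasterClass("srm")
    zone <- .depthBandMask(surfaceUm, layer, dims, px)
    srmZone <- sum(srmMask & zone)
    ## Filaments whose in-layer area would make the planted SRM share
    ## unattainable are placed below the layer instead (cyanobacteria
    ## occur throughout the upper mat, so deeper placement stays valid).
    if (length(filaments) && srmZone > 0) {
      budget <- 0.7 * srmZone * (100 / f - 1)
      cumF <- 0
      for (k in seq_along(filaments)) {
        zPx <- sum(filMasks[[k]] & !srmMask & zone)
        if (zPx > 0 && cumF + zPx > budget) {
          df <- filaments[[k]]
          minDepth <- min(df$yUm - surfFun(df$xUm))
          df$yUm <- pmin(df$yUm + (layer + 10 - minDepth), H - 2)
          filaments[[k]] <- df
          filMasks[[k]] <- rastFil(df)
          zPx <- sum(filMasks[[k]] & !srmMask & zone)
        }
        cumF <- cumF + zPx
      }
      filMask <- Reduce(`|`, filMasks, matrix(FALSE, dims[1], dims[2]))
    }
    filZone <- sum(filMask & !srmMask & zone)
    targetPx <- max(0, srmZone * 100 / f - srmZone - filZone)
    if (targetPx > 0 && srmZone > 0) {
      nPool <- max(60L, as.integer(ceiling(targetPx / 1.2) * 2))
      candX <- stats::runif(nPool, 0, W)
      candD <- stats::runif(nPool, 0, layer)
      cxy <- clampDepth(candX, candD, layer)
      candR <- .drawRadii(nPool, spec@cellRadiusMeanUm, spec@cellRadiusSdUm)
      occ <- srmMask | filMask
      cum <- 0
      kept <- 0L
      keepX <- numeric(nPool); keepY <- numeric(nPool); keepR <- numeric(nPool)
      for (k in seq_len(nPool)) {
        idx <- .diskPixels(cxy$x[k], cxy$y[k], candR[k], dims, px)
        newPx <- sum(!occ[idx] & zone[idx])
        occ[idx] <- TRUE
        cum <- cum + newPx
        kept <- kept + 1L
        keepX[kept] <- cxy$x[k]; keepY[kept] <- cxy$y[k]
        keepR[kept] <- candR[k]
        if (cum >= targetPx) break
      }
      objects <- addObjects(objects, "other", keepX[seq_len(kept)],
                            keepY[seq_len(kept)], keepR[seq_len(kept)])
      ## continue the community below the layer
      deepFactor <- if (spec@matType == "type1")
        (maxD - layer) / layer else 1
      nDeep <- round(kept * max(0, deepFactor))
      if (nDeep > 0) {
        ddx <- stats::runif(nDeep, 0, W)
        ddd <- stats::runif(nDeep, layer, max(maxD, layer + 1))
        dxy <- clampDepth(ddx, ddd, maxD)
        dxy$y <- pmax(dxy$y, surfFun(dxy$x) + layer + 0.5)
        dxy$y <- pmin(dxy$y, H - 0.5)
        objects <- addObjects(objects, "other", dxy$x, dxy$y,
                              .drawRadii(nDeep, spec@cellRadiusMeanUm,
                                         spec@cellRadiusSdUm))
      }
    }
  }

  ## ---- dimming flags ----
  dimFrac <- spec@noise$dimFraction
  if (nrow(objects) && dimFrac > 0)
    objects$dimmed <- stats::runif(nrow(objects)) < dimFrac
  if (length(filaments) && dimFrac > 0)
    for (k in seq_along(filaments))
      attr(filaments[[k]], "dimmed") <- stats::runif(1) < dimFrac

  ## ---- final truth masks ----
  masks <- list(
    srm = rasterClass("srm"),
    other = rasterClass("other"),
    filament = filMask,
    precipitate = rasterClass("precipitate"),
    ooid = rasterClass("ooid"),
    microsphere = rasterClass("microsphere"))

  rownames(objects) <- NULL
  new("GroundTruthScene", spec = spec, objects = objects,
      filaments = filaments, masks = masks, surfaceUm = surfaceUm,
      window = w)
}

#' Generate a microsphere dilution series
#'
#' Emulates the calibration experiment: five serial dilutions `c`, `c/2`,
#' `c/4`, `c/8`, `c/16` of 1.0 um fluorescent microspheres with five
#' replicate fields per dilution. Per-field counts are Poisson-distributed
#' around the dilution mean, and spheres may straddle field borders.
#'
#' @param baseCount expected spheres per field at the undiluted level `c`.
#' @param window a [Window-class].
#' @param noise noise model list passed to [sceneSpec()].
#' @param nReplicates replicate fields per dilution.
#' @param seed integer seed.
#' @return data.frame with one row per field (`dilution`, `dilutionFactor`,
#'   `replicate`, `knownCount`, `trueCount`) and the built scenes in the
#'   list column `scene`.
#' @export
makeMicrosphereSeries <- function(baseCount, window = imageWindow(),
                                  noise = list(), nReplicates = 5,
                                  seed = 1L) {
  stopifnot(baseCount >= 0)
  fac <- 2^(0:4)
  grid <- expand.grid(replicate = seq_len(nReplicates),
                      dilution = seq_along(fac))
  grid$dilutionFactor <- fac[grid$dilution]
  grid$knownCount <- baseCount / grid$dilutionFactor
  withr::with_seed(as.integer(seed), {
    grid$trueCount <- stats::rpois(nrow(grid), grid$knownCount)
    subseeds <- sample.int(.Machine$integer.max - 1, nrow(grid))
  })
  grid$scene <- lapply(seq_len(nrow(grid)), function(k) {
    buildScene(sceneSpec("microsphere", window = window,
                         nSpheres = grid$trueCount[k], noise = noise,
                         seed = subseeds[k]))
  })
  grid[c("dilution", "dilutionFactor", "replicate", "knownCount",
         "trueCount", "scene")]
}
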