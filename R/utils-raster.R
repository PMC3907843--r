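## Internal raster helpers shared by the generator and the classifiers.

## Pixel (i, j) centre in um: x = (j - 0.5) px, y = (i - 0.5) px.
.pixOfX <- function(xUm, px, n) pmin(pmax(ceiling(xUm / px), 1L), n)

## Truncated normal draw (rejection; bounds are a few sd wide, cheap).
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(numeric())
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

## Rasterize disks onto a logical matrix: a pixel is foreground when its
## centre lies within the disk. The pixel containing the centroid is always
## marked, so objects smaller than a pixel still occupy one pixel (the map
## calibration of 1.33 um/px makes 1-um cells sub-pixel).
.rasterizeDisks <- function(xUm, yUm, radiusUm, dimPx, px,
                            markCentroid = TRUE) {
  m <- matrix(FALSE, dimPx[1], dimPx[2])
  if (!length(xUm)) return(m)
  for (k in seq_along(xUm)) {
    r <- radiusUm[k]
    i0 <- max(1L, floor((yUm[k] - r) / px - 0.5) + 1L)
    i1 <- min(dimPx[1], ceiling((yUm[k] + r) / px + 0.5))
    j0 <- max(1L, floor((xUm[k] - r) / px - 0.5) + 1L)
    j1 <- min(dimPx[2], ceiling((xUm[k] + r) / px + 0.5))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    dy <- (ii - 0.5) * px - yUm[k]
    dx <- (jj - 0.5) * px - xUm[k]
    hit <- outer(dy^2, dx^2, `+`) <= r^2
    m[ii, jj] <- m[ii, jj] | hit
    if (markCentroid) {
      ic <- .pixOfX(yUm[k], px, dimPx[1]); jc <- .pixOfX(xUm[k], px, dimPx[2])
      m[ic, jc] <- TRUE
    }
  }
  m
}

## Rasterize a polyline of vertices (xUm, yUm) with a stroke width given in
## pixels: points are sampled densely along the segments and pixels whose
## centre lies within half the stroke width are marked.
.rasterizePolyline <- function(verts, widthPx, dimPx, px) {
  m <- matrix(FALSE, dimPx[1], dimPx[2])
  if (nrow(verts) < 2) return(m)
  half <- widthPx * px / 2
  rad <- ceiling(half / px) + 1L
  step <- px / 3
  for (s in seq_len(nrow(verts) - 1)) {
    p0 <- c(verts$xUm[s], verts$yUm[s])
    p1 <- c(verts$xUm[s + 1], verts$yUm[s + 1])
    len <- sqrt(sum((p1 - p0)^2))
    if (len == 0) next
    tt <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
    xs <- p0[1] + tt * (p1[1] - p0[1])
    ys <- p0[2] + tt * (p1[2] - p0[2])
    for (k in seq_along(xs)) {
      ic <- .pixOfX(ys[k], px, dimPx[1]); jc <- .pixOfX(xs[k], px, dimPx[2])
      ii <- max(1L, ic - rad):min(dimPx[1], ic + rad)
      jj <- max(1L, jc - rad):min(dimPx[2], jc + rad)
      dy <- (ii - 0.5) * px - ys[k]
      dx <- (jj - 0.5) * px - xs[k]
      hit <- outer(dy^2, dx^2, `+`) <= half^2
      m[ii, jj] <- m[ii, jj] | hit
      m[ic, jc] <- TRUE
    }
  }
  m
}

## 8-connected component labelling of a logical matrix. EBImage::bwlabel is
## 4-connected, and the counting rules here are defined on 8-connectivity,
## so labelling is done over a sparse neighbour graph instead.
.label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (!length(fg)) return(lab)
  rank <- integer(nr * nc)
  rank[fg] <- seq_along(fg)
  i <- ((fg - 1L) %% nr) + 1L
  j <- ((fg - 1L) %/% nr) + 1L
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    ni <- i + off[1]; nj <- j + off[2]
    ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
    nidx <- (nj[ok] - 1L) * nr + ni[ok]
    hit <- rank[nidx] > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(rank[fg[ok]][hit], rank[nidx][hit]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::graph_from_edgelist(rbind(edges, cbind(seq_along(fg),
                                                        seq_along(fg))),
                                     directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(fg)]
  ## relabel in first-appearance (column-major raster) order for determinism
  first <- !duplicated(comp)
  relab <- integer(max(comp))
  relab[comp[first]] <- seq_len(sum(first))
  lab[fg] <- relab[comp]
  lab
}

## Per-label summaries of a labelled raster.
.labelStats <- function(lab, px) {
  fg <- which(lab > 0L)
  if (!length(fg))
    return(data.frame(label = integer(), areaUm2 = numeric(),
                      xUm = numeric(), yUm = numeric(),
                      borderFlag = logical()))
  nr <- nrow(lab)
  i <- ((fg - 1L) %% nr) + 1L
  j <- ((fg - 1L) %/% nr) + 1L
  l <- lab[fg]
  npx <- tabulate(l)
  xs <- vapply(split((j - 0.5) * px, l), mean, numeric(1))
  ys <- vapply(split((i - 0.5) * px, l), mean, numeric(1))
  border <- i == 1L | i == nr | j == 1L | j == ncol(lab)
  bflag <- vapply(split(border, l), any, logical(1))
  data.frame(label = seq_along(npx), areaUm2 = npx * px^2,
             xUm = unname(xs), yUm = unname(ys),
             borderFlag = unname(bflag))
}

.asBinary <- function(mask) {
  if (is(mask, "Image")) mask <- EBImage::imageData(mask)
  storage.mode(mask) <- "logical"
  mask
}
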