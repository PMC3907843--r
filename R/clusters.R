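#' Detect cell clusters by concentric-region overlap (buffer dissolve)
#'
#' A concentric region (disk) of the stated diameter is generated around
#' each cell; two cells are linked when their regions overlap, i.e. when
#' their centroid distance is strictly less than the region diameter, and
#' a cluster is a connected component of the link graph. A cluster is
#' *selected* when it contains strictly more than `minCells` members
#' (greater than five cells under the defaults). The cluster area is the
#' area of the dissolved union of its member disks; when cell radii are
#' supplied, the summed cell-footprint area is reported alongside.
#'
#' @param cells data.frame with `xUm`, `yUm` and optionally `radiusUm`.
#' @param regionDiameterUm concentric-region diameter, micrometres.
#' @param minCells strict member-count threshold for selection.
#' @param dissolveResolutionUm raster resolution used to measure the
#'   dissolved disk-union area.
#' @return a [ClusterSet-class]; empty input yields an empty set.
#' @export
detectClusters <- function(cells, regionDiameterUm = 10, minCells = 5,
                           dissolveResolutionUm = regionDiameterUm / 50) {
  stopifnot(regionDiameterUm > 0)
  n <- nrow(cells)
  emptyClusters <- data.frame(cluster = integer(), nCells = integer(),
                              areaUm2 = numeric(),
                              footprintAreaUm2 = numeric(),
                              xUm = numeric(), yUm = numeric(),
                              selected = logical())
  if (is.null(n) || n == 0)
    return(new("ClusterSet",
               points = data.frame(xUm = numeric(), yUm = numeric()),
               membership = integer(), clusters = emptyClusters,
               regionDiameterUm = regionDiameterUm, minCells = minCells))
  d <- as.matrix(stats::dist(cbind(cells$xUm, cells$yUm)))
  adj <- d < regionDiameterUm
  diag(adj) <- FALSE
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges))
    g <- igraph::graph_from_edgelist(
      rbind(edges, cbind(seq_len(n), seq_len(n))), directed = FALSE)
  comp <- igraph::components(g)$membership[seq_len(n)]
  first <- !duplicated(comp)
  relab <- integer(max(comp))
  relab[comp[first]] <- seq_len(sum(first))
  member <- relab[comp]

  rr <- regionDiameterUm / 2
  res <- dissolveResolutionUm
  clusters <- do.call(rbind, lapply(seq_len(max(member)), function(cid) {
    idx <- which(member == cid)
    x <- cells$xUm[idx]; y <- cells$yUm[idx]
    ## dissolved union of member disks on a fine local grid
    gx <- seq(min(x) - rr - res, max(x) + rr + res, by = res)
    gy <- seq(min(y) - rr - res, max(y) + rr + res, by = res)
    inU <- matrix(FALSE, length(gy), length(gx))
    for (k in seq_along(idx)) {
      jj <- which(abs(gx - x[k]) <= rr + res)
      ii <- which(abs(gy - y[k]) <= rr + res)
      inU[ii, jj] <- inU[ii, jj] |
        (outer((gy[ii] - y[k])^2, (gx[jj] - x[k])^2, `+`) <= rr^2)
    }
    fp <- if (!is.null(cells$radiusUm))
      sum(pi * cells$radiusUm[idx]^2) else NA_real_
    data.frame(cluster = cid, nCells = length(idx),
               areaUm2 = sum(inU) * res^2, footprintAreaUm2 = fp,
               xUm = mean(x), yUm = mean(y),
               selected = length(idx) > minCells)
  }))
  new("ClusterSet",
      points = data.frame(xUm = cells$xUm, yUm = cells$yUm),
      membership = as.integer(member), clusters = clusters,
      regionDiameterUm = regionDiameterUm, minCells = minCells)
}
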