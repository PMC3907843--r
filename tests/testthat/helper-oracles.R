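## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths (igraph components, EBImage distmap, the
## vectorized ring counting) so that agreement is meaningful.

## Plain union-find over the pairwise distance matrix.
unionFindClusters <- function(points, diameterUm = 10) {
  n <- nrow(points)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        dij <- sqrt((points$xUm[i] - points$xUm[j])^2 +
                    (points$yUm[i] - points$yUm[j])^2)
        if (dij < diameterUm) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

## Literal double-loop pair correlation (translation edge correction,
## annulus ring area), one radius at a time.
pcfOracle <- function(pa, pb = NULL, W, H, rGrid, w) {
  auto <- is.null(pb)
  if (auto) pb <- pa
  nA <- nrow(pa); nB <- nrow(pb)
  A <- W * H
  vapply(rGrid, function(r) {
    lo <- max(0, r - w / 2); hi <- r + w / 2
    ring <- pi * (hi^2 - lo^2)
    acc <- 0
    for (i in seq_len(nA)) {
      for (j in seq_len(nB)) {
        if (auto && i == j) next
        dx <- pa$xUm[i] - pb$xUm[j]
        dy <- pa$yUm[i] - pb$yUm[j]
        d <- sqrt(dx^2 + dy^2)
        if (d >= lo && d <= hi) {
          cij <- ((W - abs(dx)) * (H - abs(dy))) / (W * H)
          acc <- acc + 1 / cij
        }
      }
    }
    (A / (nA * (if (auto) nB - 1 else nB))) * acc / ring
  }, numeric(1))
}

## Brute-force min distance from each pixel of each labelled object to any
## precipitate pixel (pixel-centre metric, in um).
minDistOracle <- function(lab, precip, px) {
  pidx <- which(precip)
  nr <- nrow(precip)
  pi_ <- ((pidx - 1L) %% nr) + 1L
  pj <- ((pidx - 1L) %/% nr) + 1L
  out <- numeric(max(lab))
  for (l in seq_len(max(lab))) {
    oidx <- which(lab == l)
    oi <- ((oidx - 1L) %% nr) + 1L
    oj <- ((oidx - 1L) %/% nr) + 1L
    best <- Inf
    for (k in seq_along(oidx))
      best <- min(best, sqrt((oi[k] - pi_)^2 + (oj[k] - pj)^2))
    out[l] <- best * px
  }
  out
}

## Disk on a pixel grid by the same centre-in-disk rule the package uses.
diskMask <- function(nr, nc, iC, jC, rPx) {
  ii <- matrix(seq_len(nr), nr, nc)
  jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (ii - iC)^2 + (jj - jC)^2 <= rPx^2
}
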