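flatSurface <- function(rowPx, nCol, nRow) {
  m <- matrix(FALSE, nRow, nCol)
  m[rowPx:nRow, ] <- TRUE
  detectSurface(m, smoothWindowPx = 1)
}

test_that("buffer zone spans 100 rows for 133 um at the map calibration", {
  px <- 682.67 / 512
  sl <- flatSurface(1, 64, 512)
  zone <- bufferZone(sl, 133, px)
  expect_equal(unname(colSums(zone)), rep(100, 64))
  expect_true(all(zone[1:100, ]) && !any(zone[101:512, ]))

  ## zones deeper than the image clip at the bottom
  sl2 <- flatSurface(400, 64, 512)
  zone2 <- bufferZone(sl2, 500, px)
  expect_true(all(zone2[400:512, ]) && !any(zone2[1:399, ]))

  ## shifted surface => equally shifted zone
  sl3 <- flatSurface(41, 64, 512)
  zone3 <- bufferZone(sl3, 133, px)
  expect_identical(zone3[41:140, ], zone[1:100, ])
  expect_false(any(zone3[1:40, ]))
})

test_that("SRM area fraction handles full, empty and undefined zones", {
  srm <- matrix(FALSE, 50, 50); srm[10:20, 10:20] <- TRUE
  zone <- matrix(TRUE, 50, 50)
  cmAll <- classMasks(list(srm = srm, other = srm & FALSE), 1)
  expect_equal(areaFractionSRM(cmAll, zone), 100)
  cmNone <- classMasks(list(srm = srm & FALSE, other = srm), 1)
  expect_equal(areaFractionSRM(cmNone, zone), 0)
  cmEmpty <- classMasks(list(srm = srm & FALSE, other = srm & FALSE), 1)
  expect_warning(res <- areaFractionSRM(cmEmpty, zone), "undefined")
  expect_true(is.na(res))
})

test_that("vertical profiles report exact planted depth splits", {
  sl <- flatSurface(1, 100, 400)
  px <- 1
  ## all cells at depth 0
  cells0 <- data.frame(xUm = runif(20, 0, 100), yUm = rep(0.5, 20))
  prof0 <- verticalProfile(cells0, sl, px, binUm = 10, maxDepthUm = 400)
  expect_equal(prof0$cumulative[1], 1)

  ## planted 90/10 split above/below 130 um
  ## surface sits at the centre of row 1 (0.5 um): plant depths below it
  cells <- data.frame(xUm = runif(100, 0, 100),
                      yUm = 0.5 + c(runif(90, 0, 129), runif(10, 140, 389)))
  expect_equal(topLayerFraction(cells, sl, px, topDepthUm = 130,
                                maxDepthUm = 400), 0.9)
  ## cells below maxDepth are excluded from the denominator
  cellsDeep <- rbind(cells, data.frame(xUm = 1, yUm = 399))
  expect_equal(topLayerFraction(cellsDeep, sl, px, topDepthUm = 130,
                                maxDepthUm = 395), 0.9)
  expect_error(verticalProfile(data.frame(xUm = 1, yUm = 399), sl, px,
                               maxDepthUm = 100), "undefined")
})

test_that("cluster detection applies the strict more-than-five rule", {
  ## isolated cells, pairwise > 10 um apart
  iso <- data.frame(xUm = seq(0, 120, by = 12), yUm = rep(5, 11))
  clIso <- detectClusters(iso)
  expect_equal(nrow(clusterTable(clIso)), 11)
  expect_false(any(clusterTable(clIso)$selected))

  ## chain of 6 at 5 um spacing: one selected cluster
  chain6 <- data.frame(xUm = seq(0, 25, by = 5), yUm = rep(0, 6))
  cl6 <- detectClusters(chain6)
  expect_equal(nrow(clusterTable(cl6)), 1)
  expect_true(clusterTable(cl6)$selected)

  ## chain of 5: linked but not selected
  chain5 <- chain6[1:5, ]
  cl5 <- detectClusters(chain5)
  expect_equal(nrow(clusterTable(cl5)), 1)
  expect_false(clusterTable(cl5)$selected)

  ## empty input
  empty <- detectClusters(data.frame(xUm = numeric(), yUm = numeric()))
  expect_equal(nrow(clusterTable(empty)), 0)
})

test_that("cluster memberships match the union-find oracle", {
  for (s in 1:20) {
    set.seed(900 + s)
    n <- sample(20:60, 1)
    pts <- data.frame(xUm = runif(n, 0, 120), yUm = runif(n, 0, 120))
    got <- memberships(detectClusters(pts))
    want <- unionFindClusters(pts, 10)
    ## identical partitions: same co-membership for every pair of cells
    expect_identical(outer(got, got, `==`), outer(want, want, `==`))
  }
})

test_that("dissolved cluster areas approximate the disk union", {
  one <- detectClusters(data.frame(xUm = 20, yUm = 20))
  expect_lt(abs(clusterTable(one)$areaUm2 - pi * 25) / (pi * 25), 0.03)
  ## two fully overlapping cells: area stays one disk
  two <- detectClusters(data.frame(xUm = c(20, 20), yUm = c(20, 20)))
  expect_lt(abs(clusterTable(two)$areaUm2 - pi * 25) / (pi * 25), 0.03)
  ## footprint areas recorded when radii are given
  wr <- detectClusters(data.frame(xUm = c(0, 3), yUm = c(0, 0),
                                  radiusUm = c(0.5, 0.5)))
  expect_equal(clusterTable(wr)$footprintAreaUm2, 2 * pi * 0.25)
})

test_that("pair correlation equals the brute-force oracle on fixed points", {
  set.seed(5)
  pts <- data.frame(xUm = runif(10, 0, 50), yUm = runif(10, 0, 50))
  w <- imageWindow(50, 50, 1)
  rGrid <- seq(0.5, 6, by = 0.5)
  got <- pcfTable(pairCorrelation(pts, window = w, rGrid = rGrid,
                                  ringWidthUm = 0.5))$g
  want <- pcfOracle(pts, NULL, 50, 50, rGrid, 0.5)
  expect_equal(got, want, tolerance = 1e-12)

  ## cross-correlation against a second set
  ptsB <- data.frame(xUm = runif(8, 0, 50), yUm = runif(8, 0, 50))
  gotX <- pcfTable(pairCorrelation(pts, ptsB, window = w, rGrid = rGrid,
                                   ringWidthUm = 0.5))$g
  wantX <- pcfOracle(pts, ptsB, 50, 50, rGrid, 0.5)
  expect_equal(gotX, wantX, tolerance = 1e-12)

  expect_error(pairCorrelation(pts[1, , drop = FALSE]), "at least 2")
})

test_that("CSR patterns stay near g = 1 and inside their envelope", {
  gbar <- vapply(1:10, function(s) {
    p <- simulatePointPattern(pointPatternSpec("csr", nPoints = 300,
                                               seed = 300 + s))
    mean(pcfTable(pairCorrelation(p))$g, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(gbar) - 1), 0.2)

  ## a dense CSR pattern stays within its own 39-sim envelope at most radii
  p <- simulatePointPattern(pointPatternSpec(
    "csr", window = imageWindow(200, 200, 1), nPoints = 400, seed = 9))
  tb <- pcfTable(pairCorrelation(p, window = imageWindow(200, 200, 1),
                                 envelopeSims = 39, seed = 10))
  frac <- mean(tb$g > tb$envHi | tb$g < tb$envLo, na.rm = TRUE)
  expect_lte(frac, 0.1)
})

test_that("Thomas patterns exceed the CSR envelope at small distances", {
  w <- imageWindow(300, 300, 1)
  p <- simulatePointPattern(pointPatternSpec(
    "thomas", window = w, kappa = 5e-4, mu = 10, sigmaUm = 2, seed = 6))
  tb <- pcfTable(pairCorrelation(p, window = w, envelopeSims = 19,
                                 seed = 7))
  sm <- tb$rUm >= 1 & tb$rUm <= 3
  expect_gt(sum(tb$g[sm], na.rm = TRUE), sum(tb$envHi[sm], na.rm = TRUE))
})

test_that("proximity fractions follow threshold arithmetic", {
  px <- 1
  precip <- matrix(FALSE, 40, 40); precip[20, 20] <- TRUE
  srm <- matrix(FALSE, 40, 40); srm[20, 21] <- TRUE   # 1 um away
  other <- matrix(FALSE, 40, 40)
  res <- proximityTable(proximityFractions(srm, other, precip, px))
  expect_equal(res$percentSrm, rep(100, 3))

  ## SRM at 2 um: excluded at 1.1, included at 2.2 and 4.4
  srm2 <- matrix(FALSE, 40, 40); srm2[20, 22] <- TRUE
  other2 <- matrix(FALSE, 40, 40); other2[20, 19] <- TRUE  # 1 um away
  res2 <- proximityTable(proximityFractions(srm2, other2, precip, px))
  expect_equal(res2$srmNear, c(0, 1, 1))
  expect_equal(res2$percentSrm, c(0, 50, 50))

  ## no precipitates: undefined
  res3 <- proximityTable(proximityFractions(srm, other,
                                            precip & FALSE, px))
  expect_true(all(!res3$defined))
})

test_that("object distances equal the brute-force pixel minima", {
  for (s in 1:5) {
    set.seed(700 + s)
    precip <- matrix(runif(900) < 0.03, 30, 30)
    if (!any(precip)) next
    cells <- matrix(runif(900) < 0.06, 30, 30) & !precip
    got <- sort(objectMinDistances(cells, precip, 1.5))
    lab <- matmicrospat:::.label8(cells)
    want <- sort(minDistOracle(lab, precip, 1.5))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("near counts are monotone in the threshold", {
  set.seed(12)
  precip <- matrix(runif(2500) < 0.02, 50, 50)
  srm <- matrix(runif(2500) < 0.05, 50, 50) & !precip
  other <- matrix(runif(2500) < 0.05, 50, 50) & !precip & !srm
  tb <- proximityTable(proximityFractions(srm, other, precip, 1.3,
                                          thresholdsUm = c(1, 2, 4, 8, 16)))
  expect_false(is.unsorted(tb$srmNear))
  expect_false(is.unsorted(tb$otherNear))
})
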