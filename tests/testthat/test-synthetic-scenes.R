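test_that("CSR patterns honour fixed counts, the window, and the seed", {
  spec <- pointPatternSpec("csr", nPoints = 300, seed = 11)
  p <- simulatePointPattern(spec)
  expect_identical(nrow(p), 300L)
  w <- spec@window
  expect_true(all(p$xUm >= 0 & p$xUm <= w@widthUm))
  expect_true(all(p$yUm >= 0 & p$yUm <= w@heightUm))
  expect_identical(p, simulatePointPattern(spec))
  expect_error(pointPatternSpec("csr", intensity = -1), "intensity")
  expect_error(pointPatternSpec("thomas", kappa = 0, mu = 5, sigmaUm = 1),
               "kappa")
})

test_that("Thomas mean count matches the Poisson-mean oracle", {
  ## E[N] = kappa * mu * A; compare the replicate mean within 3 SE
  kappa <- 5e-4; mu <- 10
  counts <- vapply(1:200, function(s) {
    nrow(simulatePointPattern(pointPatternSpec(
      "thomas", kappa = kappa, mu = mu, sigmaUm = 2, seed = 7000 + s)))
  }, numeric(1))
  expected <- kappa * mu * 682.67^2
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("Thomas empirical pair correlation approaches its closed form", {
  kappa <- 5e-4; sigma <- 2
  w <- imageWindow(300, 300, 1)
  rGrid <- seq(0.5, 3, by = 0.5)
  gMat <- t(vapply(1:30, function(s) {
    p <- simulatePointPattern(pointPatternSpec(
      "thomas", window = w, kappa = kappa, mu = 10, sigmaUm = sigma,
      seed = 8000 + s))
    pcfTable(pairCorrelation(p, window = w, rGrid = rGrid))$g
  }, numeric(length(rGrid))))
  gBar <- colMeans(gMat)
  gTheory <- thomasPcf(rGrid, kappa, sigma)
  expect_lt(max(abs(gBar - gTheory) / gTheory), 0.15)
})

test_that("type2 scenes confine SRM to the surface layer", {
  for (s in c(31, 32)) {
    sc <- buildScene(sceneSpec("type2", seed = s))
    frac <- topLayerFraction(
      sceneObjects(sc)[sceneObjects(sc)$class == "srm", ],
      trueSurface(sc), pixelSize(sc), topDepthUm = 130)
    expect_gte(frac, 0.85)
  }
})

test_that("planted type1 SRM area fraction is recovered from truth masks", {
  sc <- buildScene(sceneSpec("type1", seed = 41))
  m <- truthMasks(sc)
  px <- pixelSize(sc)
  zone <- bufferZone(trueSurface(sc), 130, px)
  total <- (m$srm | m$other | m$filament) & zone
  frac <- 100 * sum(m$srm & zone) / sum(total)
  expect_lt(abs(frac - 20.7), 3)
})

test_that("zero cell densities give an empty scene", {
  sc <- buildScene(sceneSpec("type1", nSrm = 0, nFilaments = 0,
                             nPrecipPatches = 0, nOoids = 0,
                             srmNearPrecipFraction = 0, seed = 1))
  expect_identical(nrow(sceneObjects(sc)), 0L)
  expect_true(all(vapply(truthMasks(sc), sum, numeric(1)) == 0))
  sc0 <- buildScene(sceneSpec("microsphere", nSpheres = 0, seed = 1))
  expect_identical(nrow(sceneObjects(sc0)), 0L)
})

test_that("scene specs reject impossible targets", {
  expect_error(sceneSpec("type1", srmAreaFractionTarget = 130), "100")
  expect_error(sceneSpec("type2", srmNearPrecipFraction = 1.5), "\\[0, 1\\]")
})

test_that("rendering places the peak on the planted centroid", {
  sc <- buildScene(sceneSpec("microsphere", nSpheres = 1,
                             noise = list(snr = Inf, background = 0,
                                          dimFraction = 0),
                             seed = 5))
  img <- renderScene(sc)
  ch <- getChannel(img, "probe")
  px <- pixelSize(img)
  o <- sceneObjects(sc)
  peak <- which(ch == max(ch), arr.ind = TRUE)[1, ]
  expect_lte(abs(peak["row"] - (o$yUm / px + 0.5)), 0.5 + 1e-9)
  expect_lte(abs(peak["col"] - (o$xUm / px + 0.5)), 0.5 + 1e-9)
})

test_that("noiseless unblurred renders reproduce footprint areas", {
  w <- imageWindow(100, 100, 0.2)
  sc <- buildScene(sceneSpec("microsphere", window = w, nSpheres = 12,
                             noise = list(snr = Inf, background = 0,
                                          blurSigmaPx = 0, dimFraction = 0),
                             seed = 9))
  img <- renderScene(sc)
  fg <- getChannel(img, "probe") > 0.5
  truth <- truthMasks(sc)$microsphere
  expect_identical(fg, truth)
  ## truth-mask area vs analytic footprint area, within one boundary-pixel
  ## band per object (non-overlapping placements)
  o <- sceneObjects(sc)
  analyticPx <- sum(pi * o$radiusUm^2) / 0.2^2
  boundaryPx <- sum(2 * pi * o$radiusUm / 0.2) + nrow(o)
  expect_lt(abs(sum(truth) - analyticPx), boundaryPx)
})

test_that("a fixed seed reproduces scenes and images bit-identically", {
  s1 <- buildScene(sceneSpec("type2", seed = 77))
  s2 <- buildScene(sceneSpec("type2", seed = 77))
  expect_identical(sceneObjects(s1), sceneObjects(s2))
  expect_identical(truthMasks(s1), truthMasks(s2))
  expect_identical(renderScene(s1)@channels, renderScene(s2)@channels)
})

test_that("microsphere dilution series follows c, c/2, ..., c/16", {
  ser0 <- makeMicrosphereSeries(0, seed = 1)
  expect_true(all(ser0$trueCount == 0))
  ser <- makeMicrosphereSeries(160, nReplicates = 40, seed = 3)
  expect_equal(unique(ser$knownCount), 160 / c(1, 2, 4, 8, 16))
  ## replicate means within 3 SE of the Poisson mean
  for (k in 1:5) {
    m <- ser$knownCount[ser$dilution == k][1]
    x <- ser$trueCount[ser$dilution == k]
    expect_lt(abs(mean(x) - m), 3 * sqrt(m / length(x)))
  }
  ## rendered spheres may straddle borders: truth masks are clipped inside
  sc <- ser$scene[[1]]
  expect_true(all(dim(truthMasks(sc)$microsphere) ==
                    windowDim(sc@window)))
})
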