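makeImage <- function(probe, counter = probe * 0, refl = probe * 0, px = 1) {
  calibratedImage(list(probe = probe, counterstain = counter,
                       reflectance = refl), px)
}

test_that("minimum-distance classification assigns blobs and background", {
  probe <- matrix(0, 20, 20)
  probe[5:8, 5:8] <- 1
  img <- makeImage(probe)
  train <- list(
    srm = data.frame(probe = 1, counterstain = 0, reflectance = 0),
    background = data.frame(probe = 0, counterstain = 0, reflectance = 0))
  cm <- classifySupervised(img, train)
  expect_identical(getMask(cm, "srm"), probe == 1)
  ## a pixel equal to a background training sample goes to background
  expect_true(getMask(cm, "background")[1, 1])
  expect_error(classifySupervised(img, train["srm"]), "background")
})

test_that("supervised classification is invariant to uniform scaling", {
  sc <- buildScene(sceneSpec("type2", seed = 51))
  img <- renderScene(sc)
  tm <- truthMasks(sc)
  train <- sampleTrainingPixels(img, list(
    srm = tm$srm, bacteria = tm$other | tm$filament,
    precipitate = tm$precipitate | tm$ooid), nPerClass = 60, seed = 8)
  cm1 <- classifySupervised(img, train)
  imgS <- calibratedImage(lapply(img@channels, function(ch) ch * 7.3),
                          pixelSize(img))
  trainS <- lapply(train, function(tp) tp * 7.3)
  cm2 <- classifySupervised(imgS, trainS)
  expect_identical(maskList(cm1), maskList(cm2))
})

test_that("noiseless renders are classified back to their truth masks", {
  w <- imageWindow(120, 120, 0.5)
  sc <- buildScene(sceneSpec("microsphere", window = w, nSpheres = 25,
                             noise = list(snr = Inf, background = 0,
                                          blurSigmaPx = 0, dimFraction = 0),
                             seed = 13))
  img <- renderScene(sc)
  truth <- truthMasks(sc)$microsphere
  train <- sampleTrainingPixels(img, list(srm = truth), nPerClass = 30,
                                seed = 3)
  cm <- classifySupervised(img, train)
  expect_identical(getMask(cm, "srm"), truth)
})

test_that("supervised pixel accuracy on a noisy type2 render exceeds 95%", {
  sc <- buildScene(sceneSpec("type2", seed = 21))
  img <- renderScene(sc)
  tm <- truthMasks(sc)
  train <- sampleTrainingPixels(img, list(
    srm = tm$srm, bacteria = tm$other | tm$filament,
    precipitate = tm$precipitate | tm$ooid), nPerClass = 80, seed = 2)
  cm <- classifySupervised(img, train)
  truthLab <- matrix("background", nrow(tm$srm), ncol(tm$srm))
  truthLab[tm$other | tm$filament] <- "bacteria"
  truthLab[tm$precipitate | tm$ooid] <- "precipitate"
  truthLab[tm$srm] <- "srm"
  predLab <- matrix("background", nrow(tm$srm), ncol(tm$srm))
  for (nm in c("bacteria", "precipitate", "srm"))
    predLab[getMask(cm, nm)] <- nm
  expect_gte(mean(predLab == truthLab), 0.95)
})

test_that("two-class clustering thresholds bimodal intensities", {
  set.seed(31)
  ch <- matrix(c(rnorm(5000, 0.1, 0.02), rnorm(800, 0.9, 0.02)), 58, 100)
  fg <- classifyTwoClass(ch)
  expect_identical(fg, ch > 0.5)
  expect_error(classifyTwoClass(matrix(1, 5, 5)), "constant")
})

test_that("two-class clustering approaches the Bayes rule on a balanced mixture", {
  ## equal-weight Gaussians mu = 30/200, sigma = 15: Bayes threshold 115
  set.seed(77)
  n <- 40000
  lab <- rep(c(FALSE, TRUE), each = n / 2)
  v <- ifelse(lab, rnorm(n, 200, 15), rnorm(n, 30, 15))
  fg <- classifyTwoClass(matrix(v, 200, 200))
  rate <- mean(as.vector(fg) != lab)
  bayesRate <- mean((v > 115) != lab)
  expect_lt(abs(rate - bayesRate), 0.02)
})

test_that("filament subtraction separates lines from blobs and bridges gaps", {
  px <- 0.5
  m <- matrix(FALSE, 120, 160)
  m[60:61, 20:120] <- TRUE              # 50 um straight line, 2 px wide
  m[20:21, 30:31] <- TRUE               # ~1 um blob
  m[100:102, 100:102] <- TRUE           # another blob
  out <- subtractFilaments(m, pixelSizeUm = px)
  expect_true(all(out$filament[60:61, 20:120]))
  expect_false(any(out$filament[20:21, 30:31]))
  expect_true(all(out$residual[100:102, 100:102]))
  ## partition contract
  expect_identical(out$filament | out$residual, m)
  expect_false(any(out$filament & out$residual))

  ## dashed line, 2 um gaps, bridged at maxGap 3 um
  d <- matrix(FALSE, 60, 200)
  for (s in seq(10, 180, by = 14)) d[30, s:(s + 9)] <- TRUE  # 5 um dashes
  out2 <- subtractFilaments(d, pixelSizeUm = px, maxGapUm = 3)
  expect_identical(out2$filament, d)
})

test_that("co-localization keeps whole objects by overlap fraction", {
  probe <- matrix(FALSE, 30, 30)
  probe[5:14, 5:6] <- TRUE              # object of 20 px
  counter <- matrix(FALSE, 30, 30)
  expect_identical(colocalize(probe, probe), probe)
  expect_false(any(colocalize(probe, counter)))
  counter[5:14, 5] <- TRUE              # 50% overlap
  expect_identical(colocalize(probe, counter, 0.5), probe)
  counter2 <- matrix(FALSE, 30, 30)
  counter2[5:12, 5] <- TRUE             # 40% overlap
  expect_false(any(colocalize(probe, counter2, 0.5)))
  counter3 <- matrix(FALSE, 30, 30)
  counter3[5:14, 5] <- TRUE; counter3[5:10, 6] <- TRUE  # 80%
  expect_identical(colocalize(probe, counter3, 0.5), probe)
})

test_that("counting rule pools fragments and keeps whole objects", {
  px <- 1
  m <- matrix(FALSE, 60, 140)
  for (k in 0:6) m[10:13, (5 + k * 18):(8 + k * 18)] <- TRUE  # 7 squares
  seg <- segmentAndCount(m, typicalObjectAreaUm2 = 16, pixelSizeUm = px)
  expect_equal(countEstimate(seg), 7)
  expect_equal(nrow(objectTable(seg)), 7)

  ## two half objects at opposite borders sum to one
  h <- matrix(FALSE, 40, 40)
  h[1:2, 10:13] <- TRUE                 # 8 px at top border
  h[39:40, 25:28] <- TRUE               # 8 px at bottom border
  seg2 <- segmentAndCount(h, typicalObjectAreaUm2 = 16, pixelSizeUm = px)
  expect_equal(countEstimate(seg2), 1)
})

test_that("counting rule bounds hold on random masks", {
  for (s in 1:10) {
    set.seed(200 + s)
    m <- matrix(runif(40 * 40) < 0.12, 40, 40)
    seg <- segmentAndCount(m, typicalObjectAreaUm2 = 3, pixelSizeUm = 1)
    tb <- objectTable(seg)
    expect_lte(countEstimate(seg), nrow(tb))
    expect_gte(countEstimate(seg), sum(tb$fullSize))
  }
})

test_that("microsphere fields at SNR 10 are counted within 5%", {
  sc <- buildScene(sceneSpec("microsphere", nSpheres = 200, seed = 101))
  img <- renderScene(sc)
  fg <- classifyTwoClass(getChannel(img, "probe"))
  seg <- segmentAndCount(fg, typicalObjectAreaUm2 = pi * 0.25,
                         pixelSizeUm = pixelSize(img))
  expect_lt(abs(countEstimate(seg) - 200) / 200, 0.05)
})
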