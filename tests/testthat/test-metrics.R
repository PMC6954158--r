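test_that("CRmax of the unblurred truth is exactly one", {
  ph <- singleSpherePhantom()
  vol <- rasterizeTruth(ph, smallGrid(), supersample = 1)
  sp <- phantomSpheres(ph)[[1]]
  expect_equal(crMax(vol, sp, trueAc = 24.4), 1.0)
  ## locality: an extra sphere far away leaves CRmax unchanged
  sp2 <- SphereSpec("x", 8.5, 1, c(40, 0, 0))
  ph2 <- new("PhantomDefinition", spheres = list(phantomSpheres(ph)[[1]], sp2),
             bodyRadius = 55, bodyLength = 110, bodyCenter = c(0, 0, 0),
             backgroundVoiCenter = c(0, 0, 30), backgroundVoiVolume = 5,
             activity = ActivityConfig(24.4, 3.1))
  vol2 <- rasterizeTruth(ph2, smallGrid(), supersample = 1)
  expect_equal(crMax(vol2, sp, 24.4), crMax(vol, sp, 24.4))
  ## clipped search ball errors
  expect_error(crMax(vol, SphereSpec("e", 8.5, 1, c(55, 0, 0)), 24.4),
               "clipped")
})

test_that("heavy blur at low contrast pulls CRmax below one", {
  sp <- nemaSpheres()[[6]]  # 10 mm
  sp@center <- c(0, 0, 0)
  ph <- singleSpherePhantom(sp, sphereAc = 7.5, backgroundAc = 3.9)
  vol <- rasterizeTruth(ph, smallGrid(), supersample = 4)
  bl <- applyReconSignature(vol, ReconPreset("t", blurFwhm = 8.2))
  expect_lt(crMax(bl, sp, 7.5), 1)
})

test_that("peak VOI on a uniform image returns the constant, centered", {
  g <- smallGrid()
  flat <- ImageVolume(array(4.2, dim = gridShape(g)), g)
  sp <- SphereSpec("17", 8.5, 1, c(0, 0, 0))
  pk <- peakVoiMean(flat, sp)
  expect_equal(pk$mean, 4.2, tolerance = 1e-9)
  ## tie broken toward the nominal sphere center
  expect_lt(sqrt(sum(pk$center^2)), min(gridSpacing(g)) / 2)
  expect_equal(crPeak(flat, sp, trueAc = 4.2), 1.0, tolerance = 1e-9)
})

test_that("peak VOI centers on a symmetric blurred sphere", {
  ph <- iecPhantom()
  vol <- rasterizeTruth(ph, defaultGrid(), supersample = 4)
  bl <- applyReconSignature(vol, ReconPreset("t", blurFwhm = 4.2))
  sp <- phantomSpheres(ph)[[1]]
  pk <- peakVoiMean(bl, sp)
  expect_lt(sqrt(sum((pk$center - sphereCenter(sp))^2)), 2)
  ## large blurred sphere: the 12-mm VOI nearly reaches full recovery
  cr <- pk$mean / 24.4
  expect_gt(cr, 0.9)
  expect_lt(cr, 1.01)
})

test_that("subdivided-lattice peak search matches a 0.25-mm oracle", {
  ## small case so the exhaustive oracle stays tractable
  sp <- SphereSpec("6", innerRadius = 2.5, wallThickness = 0.5,
                   center = c(0, 0, 0))
  g <- GridSpec(c(13, 13, 13), spacing = c(2, 2, 2))
  set.seed(99)
  v <- array(3.1, dim = c(13, 13, 13))
  ax <- seq(-12, 12, 2)
  for (i in 1:13) for (j in 1:13) for (k in 1:13) {
    d <- sqrt(ax[i]^2 + ax[j]^2 + ax[k]^2)
    v[i, j, k] <- 3.1 + 21 * sphereGaussProfile(d, 2.5, 1.8) +
      rnorm(1, 0, 0.2)
  }
  img <- ImageVolume(v, g)
  pk <- peakVoiMean(img, sp, voiDiameter = 12)

  ## oracle: exhaustive 0.25-mm candidate grid, same 3^3 subdivision
  cand <- as.matrix(expand.grid(x = seq(-3, 3, 0.25),
                                y = seq(-3, 3, 0.25),
                                z = seq(-3, 3, 0.25)))
  cand <- cand[sqrt(rowSums(cand^2)) <= 3, ]
  sub <- as.matrix(expand.grid(dx = (-1:1) * 2 / 3, dy = (-1:1) * 2 / 3,
                               dz = (-1:1) * 2 / 3))
  vox <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  vals <- as.vector(v)
  fine <- do.call(rbind, lapply(seq_len(nrow(sub)), function(m)
    sweep(vox, 2, -sub[m, ])))
  fineVals <- rep(vals, times = nrow(sub))
  near <- rowSums(fine^2) <= (3 + 6 + 0.5)^2  # candidate ball + VOI radius
  fine <- fine[near, ]
  fineVals <- fineVals[near]
  best <- -Inf
  for (ci in seq_len(nrow(cand))) {
    inside <- (fine[, 1] - cand[ci, 1])^2 + (fine[, 2] - cand[ci, 2])^2 +
      (fine[, 3] - cand[ci, 3])^2 <= 36
    m <- sum(fineVals[inside]) / sum(inside)
    if (m > best) best <- m
  }
  expect_lt(abs(pk$mean - best) / best, 0.005)
})

test_that("background SNR flags a constant background as degenerate", {
  g <- smallGrid()
  flat <- ImageVolume(array(3.1, dim = gridShape(g)), g)
  b <- backgroundSnr(flat, c(0, 0, 0), 5)
  expect_true(b$degenerate)
  expect_identical(b$snr, Inf)
})

test_that("background SNR is scale invariant and on target under noise", {
  ph <- singleSpherePhantom()
  vol <- rasterizeTruth(ph, smallGrid(), supersample = 2)
  bl <- applyReconSignature(vol, ReconPreset("t", blurFwhm = 5.2))
  noisy <- addNoise(bl, 0.1, 4, seed = 2,
                    voiCenter = backgroundVoiCenter(ph), voiVolume = 5)
  b1 <- backgroundSnr(noisy, backgroundVoiCenter(ph), 5)
  scaled <- ImageVolume(imageValues(noisy) * 7.3, imageGrid(noisy))
  b2 <- backgroundSnr(scaled, backgroundVoiCenter(ph), 5)
  expect_equal(b1$snr, b2$snr, tolerance = 1e-12)
  snrs <- vapply(1:5, function(s) {
    n <- addNoise(bl, 0.1, 4, seed = s,
                  voiCenter = backgroundVoiCenter(ph), voiVolume = 5)
    backgroundSnr(n, backgroundVoiCenter(ph), 5)$snr
  }, numeric(1))
  expect_lt(abs(mean(snrs) - 10) / 10, 0.1)
})

test_that("metrics table keeps CRmax above CRpeak and carries SNR", {
  ph <- singleSpherePhantom()
  series <- simulateSeries(ph, smallGrid(),
                           ReconPreset("t", 5.2, overshootAmplitude = 0.3,
                                       noiseCv = 0.15),
                           nScans = 2, seed = 4, supersample = 2)
  for (img in series) {
    mt <- analyzeVolume(img, ph)
    expect_true(all(mt$crMax >= mt$crPeak))
    expect_true(all(mt$crPeak > 0))
    expect_equal(unique(mt$snr), mt$snr[1])
    expect_equal(mt$trueAc[1], attr(img, "trueSphereAc"))
  }
})
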