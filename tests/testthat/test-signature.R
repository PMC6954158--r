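test_that("sub-voxel blur leaves the volume unchanged", {
  ph <- singleSpherePhantom()
  vol <- rasterizeTruth(ph, smallGrid(), supersample = 2)
  out <- applyReconSignature(vol, ReconPreset("tiny", blurFwhm = 0.1))
  expect_lt(max(abs(imageValues(out) - imageValues(vol))),
            1e-6 * max(imageValues(vol)))
})

test_that("convolution conserves total activity away from grid edges", {
  ## compact phantom well separated (> 4 FWHM) from every grid edge
  sp <- nemaSpheres()[[4]]
  sp@center <- c(0, 0, 0)
  ph <- singleSpherePhantom(sp, bodyRadius = 28, bodyLength = 56,
                            voiCenter = c(0, 0, 18), voiVolume = 1)
  g <- GridSpec(c(44, 44, 44), spacing = c(2.73, 2.73, 2.73))
  vol <- rasterizeTruth(ph, g, supersample = 2)
  for (blur in c(4.2, 8.2)) {
    out <- applyReconSignature(vol, ReconPreset("t", blurFwhm = blur))
    expect_lt(abs(sum(imageValues(out)) - sum(imageValues(vol))) /
                sum(imageValues(vol)), 1e-6)
  }
})

test_that("blurred sphere profile follows the analytic model", {
  ## fine sampling so that the voxel grid does not limit the comparison
  sp <- nemaSpheres()[[1]]  # 37 mm
  sp@center <- c(0, 0, 0)
  ph <- singleSpherePhantom(sp, bodyRadius = 45, bodyLength = 90,
                            voiCenter = c(0, 0, 32), voiVolume = 5)
  g <- GridSpec(c(184, 184, 176), spacing = c(0.5, 0.5, 0.5))
  vol <- rasterizeTruth(ph, g, supersample = 6)
  bl <- applyReconSignature(vol, ReconPreset("t", blurFwhm = 4.2))
  prof <- extractRadialSamples(bl, c(0, 0, 0), 35)
  sigma <- 4.2 / (2 * sqrt(2 * log(2)))
  pred <- modelProfile(prof@radii, 24.4, 3.1, sp, sigma)
  expect_lt(max(abs(prof@values - pred)) / 24.4, 1e-3)

  ## radial symmetry: angular spread in thin shells after removing the
  ## radial trend stays well below 1% of the sphere concentration
  resid <- prof@values - pred
  shells <- cut(prof@radii, seq(0, 35, 0.5))
  sds <- tapply(resid, shells, stats::sd)
  expect_lt(max(sds, na.rm = TRUE) / 24.4, 0.01)
})

test_that("edge overshoot pushes the boundary profile above the sphere AC", {
  ph <- iecPhantom()  # SBR 8:1
  vol <- rasterizeTruth(ph, defaultGrid(), supersample = 4)
  out <- applyReconSignature(vol, ReconPreset("t", blurFwhm = 4.2,
                                              overshootAmplitude = 0.5))
  sp <- phantomSpheres(ph)[[1]]  # 37 mm
  prof <- extractRadialSamples(out, sphereCenter(sp), 30)
  expect_gt(max(prof@values), 24.4)
  ## without overshoot the profile stays at or below the sphere AC (up to
  ## the sampling ripple)
  plain <- applyReconSignature(vol, ReconPreset("t", blurFwhm = 4.2))
  prof0 <- extractRadialSamples(plain, sphereCenter(sp), 30)
  expect_lt(max(prof0@values), 24.4 * 1.05)
})

test_that("noise honours the seed contract and the zero-CV identity", {
  ph <- singleSpherePhantom()
  vol <- rasterizeTruth(ph, smallGrid(), supersample = 2)
  bl <- applyReconSignature(vol, ReconPreset("t", blurFwhm = 5.2))
  expect_identical(imageValues(addNoise(bl, 0, seed = 1)),
                   imageValues(bl))
  n1 <- addNoise(bl, 0.1, 4, seed = 7,
                 voiCenter = backgroundVoiCenter(ph), voiVolume = 5)
  n2 <- addNoise(bl, 0.1, 4, seed = 7,
                 voiCenter = backgroundVoiCenter(ph), voiVolume = 5)
  expect_identical(imageValues(n1), imageValues(n2))
  n3 <- addNoise(bl, 0.1, 4, seed = 8,
                 voiCenter = backgroundVoiCenter(ph), voiVolume = 5)
  expect_false(identical(imageValues(n1), imageValues(n3)))
  ## the global RNG stream is not disturbed
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(addNoise(bl, 0.1, seed = 5)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("background CV lands on target across seeds", {
  ph <- singleSpherePhantom()
  vol <- rasterizeTruth(ph, smallGrid(), supersample = 2)
  bl <- applyReconSignature(vol, ReconPreset("t", blurFwhm = 5.2))
  voiC <- backgroundVoiCenter(ph)
  cvs <- vapply(1:10, function(s) {
    noisy <- addNoise(bl, 0.12, 4, seed = s, voiCenter = voiC,
                      voiVolume = 5)
    b <- backgroundSnr(noisy, voiC, 5)
    b$sd / b$mean
  }, numeric(1))
  expect_lt(abs(mean(cvs) - 0.12) / 0.12, 0.10)
})

test_that("decay across a simulated series follows the half-life", {
  ph <- singleSpherePhantom()
  series <- simulateSeries(ph, smallGrid(), ReconPreset("t", 4.2),
                           nScans = 5, interval = 30, seed = 1,
                           supersample = 2, noiseless = TRUE)
  b1 <- backgroundSnr(series[[1]], backgroundVoiCenter(ph), 5)$mean
  b5 <- backgroundSnr(series[[5]], backgroundVoiCenter(ph), 5)$mean
  expect_lt(abs(b5 / b1 - 2^(-120 / 109.77)), 0.01 * 2^(-120 / 109.77))
  ## true SBR attribute constant across the series
  sbrs <- vapply(series, function(im)
    attr(im, "trueSphereAc") / attr(im, "trueBackgroundAc"), numeric(1))
  expect_equal(sbrs, rep(trueSbr(24.4, 3.1), 5), tolerance = 1e-12)
  ## single-scan series equals the plain pipeline at elapsed zero
  one <- simulateSeries(ph, smallGrid(), ReconPreset("t", 4.2),
                        nScans = 1, seed = 1, supersample = 2,
                        noiseless = TRUE)[[1]]
  direct <- applyReconSignature(rasterizeTruth(ph, smallGrid(), 2),
                                ReconPreset("t", 4.2))
  expect_equal(imageValues(one), imageValues(direct), tolerance = 1e-12)
})
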