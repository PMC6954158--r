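test_that("fit recovers parameters exactly from model-generated samples", {
  sp <- SphereSpec("37", 18.3, 1.3, c(0, 0, 0))
  set.seed(5)
  r <- c(seq(0, 12, 0.8), sort(runif(2500, 0, 35)))
  sigma <- 5.0 / (2 * sqrt(2 * log(2)))
  v <- modelProfile(r, S = 24.4, B = 3.1, sp, sigma)
  prof <- new("SphereProfile", radii = r, values = v, rMax = 35,
              centerUsed = c(0, 0, 0))
  fr <- fitProfile(prof, sp)
  expect_true(fr@converged)
  expect_lt(abs(fittedFwhm(fr) - 5.0), 1e-3)
  expect_lt(abs(fittedSignal(fr) - 24.4), 1e-3)
  expect_lt(abs(fittedBackground(fr) - 3.1), 1e-3)
  ## FWHM slot is consistent with sigma
  expect_equal(fr@fwhm, fr@sigma * 2 * sqrt(2 * log(2)))
})

test_that("fit recovers the applied blur from a rasterized sphere", {
  ph <- iecPhantom()
  vol <- rasterizeTruth(ph, defaultGrid(), supersample = 4)
  bl <- applyReconSignature(vol, ReconPreset("t", blurFwhm = 4.2))
  fr <- fitSphereResolution(bl, phantomSpheres(ph)[[1]])
  expect_true(fr@converged)
  expect_lt(abs(fittedFwhm(fr) - 4.2), 0.15)
})

test_that("center refinement locates a blurred sphere to sub-voxel accuracy", {
  ph <- singleSpherePhantom()
  vol <- rasterizeTruth(ph, smallGrid(), supersample = 4)
  bl <- applyReconSignature(vol, ReconPreset("t", blurFwhm = 5.2))
  rc <- refineCenter(bl, initial = c(3, -2, 1),
                     windowRadius = outerRadius(phantomSpheres(ph)[[1]]) + 4)
  expect_true(rc$converged)
  expect_false(rc$degenerate)
  expect_lt(sqrt(sum(rc$center^2)), 0.05)
})

test_that("center refinement on a uniform image is flagged degenerate", {
  g <- smallGrid()
  flat <- ImageVolume(array(3.1, dim = gridShape(g)), g)
  rc <- refineCenter(flat, initial = c(1, 1, 0), windowRadius = 12)
  expect_true(rc$degenerate)
  expect_equal(rc$center, c(1, 1, 0))
})

test_that("center refinement stays sub-voxel under noise", {
  ph <- singleSpherePhantom()
  vol <- rasterizeTruth(ph, smallGrid(), supersample = 4)
  bl <- applyReconSignature(vol, ReconPreset("t", blurFwhm = 5.2))
  halfVoxel <- min(gridSpacing(smallGrid())) / 2
  for (s in 1:10) {
    noisy <- addNoise(bl, 0.1, 4, seed = s,
                      voiCenter = backgroundVoiCenter(ph), voiVolume = 5)
    rc <- refineCenter(noisy, initial = c(2, 0, -1), windowRadius = 13.5)
    expect_lt(sqrt(sum(rc$center^2)), halfVoxel)
  }
})

test_that("radial sampling covers the expected voxel count", {
  ph <- singleSpherePhantom()
  vol <- rasterizeTruth(ph, smallGrid(), supersample = 2)
  R <- 12
  prof <- extractRadialSamples(vol, c(0, 0, 0), R)
  nExpected <- (4 / 3) * pi * R^3 / prod(gridSpacing(smallGrid()))
  surface <- 4 * pi * R^2 * max(gridSpacing(smallGrid())) /
    prod(gridSpacing(smallGrid()))
  expect_lt(abs(length(prof@radii) - nExpected), surface)
  expect_true(all(prof@radii <= R))
  ## degenerate window returns at least the center voxel
  tinyProf <- extractRadialSamples(vol, c(0.1, 0, 0), 0.5)
  expect_gte(length(tinyProf@radii), 1)
  ## clipped ball raises an informative error
  expect_error(extractRadialSamples(vol, c(55, 0, 0), 20), "clipped")
})

test_that("a uniform image yields a flat profile", {
  g <- smallGrid()
  flat <- ImageVolume(array(7.3, dim = gridShape(g)), g)
  prof <- extractRadialSamples(flat, c(0, 0, 0), 15)
  expect_true(all(prof@values == 7.3))
})

test_that("fit scatter grows when sphere contrast drops", {
  ## same blur, same absolute background noise; only the sphere
  ## concentration changes (8:1 versus 2:1 over the same background)
  sp <- nemaSpheres()[[3]]  # 22 mm
  sp@center <- c(0, 0, 0)
  g <- GridSpec(c(36, 36, 32), spacing = c(2.73, 2.73, 2.78))
  fwhms <- function(sphereAc) {
    ph <- singleSpherePhantom(sp, sphereAc = sphereAc, backgroundAc = 3.1,
                              voiCenter = c(0, 0, 26), voiVolume = 2)
    vol <- rasterizeTruth(ph, g, supersample = 2)
    bl <- applyReconSignature(vol, ReconPreset("t", blurFwhm = 5.2))
    vapply(1:8, function(s) {
      noisy <- addNoise(bl, 0.12, 4, seed = s,
                        voiCenter = c(0, 0, 26), voiVolume = 2)
      fittedFwhm(fitSphereResolution(noisy, sp, refine = FALSE))
    }, numeric(1))
  }
  sdHigh <- stats::sd(fwhms(24.4))
  sdLow <- stats::sd(fwhms(6.2))
  expect_gt(sdLow, sdHigh)
})
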