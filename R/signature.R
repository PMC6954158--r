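## Fourier-domain filtering on a zero-padded grid.
##
## The Gaussian transfer per axis is exp(-2 pi^2 sigma^2 nu^2). When
## `boxCompensate` is TRUE the transfer is divided by the voxel box
## response sinc(pi nu dx) (clamped at 1), which cancels the voxel-average
## prefilter of the rasterized truth so that the realized point-spread
## FWHM of the sampled volume equals the nominal one. For blur well below
## the voxel size the clamp makes the filter the identity.

.fftFreqs <- function(n, spacing) {
  k <- c(seq.int(0L, floor(n / 2)), seq.int(-(ceiling(n / 2) - 1L), -1L))
  k / (n * spacing)
}

.axisTransfer <- function(n, spacing, sigma, boxCompensate,
                          supersample = NULL) {
  nu <- .fftFreqs(n, spacing)
  g <- exp(-2 * pi^2 * sigma^2 * nu^2)
  if (boxCompensate) {
    if (!is.null(supersample) && supersample >= 1) {
      ## exact transfer of the s-point subsample average the rasterizer uses
      off <- .subOffsets(supersample, spacing)
      b <- rowMeans(cos(2 * pi * outer(nu, off)))
    } else {
      x <- pi * nu * spacing
      b <- ifelse(abs(x) < 1e-12, 1, sin(x) / x)
    }
    g <- pmin(1, g / pmax(b, 1e-3))
  }
  g
}

## apply a separable-in-frequency filter; `extra` is an optional function
## mapping the (padded) per-axis Gaussian transfer product to the final
## transfer array (used for the overshoot term).
.fftFilter <- function(values, spacing, sigma, boxCompensate = FALSE,
                       overshootAmplitude = 0, overshootSigma = NULL,
                       padMm = NULL, supersample = NULL) {
  dm <- dim(values)
  ## default: circular convolution on the periodized grid (exact unit DC
  ## gain, hence exact activity conservation); padMm > 0 zero-pads instead
  if (is.null(padMm)) padMm <- 0
  np <- if (padMm > 0) {
    pad <- pmax(1L, ceiling(padMm / spacing) + 1L)
    vapply(1:3, function(a) stats::nextn(dm[a] + 2L * pad[a], c(2, 3, 5)),
           numeric(1))
  } else dm
  big <- array(0, dim = np)
  big[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- values

  tx <- .axisTransfer(np[1], spacing[1], sigma, boxCompensate, supersample)
  ty <- .axisTransfer(np[2], spacing[2], sigma, boxCompensate, supersample)
  tz <- .axisTransfer(np[3], spacing[3], sigma, boxCompensate, supersample)
  transfer <- outer(outer(tx, ty), tz)
  if (overshootAmplitude > 0) {
    gx <- .axisTransfer(np[1], spacing[1], overshootSigma, FALSE)
    gy <- .axisTransfer(np[2], spacing[2], overshootSigma, FALSE)
    gz <- .axisTransfer(np[3], spacing[3], overshootSigma, FALSE)
    g2 <- outer(outer(gx, gy), gz)
    transfer <- transfer * (1 + overshootAmplitude * (1 - g2))
  }

  out <- Re(stats::fft(stats::fft(big) * transfer, inverse = TRUE)) / prod(np)
  array(out[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])], dim = dm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Imprint a reconstruction setting's image-domain signature
#'
#' Convolves the volume with an isotropic 3D Gaussian of FWHM
#' `blurFwhm(preset)` (the emulated reconstructed resolution) and adds an
#' edge-artifact overshoot term
#' `a * (blurred - reblur(blurred, 1.5 * FWHM))` -- an unsharp-mask
#' ringing that reproduces the boundary overshoot seen with
#' resolution-modeling reconstruction. Total activity (voxel sum) is
#' preserved away from the grid edges because the filter has unit gain at
#' zero frequency.
#'
#' The convolution is performed in the Fourier domain on the periodized
#' grid (circular), which makes the unit-gain conservation exact; the
#' phantom should stay a few FWHM away from the grid edges so that
#' wraparound is negligible. By default the voxel-average prefilter of the rasterized input is
#' compensated (divided out up to a clamp at unit gain) so that the
#' realized profile of a blurred sphere follows the continuous
#' sphere-Gaussian model at the nominal FWHM; with blur far below the
#' voxel size the filter degenerates to the identity.
#'
#' @param image An [ImageVolume-class].
#' @param preset A [ReconPreset-class]; only `blurFwhm` and
#'   `overshootAmplitude` are used here (noise is added separately by
#'   [addNoise()]).
#' @param boxCompensate Compensate the voxel-average prefilter
#'   (default `TRUE`).
#' @return A blurred (and possibly overshooting) [ImageVolume-class].
#' @seealso [addNoise()], [simulateSeries()]
#' @export
applyReconSignature <- function(image, preset, boxCompensate = TRUE) {
  sigma <- .fwhmToSigma(preset@blurFwhm)
  out <- .fftFilter(image@values, image@grid@spacing, sigma,
                    boxCompensate = boxCompensate,
                    overshootAmplitude = preset@overshootAmplitude,
                    overshootSigma = .fwhmToSigma(1.5 * preset@blurFwhm),
                    supersample = attr(image, "supersample"))
  ImageVolume(out, image@grid)
}

#' Add spatially correlated background noise
#'
#' Adds zero-mean Gaussian noise obtained by convolving white noise with
#' an isotropic Gaussian of FWHM `corrFwhm`, rescaled so that the noise
#' standard deviation inside the background VOI equals
#' `noiseCv * (background mean)`. Deterministic given `seed` (the global
#' RNG state is saved and restored).
#'
#' @param image An [ImageVolume-class].
#' @param noiseCv Target background coefficient of variation (>= 0);
#'   0 returns the input unchanged.
#' @param corrFwhm Noise correlation FWHM in mm.
#' @param seed Integer seed.
#' @param voiCenter Optional world center (mm) of the background VOI used
#'   for calibration; if `NULL` the whole volume is used.
#' @param voiVolume Background VOI volume in ml (default 30).
#' @return A noisy [ImageVolume-class]. Negative voxel values may occur
#'   and are permitted.
#' @examples
#' ph <- iecPhantom()
#' g <- GridSpec(c(48, 48, 32), c(2.73, 2.73, 2.78))
#' vol <- rasterizeTruth(iecPhantom(bodyRadius = 60, bodyLength = 85,
#'                                  ringRadius = 30,
#'                                  backgroundVoiCenter = c(0, 0, 25),
#'                                  backgroundVoiVolume = 10), g, 2)
#' noisy <- addNoise(vol, 0.1, 4, seed = 1)
#' @export
addNoise <- function(image, noiseCv, corrFwhm = 4, seed = 1L,
                     voiCenter = NULL, voiVolume = 30) {
  if (noiseCv < 0) stop("noiseCv must be >= 0")
  if (noiseCv == 0) return(image)
  white <- .withLocalSeed(seed, function()
    array(stats::rnorm(prod(dim(image@values))), dim = dim(image@values)))
  sigma <- .fwhmToSigma(corrFwhm)
  noise <- .fftFilter(white, image@grid@spacing, sigma)
  if (is.null(voiCenter)) {
    mask <- rep(TRUE, length(noise))
  } else {
    mask <- .voiMask(image@grid, voiCenter, radiusFromVolume(voiVolume))
  }
  bMean <- mean(image@values[mask])
  nSd <- stats::sd(noise[mask])
  ImageVolume(image@values + noise * (noiseCv * bMean / nSd), image@grid)
}

## logical mask of voxels whose centers lie in a ball
.voiMask <- function(grid, center, radius) {
  ax <- .axisCoords(grid)
  dx2 <- (ax[[1]] - center[1])^2
  dy2 <- (ax[[2]] - center[2])^2
  dz2 <- (ax[[3]] - center[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
}

## run `fn` under a fixed seed without disturbing the caller's RNG
.withLocalSeed <- function(seed, fn) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
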