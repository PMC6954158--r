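#' Maximum contrast recovery of a sphere
#'
#' Ratio of the maximum voxel value within a search ball of radius
#' `R_outer + searchMargin` around the sphere center to the true
#' decay-corrected activity concentration.
#'
#' @param image An [ImageVolume-class].
#' @param sphere A [SphereSpec-class].
#' @param trueAc True sphere activity concentration at this scan's time
#'   point (kBq/ml).
#' @param searchMargin Margin beyond the outer radius in mm (default 2).
#' @return Dimensionless CRmax.
#' @export
crMax <- function(image, sphere, trueAc, searchMargin = 2) {
  rSearch <- outerRadius(sphere) + searchMargin
  clip <- .ballClipMessage(sphere@center, rSearch, image@grid, "CRmax search ball")
  if (!is.null(clip)) stop(clip)
  mask <- .voiMask(image@grid, sphere@center, rSearch)
  max(image@values[mask]) / trueAc
}

## circular FFT convolution of `arr` with a kernel given as an array of
## the same (padded) size whose origin sits at index [1,1,1] with wraparound
.ballMovingSum <- function(fine, fineSpacing, radius) {
  dm <- dim(fine)
  kr <- ceiling(radius / fineSpacing)
  np <- vapply(1:3, function(a) stats::nextn(dm[a] + 2L * kr[a] + 2L, c(2, 3, 5)),
               numeric(1))
  big <- array(0, dim = np)
  big[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- fine
  ## wrapped centered ball kernel
  offs <- lapply(1:3, function(a) {
    k <- c(0:(np[a] %/% 2), -((np[a] - np[a] %/% 2 - 1):1))
    k * fineSpacing[a]
  })
  d2 <- outer(outer(offs[[1]]^2, offs[[2]]^2, "+"), offs[[3]]^2, "+")
  kern <- (d2 <= radius^2) * 1
  conv <- Re(stats::fft(stats::fft(big) * stats::fft(kern), inverse = TRUE)) /
    prod(np)
  list(sums = array(conv[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])],
                    dim = dm),
       kernelCount = sum(kern))
}

#' Peak VOI: the spherical VOI position maximizing the mean AC
#'
#' Positions a spherical VOI of `voiDiameter` (default 1.2 cm) to maximize
#' its mean activity concentration near one sphere, the standard
#' peak-uptake construction. Candidate centers lie on the lattice obtained
#' by subdividing each voxel `subdivision` times per axis (step
#' `spacing / subdivision`, about 0.9 mm at the default grid, i.e. at
#' least as fine as a 1-mm search grid) and are constrained to a ball of
#' radius `R_outer` around the sphere center, which keeps the whole VOI
#' within `R_outer + voiRadius` of the sphere. Partial-volume weights are
#' the fraction of each voxel inside the VOI estimated by the same
#' subdivision, so the VOI mean is an exact moving-ball average on the
#' subdivided lattice (computed by FFT). Ties are broken toward the
#' nominal sphere center.
#'
#' @param image An [ImageVolume-class].
#' @param sphere A [SphereSpec-class].
#' @param voiDiameter Peak VOI diameter in mm (default 12).
#' @param subdivision Voxel subdivision per axis (default 3, the 3x3x3
#'   partial-volume rule).
#' @param tieTol Relative tolerance within which candidate means count as
#'   tied (handles the numerically degenerate flat plateau of large
#'   noiseless spheres).
#' @return List with `mean` (kBq/ml) and `center` (world mm).
#' @seealso [crPeak()]
#' @export
peakVoiMean <- function(image, sphere, voiDiameter = 12, subdivision = 3L,
                        tieTol = 1e-3) {
  s <- as.integer(subdivision)
  voiR <- voiDiameter / 2
  rOut <- outerRadius(sphere)
  grid <- image@grid
  halfDiag <- sqrt(sum((grid@spacing / 2)^2))
  clip <- .ballClipMessage(sphere@center, rOut + voiR + halfDiag, grid,
                           "peak VOI candidate region")
  if (!is.null(clip)) stop(clip)

  win <- .indexWindow(sphere@center, rOut + voiR + halfDiag, grid)
  ii <- win$lo[1]:win$hi[1]; jj <- win$lo[2]:win$hi[2]; kk <- win$lo[3]:win$hi[3]
  block <- array(image@values[ii, jj, kk],
                 dim = c(length(ii), length(jj), length(kk)))
  ax <- .axisCoords(grid)

  ## subdivided lattice: every voxel becomes s^3 equal-value cells
  fine <- block[rep(seq_along(ii), each = s),
                rep(seq_along(jj), each = s),
                rep(seq_along(kk), each = s)]
  fineSpacing <- grid@spacing / s
  fineCoord <- function(a, idx) {
    base <- ax[[a]][idx]
    off <- .subOffsets(s, grid@spacing[a])
    as.vector(outer(off, base, "+"))   # voxel-major, sub-minor
  }
  fx <- fineCoord(1, ii); fy <- fineCoord(2, jj); fz <- fineCoord(3, kk)

  ms <- .ballMovingSum(fine, fineSpacing, voiR)
  means <- ms$sums / ms$kernelCount

  d2 <- outer(outer((fx - sphere@center[1])^2, (fy - sphere@center[2])^2, "+"),
              (fz - sphere@center[3])^2, "+")
  cand <- d2 <= rOut^2
  if (!any(cand)) stop("empty peak-VOI candidate set")
  mv <- means[cand]
  best <- max(mv)
  ## near-ties (within tieTol, relative) arise on the flat plateau of a
  ## noiseless large sphere where the maximum is numerically degenerate;
  ## break them toward the nominal sphere center
  tied <- which(cand & means >= best - tieTol * max(1, abs(best)))
  tied <- tied[order(d2[tied])]
  pick <- tied[1]
  idx3 <- arrayInd(pick, dim(means))
  list(mean = means[pick],
       center = c(fx[idx3[1]], fy[idx3[2]], fz[idx3[3]]))
}

#' Peak contrast recovery
#'
#' `CRpeak = peak VOI mean / true AC`: the mean of the best-placed 1.2-cm
#' spherical VOI divided by the true decay-corrected sphere activity
#' concentration.
#'
#' @inheritParams peakVoiMean
#' @param trueAc True sphere AC at this scan's time point (kBq/ml).
#' @return Dimensionless CRpeak.
#' @export
crPeak <- function(image, sphere, trueAc, voiDiameter = 12, subdivision = 3L) {
  peakVoiMean(image, sphere, voiDiameter, subdivision)$mean / trueAc
}

#' Background signal-to-noise ratio
#'
#' `SNR = background mean AC / background AC standard deviation`, both
#' measured over the voxels whose centers lie inside a spherical
#' background VOI (default volume 30 ml). A zero standard deviation is
#' flagged degenerate (infinite SNR) rather than raising an error.
#'
#' @param image An [ImageVolume-class].
#' @param voiCenter Background VOI center (world mm).
#' @param voiVolume VOI volume in ml (default 30).
#' @return List with `snr`, `mean`, `sd`, `n` (voxels) and `degenerate`.
#' @export
backgroundSnr <- function(image, voiCenter, voiVolume = 30) {
  radius <- radiusFromVolume(voiVolume)
  clip <- .ballClipMessage(voiCenter, radius, image@grid, "background VOI")
  if (!is.null(clip)) stop(clip)
  mask <- .voiMask(image@grid, voiCenter, radius)
  v <- image@values[mask]
  m <- mean(v)
  sdv <- stats::sd(v)
  degenerate <- !is.finite(sdv) || sdv == 0
  list(snr = if (degenerate) Inf else m / sdv,
       mean = m, sd = sdv, n = length(v), degenerate = degenerate)
}

#' Per-sphere image-quality metrics for one volume
#'
#' Computes CRmax, CRpeak (with peak VOI center) for every sphere plus
#' the background SNR, returning one tidy row per sphere (a
#' "MetricsTable" fragment). The CRmax search ball is enlarged to cover
#' the full support of the peak VOI (`voiRadius` + half a voxel
#' diagonal), which guarantees `CRmax >= CRpeak` by containment.
#'
#' @param image An [ImageVolume-class] (typically from
#'   [simulateSeries()], whose attributes supply the defaults below).
#' @param phantom The [PhantomDefinition-class] imaged.
#' @param trueAc True sphere AC at this scan (kBq/ml); defaults to the
#'   image's `trueSphereAc` attribute.
#' @param scan,preset,sbr Bookkeeping labels stored in the output.
#' @param voiDiameter Peak VOI diameter (mm).
#' @return A data.frame with columns `scan`, `preset`, `sbr`, `label`,
#'   `diameterMm`, `crMax`, `crPeak`, `peakX`, `peakY`, `peakZ`, `snr`,
#'   `bgMean`, `bgSd`, `trueAc`.
#' @export
analyzeVolume <- function(image, phantom, trueAc = NULL, scan = NA_integer_,
                          preset = NA_character_, sbr = NA_character_,
                          voiDiameter = 12) {
  if (is.null(trueAc)) trueAc <- attr(image, "trueSphereAc")
  if (is.null(trueAc)) trueAc <- phantom@activity@sphereAc
  if (is.na(scan) && !is.null(attr(image, "scan"))) scan <- attr(image, "scan")
  snr <- backgroundSnr(image, phantom@backgroundVoiCenter,
                       phantom@backgroundVoiVolume)
  halfDiag <- sqrt(sum((image@grid@spacing / 2)^2))
  rows <- lapply(phantom@spheres, function(sp) {
    pk <- peakVoiMean(image, sp, voiDiameter)
    data.frame(
      scan = as.integer(scan), preset = preset, sbr = sbr,
      label = sp@label, diameterMm = 2 * sp@innerRadius,
      crMax = crMax(image, sp, trueAc,
                    searchMargin = voiDiameter / 2 + halfDiag),
      crPeak = pk$mean / trueAc,
      peakX = pk$center[1], peakY = pk$center[2], peakZ = pk$center[3],
      snr = snr$snr, bgMean = snr$mean, bgSd = snr$sd,
      trueAc = trueAc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
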