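#' Simulate a repeated-scan phantom series
#'
#' Generates `nScans` reconstructed phantom volumes at `interval`-minute
#' spacing. Scan k images the phantom with both compartment activities
#' decayed by `2^(-(k-1) * interval / halfLife)`, then applies the
#' reconstruction signature of `preset` and adds correlated background
#' noise with a per-scan seed `seed + (k - 1)`.
#'
#' Because rasterization and convolution are linear in the compartment
#' activities, the noise-free volume for scan k equals the scan-1 volume
#' scaled by the decay factor; the implementation exploits this and
#' computes the rasterization and blur once per series.
#'
#' With `countLossInflation = TRUE` (default) the noise coefficient of
#' variation of scan k is inflated by `2^(elapsed / (2 * halfLife))`,
#' emulating the loss of counts as activity decays (relative noise scales
#' with the inverse square root of counts).
#'
#' @param phantom A [PhantomDefinition-class].
#' @param grid A [GridSpec-class].
#' @param preset A [ReconPreset-class].
#' @param nScans Number of scans (>= 1), default 5.
#' @param interval Minutes between scan starts, default 30.
#' @param seed Integer base seed for the noise.
#' @param supersample Rasterization subsampling, see [rasterizeTruth()].
#' @param countLossInflation Inflate noise with decay (default `TRUE`).
#' @param noiseless If `TRUE`, skip the noise stage entirely.
#' @return List of [ImageVolume-class]; each element carries attributes
#'   `scan`, `elapsed`, `trueSphereAc`, `trueBackgroundAc` (the
#'   decay-corrected compartment concentrations at that scan) and
#'   `noiseCv` (the applied, possibly inflated, CV).
#' @examples
#' ph <- iecPhantom()
#' series <- simulateSeries(ph, defaultGrid(), reconPresets()[[2]],
#'                          nScans = 2, seed = 7, supersample = 2)
#' attr(series[[2]], "trueSphereAc") / attr(series[[1]], "trueSphereAc")
#' @export
simulateSeries <- function(phantom, grid, preset, nScans = 5L,
                           interval = 30, seed = 1L, supersample = 4L,
                           countLossInflation = TRUE, noiseless = FALSE) {
  nScans <- as.integer(nScans)
  if (nScans < 1L) stop("nScans must be >= 1")
  act <- phantom@activity
  truth <- rasterizeTruth(phantom, grid, supersample)
  clean <- applyReconSignature(truth, preset)
  voiC <- phantom@backgroundVoiCenter
  voiV <- phantom@backgroundVoiVolume

  lapply(seq_len(nScans), function(k) {
    elapsed <- (k - 1L) * interval
    fac <- 2^(-elapsed / act@halfLife)
    img <- ImageVolume(clean@values * fac, grid)
    cv <- preset@noiseCv *
      (if (countLossInflation) 2^(elapsed / (2 * act@halfLife)) else 1)
    if (!noiseless && cv > 0)
      img <- addNoise(img, cv, preset@noiseCorrFwhm, seed + (k - 1L),
                      voiCenter = voiC, voiVolume = voiV)
    attr(img, "scan") <- k
    attr(img, "elapsed") <- elapsed
    attr(img, "trueSphereAc") <- act@sphereAc * fac
    attr(img, "trueBackgroundAc") <- act@backgroundAc * fac
    attr(img, "noiseCv") <- if (noiseless) 0 else cv
    img
  })
}
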