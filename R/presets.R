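#' Bundled reconstruction-signature presets
#'
#' Nine named [ReconPreset-class] fixtures emulating the image-domain
#' signatures of three Bayesian penalized likelihood settings (penalization
#' factor 150/300/450) and six conventional TOF-OSEM settings with and
#' without PSF modeling. The `blurFwhm` defaults are the published mean
#' reconstructed resolutions of the three largest spheres at SBR 8:1, and
#' the `noiseCv` defaults are the reciprocal of the published mean
#' background SNR pooled over contrast levels. These numbers parameterize
#' the simulator; they are fixtures describing the emulated conditions,
#' not measurements reproduced by this package.
#'
#' Overshoot amplitudes encode the qualitative edge-artifact ordering seen
#' in reconstructed sphere profiles: strongest for the lowest penalization
#' factor and for PSF with many iterations and a narrow filter, absent for
#' plain OSEM.
#'
#' @param names Optional character vector selecting a subset (in order).
#' @return Named list of [ReconPreset-class] objects.
#' @examples
#' names(reconPresets())
#' reconPresets("Q.Clear_300")[[1]]
#' @export
reconPresets <- function(names = NULL) {
  def <- list(
    ##            blur  overshoot  1/SNR   metadata
    "Q.Clear_150"   = c(3.7, 0.40, 1 / 4.2),
    "Q.Clear_300"   = c(4.3, 0.25, 1 / 7.0),
    "Q.Clear_450"   = c(4.7, 0.15, 1 / 9.3),
    "PSF+TOF_4/16"  = c(4.2, 0.35, 1 / 4.4),
    "PSF+TOF_2/17"  = c(5.1, 0.25, 1 / 7.0),
    "PSF+TOF_4/8"   = c(7.0, 0.10, 1 / 12.8),
    "OSEM+TOF_4/16" = c(4.8, 0.00, 1 / 2.5),
    "OSEM+TOF_2/17" = c(5.2, 0.00, 1 / 3.9),
    "OSEM+TOF_2/8"  = c(8.2, 0.00, 1 / 16.6)
  )
  meta <- c(
    "BPL, beta 150", "BPL, beta 300", "BPL, beta 450",
    "PSF+TOF, 4 it / 16 ss / 2.0 mm filter",
    "PSF+TOF, 2 it / 17 ss / 2.0 mm filter",
    "PSF+TOF, 4 it / 8 ss / 6.4 mm filter",
    "OSEM+TOF, 4 it / 16 ss / 2.0 mm filter",
    "OSEM+TOF, 2 it / 17 ss / 2.0 mm filter",
    "OSEM+TOF, 2 it / 8 ss / 6.4 mm filter")
  out <- lapply(seq_along(def), function(i)
    ReconPreset(names(def)[i], blurFwhm = def[[i]][1],
                overshootAmplitude = def[[i]][2], noiseCv = def[[i]][3],
                noiseCorrFwhm = 4, metadata = meta[i]))
  names(out) <- names(def)
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(out))
    if (length(missing))
      stop("unknown preset(s): ", paste(missing, collapse = ", "))
    out <- out[names]
  }
  out
}
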