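#' Write the canonical experiment configuration
#'
#' Emits a YAML description of a phantom experiment: sphere geometry,
#' compartment activities, grid, reconstruction presets, series design
#' and seed. [readExperimentConfig()] restores it. With the default
#' arguments this is the canonical default configuration.
#'
#' @param path Output YAML path.
#' @param phantom A [PhantomDefinition-class].
#' @param grid A [GridSpec-class].
#' @param presets List of [ReconPreset-class].
#' @param nScans,interval Series design.
#' @param seed Integer seed.
#' @param supersample Rasterization subsampling.
#' @return Invisibly, `path`.
#' @export
writeExperimentConfig <- function(path, phantom = iecPhantom(),
                                  grid = defaultGrid(),
                                  presets = reconPresets(),
                                  nScans = 5L, interval = 30, seed = 1L,
                                  supersample = 4L) {
  cfg <- list(
    phantom = list(
      spheres = lapply(phantom@spheres, function(s) list(
        label = s@label, innerRadius = s@innerRadius,
        wallThickness = s@wallThickness, center = s@center)),
      bodyRadius = phantom@bodyRadius, bodyLength = phantom@bodyLength,
      bodyCenter = phantom@bodyCenter,
      backgroundVoiCenter = phantom@backgroundVoiCenter,
      backgroundVoiVolume = phantom@backgroundVoiVolume,
      activity = list(sphereAc = phantom@activity@sphereAc,
                      backgroundAc = phantom@activity@backgroundAc,
                      referenceTime = phantom@activity@referenceTime,
                      halfLife = phantom@activity@halfLife)),
    grid = list(shape = grid@shape, spacing = grid@spacing,
                origin = grid@origin),
    presets = lapply(presets, function(p) list(
      name = p@name, blurFwhm = p@blurFwhm,
      overshootAmplitude = p@overshootAmplitude, noiseCv = p@noiseCv,
      noiseCorrFwhm = p@noiseCorrFwhm, metadata = p@metadata)),
    series = list(nScans = nScans, interval = interval,
                  supersample = supersample),
    seed = seed)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read an experiment configuration
#'
#' @param path YAML path written by [writeExperimentConfig()] (or
#'   hand-edited in the same schema).
#' @return List with `phantom` ([PhantomDefinition-class]),
#'   `grid` ([GridSpec-class]), `presets` (list of
#'   [ReconPreset-class]), `nScans`, `interval`, `supersample`, `seed`.
#' @export
readExperimentConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  ph <- cfg$phantom
  spheres <- lapply(ph$spheres, function(s)
    SphereSpec(s$label, s$innerRadius, s$wallThickness,
               as.numeric(s$center)))
  act <- ActivityConfig(ph$activity$sphereAc, ph$activity$backgroundAc,
                        ph$activity$referenceTime %||% 0,
                        ph$activity$halfLife %||% 109.77)
  phantom <- new("PhantomDefinition", spheres = spheres,
                 bodyRadius = as.numeric(ph$bodyRadius),
                 bodyLength = as.numeric(ph$bodyLength),
                 bodyCenter = as.numeric(ph$bodyCenter %||% c(0, 0, 0)),
                 backgroundVoiCenter = as.numeric(ph$backgroundVoiCenter),
                 backgroundVoiVolume = as.numeric(ph$backgroundVoiVolume %||% 30),
                 activity = act)
  grid <- GridSpec(as.integer(cfg$grid$shape),
                   as.numeric(cfg$grid$spacing),
                   if (is.null(cfg$grid$origin)) NULL
                   else as.numeric(cfg$grid$origin))
  presets <- lapply(cfg$presets, function(p)
    ReconPreset(p$name, p$blurFwhm, p$overshootAmplitude %||% 0,
                p$noiseCv %||% 0, p$noiseCorrFwhm %||% 4,
                p$metadata %||% ""))
  names(presets) <- vapply(presets, function(p) p@name, character(1))
  list(phantom = phantom, grid = grid, presets = presets,
       nScans = as.integer(cfg$series$nScans %||% 5L),
       interval = as.numeric(cfg$series$interval %||% 30),
       supersample = as.integer(cfg$series$supersample %||% 4L),
       seed = as.integer(cfg$seed %||% 1L))
}
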