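#' @import methods
#' @include AllGenerics.R
NULL

## central S4 containers: phantom geometry, acquisition grid, reconstruction
## preset, image volume, radial profile, profile fit.

#' Geometry of one fillable phantom sphere
#'
#' A `SphereSpec` describes a single hollow sphere insert of the NEMA IEC
#' body phantom: its nominal label, inner radius, (cold) wall thickness and
#' position in the phantom world frame (mm).
#'
#' @slot label Nominal sphere label, conventionally the nominal inner
#'   diameter in mm (e.g. `"37"`).
#' @slot innerRadius Inner radius in mm (fillable cavity).
#' @slot wallThickness Plastic wall thickness in mm; the wall holds no
#'   activity.
#' @slot center Numeric length-3 world coordinate of the sphere center (mm).
#'
#' @seealso [nemaSpheres()] for the standard six-sphere set.
#' @export
setClass("SphereSpec",
  representation(
    label = "character",
    innerRadius = "numeric",
    wallThickness = "numeric",
    center = "numeric"
  )
)

setValidity("SphereSpec", function(object) {
  msg <- character()
  if (length(object@innerRadius) != 1 || !is.finite(object@innerRadius) ||
      object@innerRadius <= 0)
    msg <- c(msg, "innerRadius must be a single positive number (mm)")
  if (length(object@wallThickness) != 1 || !is.finite(object@wallThickness) ||
      object@wallThickness <= 0 ||
      object@wallThickness >= object@innerRadius)
    msg <- c(msg, "wallThickness must satisfy 0 < wall < innerRadius")
  if (length(object@center) != 3 || any(!is.finite(object@center)))
    msg <- c(msg, "center must be a finite length-3 vector (mm)")
  if (length(msg)) msg else TRUE
})

#' @rdname SphereSpec-class
#' @param label,innerRadius,wallThickness,center See slot documentation.
#' @return A `SphereSpec` object.
#' @examples
#' SphereSpec("37", innerRadius = 18.3, wallThickness = 1.3,
#'            center = c(57.2, 0, 0))
#' @export
SphereSpec <- function(label, innerRadius, wallThickness, center) {
  new("SphereSpec", label = as.character(label),
      innerRadius = as.numeric(innerRadius),
      wallThickness = as.numeric(wallThickness),
      center = as.numeric(center))
}

#' @export
setMethod("sphereLabel", "SphereSpec", function(x) x@label)
#' @export
setMethod("innerRadius", "SphereSpec", function(x) x@innerRadius)
#' @export
setMethod("wallThickness", "SphereSpec", function(x) x@wallThickness)
#' @export
setMethod("outerRadius", "SphereSpec",
          function(x) x@innerRadius + x@wallThickness)
#' @export
setMethod("sphereCenter", "SphereSpec", function(x) x@center)

setMethod("show", "SphereSpec", function(object) {
  cat(sprintf(
    "SphereSpec '%s': inner radius %.2f mm, wall %.2f mm, center (%.1f, %.1f, %.1f) mm\n",
    object@label, object@innerRadius, object@wallThickness,
    object@center[1], object@center[2], object@center[3]))
})

#' Compartment activity concentrations
#'
#' Activity concentrations (kBq/ml) of the sphere and background
#' compartments at a reference time, together with the radionuclide
#' half-life used for decay scaling. The default half-life is F-18
#' (109.77 min).
#'
#' @slot sphereAc Sphere activity concentration at `referenceTime` (kBq/ml).
#' @slot backgroundAc Background activity concentration (kBq/ml).
#' @slot referenceTime Reference time in minutes (all decay scaling is
#'   relative to this time; conventionally the start of the first scan).
#' @slot halfLife Radionuclide half-life in minutes.
#' @export
setClass("ActivityConfig",
  representation(
    sphereAc = "numeric",
    backgroundAc = "numeric",
    referenceTime = "numeric",
    halfLife = "numeric"
  )
)

setValidity("ActivityConfig", function(object) {
  msg <- character()
  if (!(length(object@sphereAc) == 1 && is.finite(object@sphereAc) &&
        length(object@backgroundAc) == 1 && is.finite(object@backgroundAc) &&
        object@sphereAc > object@backgroundAc && object@backgroundAc > 0))
    msg <- c(msg, "need sphereAc > backgroundAc > 0 (kBq/ml)")
  if (length(object@halfLife) != 1 || !is.finite(object@halfLife) ||
      object@halfLife <= 0)
    msg <- c(msg, "halfLife must be positive (minutes)")
  if (length(msg)) msg else TRUE
})

#' @rdname ActivityConfig-class
#' @param sphereAc,backgroundAc,referenceTime,halfLife See slots.
#' @return An `ActivityConfig`.
#' @examples
#' ActivityConfig(sphereAc = 24.4, backgroundAc = 3.1)
#' @export
ActivityConfig <- function(sphereAc, backgroundAc, referenceTime = 0,
                           halfLife = 109.77) {
  new("ActivityConfig", sphereAc = as.numeric(sphereAc),
      backgroundAc = as.numeric(backgroundAc),
      referenceTime = as.numeric(referenceTime),
      halfLife = as.numeric(halfLife))
}

setMethod("show", "ActivityConfig", function(object) {
  cat(sprintf(
    "ActivityConfig: sphere %.2f kBq/ml, background %.2f kBq/ml (SBR %.2f), T1/2 %.2f min\n",
    object@sphereAc, object@backgroundAc,
    object@sphereAc / object@backgroundAc, object@halfLife))
})

#' Full phantom description
#'
#' A `PhantomDefinition` couples the six sphere inserts, the (cylindrical)
#' body compartment, the 30-ml spherical background VOI used for noise
#' measurement, and the compartment activities. Validity enforces that
#' spheres do not overlap pairwise and that the background VOI neither
#' leaves the body nor touches any sphere's outer surface.
#'
#' @slot spheres List of [SphereSpec-class] objects.
#' @slot bodyRadius Radius (mm) of the cylindrical body compartment.
#' @slot bodyLength Axial length (mm) of the body compartment.
#' @slot bodyCenter World center (mm) of the body cylinder.
#' @slot backgroundVoiCenter World center (mm) of the background VOI.
#' @slot backgroundVoiVolume Background VOI volume in ml (default 30).
#' @slot activity An [ActivityConfig-class].
#'
#' @seealso [iecPhantom()] for the default NEMA IEC layout.
#' @export
setClass("PhantomDefinition",
  representation(
    spheres = "list",
    bodyRadius = "numeric",
    bodyLength = "numeric",
    bodyCenter = "numeric",
    backgroundVoiCenter = "numeric",
    backgroundVoiVolume = "numeric",
    activity = "ActivityConfig"
  )
)

setValidity("PhantomDefinition", function(object) {
  msg <- character()
  sp <- object@spheres
  if (!all(vapply(sp, is, logical(1), class2 = "SphereSpec")))
    msg <- c(msg, "spheres must be a list of SphereSpec objects")
  else {
    n <- length(sp)
    if (n >= 2) {
      for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        d <- sqrt(sum((sp[[i]]@center - sp[[j]]@center)^2))
        if (d <= outerRadius(sp[[i]]) + outerRadius(sp[[j]]))
          msg <- c(msg, sprintf("spheres '%s' and '%s' overlap",
                                sp[[i]]@label, sp[[j]]@label))
      }
    }
    voiR <- radiusFromVolume(object@backgroundVoiVolume)
    for (s in sp) {
      d <- sqrt(sum((s@center - object@backgroundVoiCenter)^2))
      if (d <= voiR + outerRadius(s))
        msg <- c(msg, sprintf("background VOI clips sphere '%s'", s@label))
    }
    ## VOI inside body cylinder (axis along z through bodyCenter)
    dxy <- sqrt(sum((object@backgroundVoiCenter[1:2] - object@bodyCenter[1:2])^2))
    dz <- abs(object@backgroundVoiCenter[3] - object@bodyCenter[3])
    if (dxy + voiR > object@bodyRadius ||
        dz + voiR > object@bodyLength / 2)
      msg <- c(msg, "background VOI extends outside the body compartment")
  }
  if (object@bodyRadius <= 0 || object@bodyLength <= 0)
    msg <- c(msg, "body dimensions must be positive")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("phantomSpheres", "PhantomDefinition", function(x) x@spheres)
#' @export
setMethod("phantomActivity", "PhantomDefinition", function(x) x@activity)
#' @export
setMethod("backgroundVoiCenter", "PhantomDefinition",
          function(x) x@backgroundVoiCenter)
#' @export
setMethod("backgroundVoiVolume", "PhantomDefinition",
          function(x) x@backgroundVoiVolume)

setMethod("show", "PhantomDefinition", function(object) {
  cat(sprintf("PhantomDefinition: %d spheres, body r=%.0f mm / L=%.0f mm\n",
              length(object@spheres), object@bodyRadius, object@bodyLength))
  for (s in object@spheres) show(s)
  show(object@activity)
  cat(sprintf("background VOI: %.0f ml at (%.1f, %.1f, %.1f) mm\n",
              object@backgroundVoiVolume, object@backgroundVoiCenter[1],
              object@backgroundVoiCenter[2], object@backgroundVoiCenter[3]))
})

#' Regular voxel grid specification
#'
#' Axis-aligned regular grid in world mm coordinates. The world coordinate
#' of the *center* of the first array element (R index `[1, 1, 1]`) is
#' `origin`; element `[i, j, k]` is centered at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @slot shape Integer length-3 array dimensions.
#' @slot spacing Numeric length-3 voxel spacing (mm).
#' @slot origin Numeric length-3 world coordinate of the first voxel
#'   center (mm).
#' @export
setClass("GridSpec",
  representation(shape = "integer", spacing = "numeric", origin = "numeric")
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3 || any(object@shape < 1L))
    msg <- c(msg, "shape must be three positive integers")
  if (length(object@spacing) != 3 || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive numbers (mm)")
  if (length(object@origin) != 3 || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be a finite length-3 vector (mm)")
  if (length(msg)) msg else TRUE
})

#' @rdname GridSpec-class
#' @param shape,spacing,origin See slots. If `origin` is `NULL` the grid is
#'   centered on the world origin.
#' @return A `GridSpec`.
#' @examples
#' GridSpec(c(128, 128, 64), spacing = c(2.73, 2.73, 2.78))
#' @export
GridSpec <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (is.null(origin)) origin <- -spacing * (shape - 1L) / 2
  new("GridSpec", shape = shape, spacing = spacing,
      origin = as.numeric(origin))
}

#' @export
setMethod("gridShape", "GridSpec", function(x) x@shape)
#' @export
setMethod("gridSpacing", "GridSpec", function(x) x@spacing)
#' @export
setMethod("gridOrigin", "GridSpec", function(x) x@origin)
#' @export
setMethod("voxelVolume", "GridSpec", function(x) prod(x@spacing) / 1000)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d x %d voxels at %.2f x %.2f x %.2f mm\n",
              object@shape[1], object@shape[2], object@shape[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
})

#' Image-domain signature of a reconstruction setting
#'
#' A `ReconPreset` parameterizes the image-domain appearance a
#' reconstruction algorithm imprints on the phantom: effective resolution
#' (isotropic Gaussian blur FWHM), boundary-overshoot amplitude
#' (edge-artifact ringing), background noise magnitude (coefficient of
#' variation) and noise correlation length. The algorithm parameters
#' themselves (penalization factor, iterations/subsets/filter) are carried
#' only as free-text metadata.
#'
#' @slot name Preset name (e.g. `"Q.Clear_300"`).
#' @slot blurFwhm Isotropic Gaussian blur FWHM in mm.
#' @slot overshootAmplitude Dimensionless edge-overshoot amplitude (>= 0).
#' @slot noiseCv Background noise coefficient of variation (SD/mean, >= 0).
#' @slot noiseCorrFwhm Spatial correlation FWHM of the noise (mm).
#' @slot metadata Free-text description of the emulated algorithm.
#'
#' @seealso [reconPresets()] for the bundled preset library.
#' @export
setClass("ReconPreset",
  representation(
    name = "character",
    blurFwhm = "numeric",
    overshootAmplitude = "numeric",
    noiseCv = "numeric",
    noiseCorrFwhm = "numeric",
    metadata = "character"
  )
)

setValidity("ReconPreset", function(object) {
  msg <- character()
  if (length(object@blurFwhm) != 1 || !is.finite(object@blurFwhm) ||
      object@blurFwhm <= 0)
    msg <- c(msg, "blurFwhm must be positive (mm)")
  if (object@overshootAmplitude < 0)
    msg <- c(msg, "overshootAmplitude must be >= 0")
  if (object@noiseCv < 0) msg <- c(msg, "noiseCv must be >= 0")
  if (object@noiseCorrFwhm <= 0) msg <- c(msg, "noiseCorrFwhm must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ReconPreset-class
#' @param name,blurFwhm,overshootAmplitude,noiseCv,noiseCorrFwhm,metadata
#'   See slots.
#' @return A `ReconPreset`.
#' @export
ReconPreset <- function(name, blurFwhm, overshootAmplitude = 0,
                        noiseCv = 0, noiseCorrFwhm = 4, metadata = "") {
  new("ReconPreset", name = as.character(name),
      blurFwhm = as.numeric(blurFwhm),
      overshootAmplitude = as.numeric(overshootAmplitude),
      noiseCv = as.numeric(noiseCv),
      noiseCorrFwhm = as.numeric(noiseCorrFwhm),
      metadata = as.character(metadata))
}

setMethod("show", "ReconPreset", function(object) {
  cat(sprintf(
    "ReconPreset '%s': blur %.1f mm FWHM, overshoot %.2f, noise CV %.3f (corr %.1f mm)\n",
    object@name, object@blurFwhm, object@overshootAmplitude,
    object@noiseCv, object@noiseCorrFwhm))
})

#' 3D activity-concentration volume
#'
#' A 3D array of activity concentrations (kBq/ml) on a [GridSpec-class].
#'
#' @slot values 3D numeric array (kBq/ml), all finite.
#' @slot grid The [GridSpec-class] the values live on.
#' @export
setClass("ImageVolume",
  representation(values = "array", grid = "GridSpec")
)

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3)
    msg <- c(msg, "values must be a 3D array")
  else if (!all(dim(object@values) == object@grid@shape))
    msg <- c(msg, "array dimensions do not match grid shape")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "all voxel values must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname ImageVolume-class
#' @param values,grid See slots.
#' @return An `ImageVolume`.
#' @export
ImageVolume <- function(values, grid) {
  new("ImageVolume", values = values, grid = grid)
}

#' @export
setMethod("imageValues", "ImageVolume", function(x) x@values)
#' @export
setMethod("imageGrid", "ImageVolume", function(x) x@grid)

setMethod("show", "ImageVolume", function(object) {
  v <- object@values
  cat(sprintf(
    "ImageVolume: %d x %d x %d voxels, range [%.3g, %.3g] kBq/ml%s\n",
    dim(v)[1], dim(v)[2], dim(v)[3], min(v), max(v),
    if (any(v < 0)) " (contains negatives)" else ""))
  show(object@grid)
})

#' Unbinned radial activity profile around a sphere center
#'
#' Voxel samples in the 3D vicinity of one sphere, expressed in spherical
#' coordinates relative to the sphere center: the radius of each voxel
#' center and its activity concentration, with no angular averaging or
#' radial binning.
#'
#' @slot radii Distances (mm) of the voxel centers to the sphere center.
#' @slot values Activity concentrations (kBq/ml), same length as `radii`.
#' @slot rMax Maximum radius included (mm).
#' @slot centerUsed The sphere center (mm) the radii refer to.
#' @export
setClass("SphereProfile",
  representation(radii = "numeric", values = "numeric",
                 rMax = "numeric", centerUsed = "numeric")
)

setValidity("SphereProfile", function(object) {
  msg <- character()
  if (length(object@radii) != length(object@values))
    msg <- c(msg, "radii and values must have equal length")
  if (any(object@radii < 0) || any(object@radii > object@rMax + 1e-9))
    msg <- c(msg, "radii must lie in [0, rMax]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SphereProfile", function(object) {
  cat(sprintf("SphereProfile: %d samples, r in [%.2f, %.2f] mm\n",
              length(object@radii), min(object@radii), max(object@radii)))
})

#' Result of a sphere-profile resolution fit
#'
#' Parameters of the three-parameter non-linear least-squares fit of the
#' walled-sphere/Gaussian profile model: signal S (true in-sphere activity
#' concentration), background level B, and the Gaussian point-spread sigma
#' with its FWHM (`fwhm = sigma * 2 * sqrt(2 * log(2))`), plus residual sum
#' of squares and convergence diagnostics.
#'
#' @slot signal Fitted signal S (kBq/ml).
#' @slot background Fitted background B (kBq/ml).
#' @slot sigma Fitted Gaussian sigma (mm).
#' @slot fwhm Fitted FWHM (mm).
#' @slot rss Residual sum of squares ((kBq/ml)^2).
#' @slot nSamples Number of profile samples used.
#' @slot converged `TRUE` if the optimizer converged with sigma strictly
#'   inside its bounds.
#' @slot covariance Estimated parameter covariance (3x3, may be `NA`).
#' @slot message Optimizer status message.
#' @export
setClass("FitResult",
  representation(
    signal = "numeric", background = "numeric", sigma = "numeric",
    fwhm = "numeric", rss = "numeric", nSamples = "integer",
    converged = "logical", covariance = "matrix", message = "character"
  )
)

setValidity("FitResult", function(object) {
  msg <- character()
  if (object@sigma <= 0) msg <- c(msg, "sigma must be positive")
  if (abs(object@fwhm - object@sigma * 2 * sqrt(2 * log(2))) >
      1e-9 * max(1, object@fwhm))
    msg <- c(msg, "fwhm must equal sigma * 2 * sqrt(2 * log(2))")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("fittedFwhm", "FitResult", function(x) x@fwhm)
#' @export
setMethod("fittedSigma", "FitResult", function(x) x@sigma)
#' @export
setMethod("fittedSignal", "FitResult", function(x) x@signal)
#' @export
setMethod("fittedBackground", "FitResult", function(x) x@background)

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "FitResult: S=%.3f, B=%.3f kBq/ml, FWHM=%.3f mm (sigma %.3f), rss=%.4g, n=%d%s\n",
    object@signal, object@background, object@fwhm, object@sigma,
    object@rss, object@nSamples,
    if (object@converged) "" else " [NOT CONVERGED]"))
})
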