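#' Sphere radius from volume
#'
#' Converts a sphere volume in ml to its radius in mm,
#' `r = (3 V / (4 pi))^(1/3)` with 1 ml = 1000 mm^3. Used to recover the
#' inner radii of the phantom spheres from their measured fill volumes and
#' to size spherical VOIs (e.g. the 30-ml background VOI).
#'
#' @param volume Sphere volume in ml (> 0). Vectorized.
#' @return Radius in mm.
#' @examples
#' radiusFromVolume(25.6)  # ~18.3 mm, the largest IEC sphere
#' radiusFromVolume(30)    # background VOI radius
#' @seealso [volumeFromRadius()]
#' @export
radiusFromVolume <- function(volume) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volume must be positive (ml)")
  (3 * volume * 1000 / (4 * pi))^(1 / 3)
}

#' Sphere volume from radius
#'
#' Inverse of [radiusFromVolume()]: `V = 4/3 pi r^3`, returned in ml.
#'
#' @param radius Sphere radius in mm (> 0). Vectorized.
#' @return Volume in ml.
#' @export
volumeFromRadius <- function(radius) {
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("radius must be positive (mm)")
  (4 / 3) * pi * radius^3 / 1000
}

#' True sphere-to-background activity ratio
#'
#' @param sphereAc Sphere activity concentration (kBq/ml, > 0).
#' @param backgroundAc Background activity concentration (kBq/ml, > 0).
#' @return The dimensionless SBR `sphereAc / backgroundAc`.
#' @examples
#' trueSbr(24.4, 3.1)  # ~7.87, the highest-contrast fill
#' @export
trueSbr <- function(sphereAc, backgroundAc) {
  if (any(!is.finite(sphereAc)) || any(sphereAc <= 0) ||
      any(!is.finite(backgroundAc)) || any(backgroundAc <= 0))
    stop("activity concentrations must be positive (kBq/ml)")
  sphereAc / backgroundAc
}

#' Radioactive decay scaling
#'
#' Scales an activity concentration by `2^(-elapsed / halfLife)`.
#' Because both compartments decay with the same half-life, the SBR is
#' invariant under decay.
#'
#' @param ac0 Activity concentration at time zero (kBq/ml).
#' @param elapsed Elapsed time in minutes (>= 0).
#' @param halfLife Half-life in minutes (> 0); default F-18.
#' @return Decayed activity concentration (kBq/ml).
#' @export
decayScale <- function(ac0, elapsed, halfLife = 109.77) {
  if (any(!is.finite(elapsed)) || any(elapsed < 0))
    stop("elapsed must be >= 0 (minutes)")
  if (any(!is.finite(halfLife)) || any(halfLife <= 0))
    stop("halfLife must be > 0 (minutes)")
  ac0 * 2^(-elapsed / halfLife)
}

## measured inner volumes (ml) and the derived radii/walls of the six
## IEC sphere inserts; labels are the nominal inner diameters in mm.
.nemaSphereTable <- function() {
  data.frame(
    label = c("37", "28", "22", "17", "13", "10"),
    innerVolume = c(25.6, 10.7, 5.4, 2.6, 1.2, 0.58),
    innerRadius = c(18.3, 13.7, 10.9, 8.5, 6.6, 5.2),
    stringsAsFactors = FALSE
  )
}

#' The six NEMA IEC sphere inserts
#'
#' Returns the six fillable spheres of the NEMA IEC body phantom with
#' measured inner radii 18.3, 13.7, 10.9, 8.5, 6.6 and 5.2 mm (inner
#' volumes 25.6, 10.7, 5.4, 2.6, 1.2 and 0.58 ml). Wall thicknesses are
#' only known to lie in 0.9--1.3 mm, so by default they are linearly
#' interpolated from 0.9 mm (smallest sphere) to 1.3 mm (largest);
#' pass `wallThickness` to override per sphere.
#'
#' Centers default to a ring of radius `ringRadius` in the z = 0
#' transaxial plane, equally spaced at 60 degrees with the largest sphere
#' at angle 0 (the conventional IEC arrangement).
#'
#' @param ringRadius Radius (mm) of the sphere-center ring (default 57.2).
#' @param wallThickness Optional numeric(6) wall thicknesses (mm), in the
#'   order largest to smallest sphere.
#' @return List of six [SphereSpec-class] objects, largest first.
#' @examples
#' sp <- nemaSpheres()
#' vapply(sp, innerRadius, numeric(1))
#' @export
nemaSpheres <- function(ringRadius = 57.2, wallThickness = NULL) {
  tab <- .nemaSphereTable()
  n <- nrow(tab)
  if (is.null(wallThickness)) {
    ## largest sphere gets 1.3 mm, smallest 0.9 mm
    wallThickness <- seq(1.3, 0.9, length.out = n)
  }
  stopifnot(length(wallThickness) == n)
  angles <- (seq_len(n) - 1) * (2 * pi / n)
  lapply(seq_len(n), function(i) {
    SphereSpec(tab$label[i], tab$innerRadius[i], wallThickness[i],
               center = c(ringRadius * cos(angles[i]),
                          ringRadius * sin(angles[i]), 0))
  })
}

#' Default activity fills for the three contrast levels
#'
#' The three sphere/background fills used at SBR 8:1, 4:1 and 2:1:
#' spheres at 24.4, 12.5 or 7.5 kBq/ml over backgrounds of 3.1, 3.1 or
#' 3.9 kBq/ml (decay-corrected to the start of the first scan).
#'
#' @param sbr One of `"8:1"`, `"4:1"`, `"2:1"`.
#' @return An [ActivityConfig-class].
#' @examples
#' trueSbr(24.4, 3.1)
#' nemaActivity("8:1")
#' @export
nemaActivity <- function(sbr = c("8:1", "4:1", "2:1")) {
  sbr <- match.arg(sbr)
  switch(sbr,
    "8:1" = ActivityConfig(24.4, 3.1),
    "4:1" = ActivityConfig(12.5, 3.1),
    "2:1" = ActivityConfig(7.5, 3.9))
}

#' Default NEMA IEC phantom definition
#'
#' Assembles a [PhantomDefinition-class] with the six standard spheres on
#' a 57.2-mm ring, a cylindrical body compartment large enough that its
#' boundary does not influence any in-scope measurement (radius 140 mm,
#' length 180 mm), and a 30-ml spherical background VOI centered between
#' two adjacent spheres on the ring at a 40-mm axial offset from the
#' sphere plane (validated not to clip any sphere).
#'
#' @param activity An [ActivityConfig-class]; default the 8:1 fill.
#' @param ringRadius Sphere ring radius in mm.
#' @param wallThickness Optional per-sphere wall thicknesses, see
#'   [nemaSpheres()].
#' @param bodyRadius,bodyLength Body cylinder dimensions (mm).
#' @param backgroundVoiCenter Optional VOI center override (mm).
#' @param backgroundVoiVolume Background VOI volume in ml.
#' @return A validated [PhantomDefinition-class].
#' @examples
#' ph <- iecPhantom()
#' length(phantomSpheres(ph))
#' @export
iecPhantom <- function(activity = nemaActivity("8:1"), ringRadius = 57.2,
                       wallThickness = NULL, bodyRadius = 140,
                       bodyLength = 180, backgroundVoiCenter = NULL,
                       backgroundVoiVolume = 30) {
  spheres <- nemaSpheres(ringRadius, wallThickness)
  if (is.null(backgroundVoiCenter)) {
    ## midway (in angle) between the first two spheres, 40 mm off-plane
    a <- pi / length(spheres)
    backgroundVoiCenter <- c(ringRadius * cos(a), ringRadius * sin(a), 40)
  }
  new("PhantomDefinition", spheres = spheres,
      bodyRadius = as.numeric(bodyRadius),
      bodyLength = as.numeric(bodyLength),
      bodyCenter = c(0, 0, 0),
      backgroundVoiCenter = as.numeric(backgroundVoiCenter),
      backgroundVoiVolume = as.numeric(backgroundVoiVolume),
      activity = activity)
}

#' Default simulation grid
#'
#' A 128 x 128 x 64 grid at the scanner voxel size 2.73 x 2.73 x 2.78 mm
#' (the 70-cm / 256-matrix in-plane spacing), centered on the phantom.
#' The full 256 x 256 field of view is available via `shape`.
#'
#' @param shape Grid dimensions, default `c(128, 128, 64)`.
#' @param spacing Voxel spacing in mm.
#' @return A [GridSpec-class] centered on the world origin.
#' @examples
#' 700 / 256  # in-plane voxel size of the 70-cm FOV at matrix 256
#' defaultGrid()
#' @export
defaultGrid <- function(shape = c(128, 128, 64),
                        spacing = c(2.73, 2.73, 2.78)) {
  GridSpec(shape, spacing)
}
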