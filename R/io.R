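#' Write an activity-concentration volume as NIfTI-1
#'
#' Writes the values as NIfTI with the voxel spacing in the header, plus
#' a JSON sidecar (`<path>.json` with the `.nii`/`.nii.gz` extension
#' stripped) recording the units (kBq/ml), world origin and any scan
#' metadata attributes attached by [simulateSeries()].
#'
#' @param image An [ImageVolume-class].
#' @param path Output path, ending in `.nii` or `.nii.gz`.
#' @return Invisibly, `path`.
#' @export
writeVolume <- function(image, path) {
  nim <- RNifti::asNifti(image@values)
  RNifti::pixdim(nim) <- image@grid@spacing
  RNifti::writeNifti(nim, path)
  side <- list(units = "kBq/ml", origin = image@grid@origin,
               spacing = image@grid@spacing)
  for (a in c("scan", "elapsed", "trueSphereAc", "trueBackgroundAc",
              "noiseCv")) {
    if (!is.null(attr(image, a))) side[[a]] <- attr(image, a)
  }
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.sidecarPath <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Read an activity-concentration volume from NIfTI-1
#'
#' Spacing is taken from the NIfTI header; the world origin (and any scan
#' metadata) from the JSON sidecar written by [writeVolume()] when
#' present, otherwise the grid is centered on the world origin.
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return An [ImageVolume-class]; sidecar metadata is restored as
#'   attributes.
#' @export
readVolume <- function(path) {
  nim <- RNifti::readNifti(path)
  values <- array(as.numeric(nim), dim = dim(nim))
  spacing <- RNifti::pixdim(nim)[1:3]
  origin <- NULL
  meta <- NULL
  sc <- .sidecarPath(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$origin)) origin <- as.numeric(meta$origin)
    if (!is.null(meta$spacing)) spacing <- as.numeric(meta$spacing)
  }
  img <- ImageVolume(values, GridSpec(dim(values), spacing, origin))
  for (a in c("scan", "elapsed", "trueSphereAc", "trueBackgroundAc",
              "noiseCv")) {
    if (!is.null(meta[[a]])) attr(img, a) <- meta[[a]]
  }
  img
}
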