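NULL

#' @export
setGeneric("sphereLabel", function(x) standardGeneric("sphereLabel"))

#' @export
setGeneric("innerRadius", function(x) standardGeneric("innerRadius"))

#' @export
setGeneric("wallThickness", function(x) standardGeneric("wallThickness"))

#' @export
setGeneric("outerRadius", function(x) standardGeneric("outerRadius"))

#' @export
setGeneric("sphereCenter", function(x) standardGeneric("sphereCenter"))

#' @export
setGeneric("phantomSpheres", function(x) standardGeneric("phantomSpheres"))

#' @export
setGeneric("phantomActivity", function(x) standardGeneric("phantomActivity"))

#' @export
setGeneric("backgroundVoiCenter", function(x) standardGeneric("backgroundVoiCenter"))

#' @export
setGeneric("backgroundVoiVolume", function(x) standardGeneric("backgroundVoiVolume"))

#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))

#' @export
setGeneric("imageGrid", function(x) standardGeneric("imageGrid"))

#' @export
setGeneric("fittedFwhm", function(x) standardGeneric("fittedFwhm"))

#' @export
setGeneric("fittedSigma", function(x) standardGeneric("fittedSigma"))

#' @export
setGeneric("fittedSignal", function(x) standardGeneric("fittedSignal"))

#' @export
setGeneric("fittedBackground", function(x) standardGeneric("fittedBackground"))
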