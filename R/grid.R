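## internal grid helpers (world mm <-> 1-based array index)

## per-axis voxel-center coordinates
.axisCoords <- function(grid) {
  lapply(1:3, function(a)
    grid@origin[a] + (seq_len(grid@shape[a]) - 1) * grid@spacing[a])
}

## world extent of the voxel-center lattice per axis: 3x2 matrix (lo, hi)
.centerExtent <- function(grid) {
  lo <- grid@origin
  hi <- grid@origin + (grid@shape - 1L) * grid@spacing
  cbind(lo, hi)
}

## world extent including the outer half-voxel border
.edgeExtent <- function(grid) {
  lo <- grid@origin - grid@spacing / 2
  hi <- grid@origin + (grid@shape - 1L + 0.5) * grid@spacing
  cbind(lo, hi)
}

## is the ball of `radius` around `center` inside the voxel-center lattice?
## returns NULL if yes, otherwise a message naming the offending margins
.ballClipMessage <- function(center, radius, grid, what = "ball") {
  ext <- .centerExtent(grid)
  ax <- c("x", "y", "z")
  bad <- character()
  for (a in 1:3) {
    if (center[a] - radius < ext[a, 1])
      bad <- c(bad, sprintf("%s low (%.1f < %.1f mm)", ax[a],
                            center[a] - radius, ext[a, 1]))
    if (center[a] + radius > ext[a, 2])
      bad <- c(bad, sprintf("%s high (%.1f > %.1f mm)", ax[a],
                            center[a] + radius, ext[a, 2]))
  }
  if (!length(bad)) return(NULL)
  sprintf("%s of radius %.1f mm around (%.1f, %.1f, %.1f) clipped by image boundary: %s",
          what, radius, center[1], center[2], center[3],
          paste(bad, collapse = ", "))
}

## index range of voxels whose centers fall within center +/- radius
.indexWindow <- function(center, radius, grid) {
  lo <- pmax(1L, ceiling((center - radius - grid@origin) / grid@spacing) + 1L)
  hi <- pmin(grid@shape,
             floor((center + radius - grid@origin) / grid@spacing) + 1L)
  if (any(lo > hi)) return(NULL)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

## centered subsample offsets for one axis: s points spanning one voxel
.subOffsets <- function(s, spacing) {
  ((seq_len(s) - (s + 1) / 2) / s) * spacing
}
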