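#' Rasterize the noise-free phantom onto a voxel grid
#'
#' Produces the ground-truth activity-concentration volume: each voxel
#' value is the volume-weighted mixture of compartment concentrations
#' (sphere interior = sphere AC, sphere wall = 0, body background =
#' background AC, outside the body = 0), with partial-volume fractions
#' estimated by `supersample^3` regular subsampling of each voxel.
#'
#' All spheres and the background VOI must lie inside the grid; the body
#' cylinder itself may be truncated by the grid since no in-scope
#' measurement involves the body boundary.
#'
#' @param phantom A [PhantomDefinition-class].
#' @param grid A [GridSpec-class].
#' @param supersample Subsamples per voxel edge (integer >= 1); 4 gives
#'   partial-volume fractions accurate to ~1/64 of a voxel.
#' @return An [ImageVolume-class] with the true (unblurred) AC map.
#' @examples
#' ph <- iecPhantom()
#' vol <- rasterizeTruth(ph, defaultGrid(), supersample = 2)
#' range(imageValues(vol))
#' @export
rasterizeTruth <- function(phantom, grid, supersample = 4L) {
  supersample <- as.integer(supersample)
  if (supersample < 1L) stop("supersample must be >= 1")
  act <- phantom@activity
  sAc <- act@sphereAc
  bAc <- act@backgroundAc

  ## containment: spheres and background VOI inside the grid edges
  ext <- .edgeExtent(grid)
  checkBall <- function(center, radius, what) {
    if (any(center - radius < ext[, 1]) || any(center + radius > ext[, 2]))
      stop(sprintf("%s (radius %.1f mm) not contained in grid", what, radius))
  }
  for (s in phantom@spheres)
    checkBall(s@center, outerRadius(s), paste0("sphere '", s@label, "'"))
  checkBall(phantom@backgroundVoiCenter,
            radiusFromVolume(phantom@backgroundVoiVolume), "background VOI")

  ax <- .axisCoords(grid)
  nx <- grid@shape[1]; ny <- grid@shape[2]; nz <- grid@shape[3]

  ## body cylinder (axis along z): separable in-plane x axial fractions
  offx <- .subOffsets(supersample, grid@spacing[1])
  offy <- .subOffsets(supersample, grid@spacing[2])
  offz <- .subOffsets(supersample, grid@spacing[3])
  xs <- outer(ax[[1]], offx, "+") - phantom@bodyCenter[1]  # nx x s
  ys <- outer(ax[[2]], offy, "+") - phantom@bodyCenter[2]
  ## fraction of in-plane subsample pairs inside the body circle
  fxy <- matrix(0, nx, ny)
  r2 <- phantom@bodyRadius^2
  for (k in seq_len(supersample)) {
    xk2 <- xs[, k]^2
    for (l in seq_len(supersample)) {
      fxy <- fxy + (outer(xk2, ys[, l]^2, "+") <= r2)
    }
  }
  fxy <- fxy / supersample^2
  zs <- outer(ax[[3]], offz, "+") - phantom@bodyCenter[3]
  fz <- rowMeans(abs(zs) <= phantom@bodyLength / 2)

  values <- array(0, dim = c(nx, ny, nz))
  bodyFrac <- outer(fxy, fz)     # nx x ny x nz
  values[] <- bAc * bodyFrac

  ## sphere compartments: only voxels near each sphere need revisiting
  subs <- as.matrix(expand.grid(x = offx, y = offy, z = offz))  # s^3 x 3
  halfDiag <- sqrt(sum((grid@spacing / 2)^2))
  for (s in phantom@spheres) {
    rIn <- s@innerRadius
    rOut <- outerRadius(s)
    win <- .indexWindow(s@center, rOut + halfDiag, grid)
    if (is.null(win)) next
    ii <- win$lo[1]:win$hi[1]; jj <- win$lo[2]:win$hi[2]
    kk <- win$lo[3]:win$hi[3]
    cen <- as.matrix(expand.grid(x = ax[[1]][ii], y = ax[[2]][jj],
                                 z = ax[[3]][kk]))
    nV <- nrow(cen)
    fin <- numeric(nV); fout <- numeric(nV)
    for (m in seq_len(nrow(subs))) {
      d2 <- (cen[, 1] + subs[m, 1] - s@center[1])^2 +
            (cen[, 2] + subs[m, 2] - s@center[2])^2 +
            (cen[, 3] + subs[m, 3] - s@center[3])^2
      fin <- fin + (d2 <= rIn^2)
      fout <- fout + (d2 <= rOut^2)
    }
    fin <- fin / nrow(subs)
    fout <- fout / nrow(subs)
    block <- array(values[ii, jj, kk], dim = c(length(ii), length(jj), length(kk)))
    bf <- array(bodyFrac[ii, jj, kk], dim = dim(block))
    ## interior = sphere AC, wall = cold, remainder keeps background share
    block[] <- sAc * fin + bAc * bf * (1 - fout)
    values[ii, jj, kk] <- block
  }

  out <- ImageVolume(values, grid)
  attr(out, "supersample") <- supersample
  out
}
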