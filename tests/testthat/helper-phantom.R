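## shared fixtures (built in code) and independent oracles

## a phantom holding a single sphere at the world origin, with a small
## background VOI on the axis above it
singleSpherePhantom <- function(sphere = NULL, sphereAc = 24.4,
                                backgroundAc = 3.1, bodyRadius = 55,
                                bodyLength = 110, voiCenter = c(0, 0, 30),
                                voiVolume = 5) {
  if (is.null(sphere)) {
    sphere <- nemaSpheres()[[4]]  # 17 mm
    sphere@center <- c(0, 0, 0)
  }
  new("PhantomDefinition", spheres = list(sphere),
      bodyRadius = bodyRadius, bodyLength = bodyLength,
      bodyCenter = c(0, 0, 0), backgroundVoiCenter = voiCenter,
      backgroundVoiVolume = voiVolume,
      activity = ActivityConfig(sphereAc, backgroundAc))
}

## scanner-spacing grid just large enough for a single centered sphere
smallGrid <- function(nxy = 44L, nz = 42L) {
  GridSpec(c(nxy, nxy, nz), spacing = c(2.73, 2.73, 2.78))
}

## ---- independent oracles ------------------------------------------------

## brute-force 3D oracle for the sphere-Gaussian profile: discrete sum of
## the Gaussian kernel over a fine rasterization of the sphere, with
## partial-volume weights (5^3 subdivision) for cells straddling the
## boundary
sphereGaussOracle3d <- function(r, R, sigma, h = 0.25) {
  g <- seq(-R - h / 2, R + h / 2, by = h)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  d <- sqrt(rowSums(pts^2))
  halfDiag <- sqrt(3) * h / 2
  interior <- d <= R - halfDiag
  boundary <- !interior & d <= R + halfDiag
  w <- as.numeric(interior)
  if (any(boundary)) {
    off <- ((1:5) - 3) / 5 * h
    sub <- as.matrix(expand.grid(off, off, off))
    bp <- pts[boundary, , drop = FALSE]
    frac <- numeric(nrow(bp))
    for (m in seq_len(nrow(sub))) {
      frac <- frac + (rowSums(sweep(bp, 2, -sub[m, ])^2) <= R^2)
    }
    w[boundary] <- frac / nrow(sub)
  }
  keep <- w > 0
  pts <- pts[keep, , drop = FALSE]
  w <- w[keep]
  norm <- h^3 / ((2 * pi)^(3 / 2) * sigma^3)
  vapply(r, function(r0) {
    d2 <- pts[, 1]^2 + pts[, 2]^2 + (pts[, 3] - r0)^2
    norm * sum(w * exp(-d2 / (2 * sigma^2)))
  }, numeric(1))
}

## 1D quadrature oracle for the central value f(0): integral of the
## isotropic Gaussian over a ball of radius R
sphereGaussCenterOracle <- function(R, sigma) {
  stats::integrate(function(rp)
    4 * pi * rp^2 * exp(-rp^2 / (2 * sigma^2)) /
      ((2 * pi)^(3 / 2) * sigma^3),
    lower = 0, upper = R, rel.tol = 1e-10)$value
}

## ---- exact rank-test enumeration oracles --------------------------------

## two-sided signed-rank p by enumerating all 2^n sign assignments
wilcoxonSignOracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  vObs <- sum(rk[d > 0])
  ev <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vAll <- as.vector(signs %*% rk)
  mean(abs(vAll - ev) >= abs(vObs - ev) - 1e-9)
}

## two-sided Mann-Whitney p by enumerating all choose(n, nA) group splits
mannWhitneyOracle <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a)
  rk <- rank(pooled)
  uOf <- function(idx) sum(rk[idx]) - nA * (nA + 1) / 2
  uObs <- uOf(seq_len(nA))
  ev <- nA * length(b) / 2
  splits <- utils::combn(length(pooled), nA, simplify = FALSE)
  uAll <- vapply(splits, uOf, numeric(1))
  mean(abs(uAll - ev) >= abs(uObs - ev) - 1e-9)
}

## exact Kruskal-Wallis p by enumerating all distinct group assignments
kruskalWallisOracle <- function(groups) {
  sizes <- vapply(groups, length, integer(1))
  pooled <- unlist(groups, use.names = FALSE)
  hOf <- function(g) {
    n <- length(pooled)
    rk <- rank(pooled)
    h <- 12 / (n * (n + 1)) *
      sum(tapply(rk, g, function(r) length(r) * (mean(r) - (n + 1) / 2)^2))
    ties <- table(pooled)
    h / (1 - sum(ties^3 - ties) / (n^3 - n))
  }
  gObs <- factor(rep(seq_along(groups), sizes))
  hObs <- hOf(gObs)
  n <- sum(sizes)
  ## enumerate via permutations of the label multiset (n is small)
  labs <- rep(seq_along(sizes), sizes)
  perms <- unique(combinat_perms(labs))
  hs <- vapply(perms, function(l) hOf(factor(l, levels = seq_along(sizes))),
               numeric(1))
  mean(hs >= hObs - 1e-9)
}

## all permutations of a (short) vector, as a list
combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    rest <- combinat_perms(v[-i])
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}
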