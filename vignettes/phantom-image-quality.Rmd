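---
title: "Quantifying PET image quality with the NEMA IEC body phantom"
author: "PhantomIQ authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PET image quality with the NEMA IEC body phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhantomIQ)
```

## The measurement problem

PET reconstruction settings trade contrast recovery against noise: more
iterations, resolution modeling (PSF) or a weaker penalization factor in
Bayesian penalized likelihood (BPL) reconstruction all sharpen small hot
objects but amplify background noise. Scanner sites quantify this
tradeoff with the NEMA IEC body phantom: six hollow spheres
(nominal diameters 10–37 mm) filled with a known activity concentration
over a warm background, imaged repeatedly and evaluated per
reconstruction setting with three families of metrics:

* **Reconstructed spatial resolution**, estimated per sphere by fitting
  the analytic radial profile of a walled homogeneous sphere convolved
  with an isotropic 3D Gaussian point-spread function;
* **Contrast recovery**, as the maximum-voxel ratio CRmax and the
  peak-VOI ratio CRpeak (mean of the best-placed 1.2-cm spherical VOI),
  both relative to the true decay-corrected activity concentration;
* **Background SNR**, the mean over standard deviation of the voxels in
  a 30-ml spherical background VOI.

PhantomIQ implements this full analysis chain and, because the deposited
scanner volumes are not needed to validate the *methods*, ships a
synthetic phantom generator whose outputs exercise every stage with
known ground truth.

## The resolution model

The activity profile of a homogeneous sphere of radius $R$ at unit
concentration, blurred by an isotropic Gaussian of width $\sigma$, has
the closed form

$$
f(r;R,\sigma) = \tfrac12\!\left[\operatorname{erf}\!\frac{R-r}{\sigma\sqrt2}
  + \operatorname{erf}\!\frac{R+r}{\sigma\sqrt2}\right]
  - \frac{\sigma}{r\sqrt{2\pi}}\!\left[e^{-(r-R)^2/2\sigma^2}
  - e^{-(r+R)^2/2\sigma^2}\right],
$$

with the removable singularity at $r=0$ handled by series expansion and
the difference of exponentials evaluated through $\sinh$ to avoid
cancellation (`sphereGaussProfile()`). A hollow sphere insert is then
modeled as hot interior, cold plastic wall and warm exterior:

$$
m(r) = S\,f(r;R_\mathrm{in},\sigma) + B\,[1 - f(r;R_\mathrm{in}+d,\sigma)],
$$

where $S$ is the in-sphere concentration, $B$ the background and $d$ the
wall thickness. `fitProfile()` fixes $R_\mathrm{in}$ and $d$ to their
known values and estimates $(S, B, \sigma)$ by unweighted non-linear
least squares (Levenberg–Marquardt with box bounds) on the *unbinned*
3D samples around the sphere center — every voxel within the fit radius
contributes one (radius, value) pair, with no angular averaging. The
reported resolution is $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$.

Numerical choices, all surfaced as arguments:

* fit radius $R_\mathrm{out} + \max(12\ \mathrm{mm},\ 2.5\times$ initial
  FWHM guess$)$, enough to anchor the background shoulder;
* initialization $B_0$ = median beyond $R_\mathrm{out}+6$ mm, $S_0$ =
  core mean minus $B_0$ (max-value fallback for spheres with
  $R_\mathrm{in} < 7$ mm), $\sigma_0 = 2$ mm; bounds
  $S \in (0, 10S_0]$, $B \in [0, 10B_0]$, $\sigma \in [0.3, 15]$ mm;
* a fit ending with $\sigma$ on a bound is flagged not-converged;
* the sphere center is first refined by an iterated
  background-subtracted centroid (`refineCenter()`), accurate to well
  under half a voxel even at a background CV of 0.1.

The model deliberately omits the edge-artifact overshoot (the Gaussian
PSF assumption is an approximation by design); fit quality is carried in
the residual sum of squares. A practical consequence, visible in the
synthetic studies: on images with strong overshoot the fitted FWHM reads
*below* the nominal Gaussian blur, because the ringing steepens the edge
the fit measures. This mirrors the behavior of the estimator on real
resolution-modeling reconstructions.

## Contrast recovery and SNR

`crMax()` takes the maximum voxel within the sphere's outer radius plus
a small margin. `peakVoiMean()` maximizes the mean of a 12-mm spherical
VOI over candidate centers within $R_\mathrm{out}$ of the sphere center,
which keeps the VOI inside $R_\mathrm{out} + 6$ mm of the sphere.
Candidates sit on the lattice obtained by subdividing each voxel
$3\times3\times3$ (step $\approx 0.91$ mm at the scanner grid — the same
subdivision supplies the partial-volume weights, making the VOI mean an
exact moving-ball average on that lattice, computed via FFT). An
exhaustive 0.25-mm brute-force search in the test suite bounds the
residual discretization error below 0.5%. Near-ties (within $10^{-3}$
relative, the numerically flat plateau of a large noiseless sphere) are
broken toward the nominal center.

In the per-volume metrics table the CRmax search ball is enlarged to
cover the peak VOI's full support, so `CRmax >= CRpeak` holds by
containment rather than by luck. `backgroundSnr()` uses plain
voxel-center membership in the 30-ml VOI ($\approx$ 1440 voxels at the
scanner grid, so surface weighting is immaterial); a zero standard
deviation is flagged degenerate instead of raising.

## What the synthetic generator emulates — and what it does not

`rasterizeTruth()` produces the ground-truth concentration map
(supersampled partial-volume fractions; hot interiors, cold walls, warm
cylindrical body). `applyReconSignature()` then imprints a
reconstruction setting's image-domain signature:

* **Resolution**: isotropic Gaussian blur of the preset's FWHM, applied
  in the Fourier domain. The voxel-average prefilter of the raster is
  compensated per axis (transfer $\min(1, G/B_s)$, where $B_s$ is the
  exact transfer of the $s$-point subsample average), so the realized
  PSF of the *sampled* volume equals the nominal FWHM; for blur far
  below the voxel size the clamp turns the filter into the identity.
  The filter is circular on the periodized grid, so total activity is
  conserved exactly; phantoms should stay a few FWHM clear of the grid
  edges.
* **Edge artifacts**: an unsharp-mask ringing term
  $a\,[x - G_{1.5\mathrm{FWHM}}(x)]$ added to the blurred volume. One
  parameter reproduces the boundary-overshoot phenomenology of
  resolution-modeling reconstruction; no claim is made of modeling true
  PSF-reconstruction Gibbs behavior.
* **Noise**: additive Gaussian noise, spatially correlated by a 4-mm
  Gaussian, rescaled so the SD inside the background VOI equals
  `noiseCv` times the background mean; deterministic per seed.
  It is *not* Poisson sinogram noise — downstream metrics only require a
  controllable background mean/SD and correlation scale, and no claim is
  made about noise texture differences between algorithms.
* **Series**: five scans at 30-min intervals with F-18 decay
  (half-life 109.77 min) on both compartments, per-scan seeds
  `seed + scan - 1`, and optional count-loss inflation of the noise CV
  by $2^{\,t/2T_{1/2}}$.

Passing tests on these volumes validates the estimators (geometry,
profile fitting, VOI search, rank statistics) — they do not validate
scanner physics: attenuation, scatter, randoms, TOF weighting,
reconstruction non-stationarity and inter-algorithm noise texture are
all out of scope, which is why the bundled presets are explicitly
fixtures. Their blur defaults are published mean resolutions at the
highest contrast and their noise CVs the reciprocal published SNRs;
overshoot amplitudes are a one-time phenomenological choice encoding
"stronger with lower penalization, strongest for PSF with a narrow
filter, absent for plain OSEM".

### Design choices that were genuinely open

* **Sphere layout**: centers on the conventional 57.2-mm ring, equally
  spaced at 60°, largest sphere at angle 0; configurable.
* **Wall thicknesses**: only the 0.9–1.3 mm range is known per set; we
  interpolate linearly from 0.9 mm (smallest) to 1.3 mm (largest),
  configurable per sphere.
* **Body shape**: a cylinder (radius 140 mm, length 180 mm) large
  enough that the boundary cannot influence any in-scope VOI; the true
  torso cross-section would only change voxels no metric reads. The
  body may be truncated by the default 128×128×64 grid (axial extent
  177.9 mm); containment is enforced for spheres and the background VOI
  only.
* **Background VOI placement**: on the sphere ring at the angle midway
  between the two largest spheres, 40 mm off the sphere plane —
  validated at construction against clipping any sphere or leaving the
  body.
* **Grid**: 128×128×64 at 2.73×2.73×2.78 mm (cropped from the full
  256-matrix field of view). This keeps a complete simulated study —
  four presets × three contrast levels × five scans, with all metrics —
  around a minute on one core, the scale at which the test suite and
  the acceptance script run; the full grid is available by
  configuration.
* **Statistics pairing**: the resolution comparison pairs by
  (scan × sphere) over the three largest spheres (n = 15); the SNR
  comparison pairs by (scan × contrast level), also n = 15, matching
  the pooled SNR summary. No multiple-testing correction is applied;
  verdicts use p < 0.05.
* **Tradeoff rule**: method A beats method B on contrast when the mean
  relative CRpeak difference exceeds 10% for at least one of the 10, 13
  and 17-mm spheres with a consistent sign (conflicting signs above
  threshold fall back to "equal"); the SNR verdict is the paired
  Wilcoxon sign at p < 0.05. The relative-difference denominator is the
  second-named (comparator) method, so the definition is intentionally
  not antisymmetric.

### Known limitations

* At the 2.73-mm scanner grid, sampling a sharp sphere edge leaves a
  percent-level aliasing ripple near the boundary; the pointwise match
  between simulated volumes and the closed-form profile is therefore
  verified on a 0.5-mm sampling, while at the scanner grid the fit
  (which averages the ripple over thousands of voxels) recovers the
  applied blur to well within 0.15 mm.
* The FWHM estimate is contrast-dependent in noise (fit scatter grows as
  contrast drops), as expected from the estimator; the package reports
  per-fit convergence and residuals rather than hiding them.
* Rank tests use exact null distributions for small untied samples
  (signed-rank n ≤ 25; rank-sum total n ≤ 12; Kruskal–Wallis enumerated
  in-package for total n ≤ 12) and tie-corrected normal/χ²
  approximations otherwise.

## A minimal study

```{r study, eval = FALSE}
presets <- reconPresets(c("Q.Clear_300", "OSEM+TOF_2/17"))
st <- runStudy(presets, sbrs = c("8:1", "4:1", "2:1"),
               nScans = 5, seed = 42)
reports <- buildReports(st$metrics, st$fits)
reports$snr
classifyTradeoff(subset(st$metrics, preset == "Q.Clear_300"),
                 subset(st$metrics, preset == "OSEM+TOF_2/17"))
```

Volumes can be exported and re-imported as NIfTI-1 with a JSON sidecar
(`writeVolume()` / `readVolume()`), experiments described in YAML
(`writeExperimentConfig()`), and the same pipeline driven from a shell
via the `phantomiq` script in `inst/scripts/` (simulate / analyze /
compare).
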