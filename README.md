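# PhantomIQ

Quantitative image-quality analysis for PET reconstructions, built
around the NEMA IEC body phantom: six hollow spheres (nominal diameters
10–37 mm, measured inner radii 18.3/13.7/10.9/8.5/6.6/5.2 mm) filled at
a known activity concentration over a warm background and imaged
repeatedly. The package is aimed at physicists and methodologists
comparing reconstruction settings (Bayesian penalized likelihood at
different penalization factors versus TOF-OSEM with and without PSF
modeling) on three axes:

* **Reconstructed spatial resolution.** Per sphere, the full 3D
  vicinity is transformed to spherical coordinates about the sphere
  center and the unbinned (radius, activity) samples are fitted with
  the analytic profile of a walled homogeneous sphere convolved with an
  isotropic 3D Gaussian,

  `m(r) = S·f(r; R_in, σ) + B·[1 − f(r; R_in + d, σ)]`,

  `f(r;R,σ) = ½[erf((R−r)/σ√2) + erf((R+r)/σ√2)] −
  (σ/r√(2π))[e^{−(r−R)²/2σ²} − e^{−(r+R)²/2σ²}]`,

  with the sphere radius `R_in` and wall `d` fixed to their known
  values and (S, B, σ) free (non-linear least squares). The resolution
  estimate is `FWHM = 2√(2 ln 2)·σ`.
* **Contrast recovery.** `CRmax` (maximum voxel / true decay-corrected
  activity concentration) and `CRpeak` (mean of the 1.2-cm spherical
  VOI positioned to maximize it / true AC).
* **Background SNR.** Mean over standard deviation in a 30-ml spherical
  background VOI.

A comparison layer reproduces the standard study design: paired
Wilcoxon signed-rank tests (exact for small untied samples),
Mann-Whitney U and Kruskal–Wallis across contrast levels, and a
CR-vs-SNR tradeoff classification ("higher" = mean relative CRpeak
difference > 10% for at least one of the 10/13/17-mm spheres; SNR
verdicts by Wilcoxon significance at p < 0.05).

Because validating these estimators needs ground truth rather than
scanner data, the package includes a synthetic phantom generator:
supersampled rasterization of the phantom (hot spheres, cold walls,
warm body), reconstruction-dependent Gaussian blur with an
edge-artifact overshoot term, spatially correlated background noise
with seed-exact reproducibility, and repeated scans with F-18 decay.
Nine bundled presets carry published summary statistics (mean
resolution, mean SNR) as simulation fixtures.

## Worked example

```r
library(PhantomIQ)
ph <- iecPhantom()                       # spheres 24.4, background 3.1 kBq/ml
series <- simulateSeries(ph, defaultGrid(), reconPresets("Q.Clear_300")[[1]],
                         nScans = 5, seed = 42)
img <- series[[1]]

fitSphereResolution(img, phantomSpheres(ph)[[1]])
#> FitResult: S=24.616, B=3.034 kBq/ml, FWHM=3.818 mm (sigma 1.621), rss=1369, n=6353

mt <- analyzeVolume(img, ph, preset = "Q.Clear_300", sbr = "8:1")
print(mt[, c("label", "diameterMm", "crMax", "crPeak", "snr")], digits = 3)
#>   label diameterMm crMax crPeak  snr
#> 1    37       36.6  1.07  1.019 6.88
#> 2    28       27.4  1.10  1.007 6.88
#> 3    22       21.8  1.06  1.015 6.88
#> 4    17       17.0  1.08  0.991 6.88
#> 5    13       13.2  1.05  0.778 6.88
#> 6    10       10.4  1.02  0.533 6.88
```

Reading the output: the fitted signal and background (24.6 and 3.0
kBq/ml) recover the configured fill; the fitted FWHM (3.8 mm) sits
slightly below the preset's nominal 4.3-mm blur because the preset also
adds edge-artifact overshoot, which steepens the edge the Gaussian
model measures. Contrast recovery degrades from ≈1.0 for the 37-mm
sphere to ≈0.53 for the 10-mm sphere (partial-volume effect), CRmax
exceeds CRpeak everywhere, and the background SNR of ≈6.9 matches the
preset's noise CV of 1/7.

Full studies (presets × contrast levels × scans) run through
`runStudy()`, are summarized with `buildReports()` (resolution and SNR
tables, recovery curves, tradeoff matrix) and plotted with
`plotRecoveryCurves()` / `plotTradeoff()`. Volumes round-trip as
NIfTI-1 plus JSON sidecar; `inst/scripts/phantomiq` exposes
simulate/analyze/compare subcommands over YAML configs. The methods,
default parameters and known limitations are documented in the vignette
(`vignettes/phantom-image-quality.Rmd`).

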