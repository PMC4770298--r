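---
title: "Scanner-based absorbance profilometry: model, design and limits"
author: "scanprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanner-based absorbance profilometry: model, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanprof)
```

## The measurement model

A transparent microfluidic structure is filled with an absorbing dye and
scanned in transmission. At each pixel the dye column of depth $d$ (µm)
attenuates light according to the Beer–Lambert law, so the absorbance in
one colour channel,

$$A = \log_{10}\!\frac{I_0}{I_t} = \varepsilon\, c\, d,$$

is proportional both to the dye concentration $c$ (mM) and to the optical
path length $d$, with the extinction coefficient $\varepsilon$
(mM⁻¹ µm⁻¹) as the single calibration constant. $I_0$ and $I_t$ are
16-bit grayscale counts; $I_0$ comes either from a paired scan of the
same structure filled with blank solvent (the default and the more
faithful mode, since it cancels pixel-wise illumination structure) or
from the mean of a designated blank region of the sample itself.

Inverting per pixel, $d = A/(\varepsilon c)$, turns an absorbance map
into a depth map on a physical grid of pitch $p = 25400/\mathrm{dpi}$ µm.
All downstream morphometry is arithmetic on that grid: a region's volume
is $\sum d \cdot p^2$ (reported in nL, $10^6$ µm³), its half-depth area
is the area of pixels reaching at least half the region's maximum depth.

Two assumptions matter. First, log base 10: the magnitude of
$\varepsilon$ and the standard absorbance convention both presume decadic
logarithms, and the calibration is self-consistent only under one fixed
base. Second, one bounding surface of the structure is taken as flat.
Where both surfaces deform (laminated film chambers), the reconstruction
is the *summed* deformation of floor and ceiling: the rendered surface
shape is advisory, but the integrated volume remains exact, which is the
quantity of interest for chamber QC.

## Calibration

`fitSeries()` fits an ordinary least-squares line of mean absorbance on
depth (concentration fixed) or on concentration (depth fixed), and
derives $\varepsilon$ from the slope divided by the fixed quantity. The
intercept is deliberately left free: a forced-origin fit would hide
reference-mismatch offsets that the intercept magnitude exposes as a QC
diagnostic. $R^2$ is always reported; a non-positive slope flags the
resulting $\varepsilon$ invalid rather than erroring, so a batch of fits
can be triaged. `combineFits()` pools several series by
inverse-variance-weighted mean of $\varepsilon$ (equal weights when
standard errors are unavailable, e.g. for noiseless synthetic series).

Because the law is bilinear in $c$ and $d$, a depth series and a
concentration series generated with one $\varepsilon$ must agree; the
test suite asserts this equivalence to four significant figures on
noiseless synthetic data.

The linear regime is bounded: the calibration holds below an absorbance
of about 0.6, so `recommendConcentration()` returns
$c = A_{\max}/(\varepsilon d_{\max})$, placing the deepest point of the
structure exactly at the ceiling (default $A_{\max} = 0.6$). Deep
chambers therefore take dilute dye (a 160 µm chamber tolerates up to
~7.2 mM; 6 mM gives $A = 0.4992$) while 10 µm wells need two orders of
magnitude more concentrated solution.

## The forward model and what it emulates

`renderDepthField()` rasterizes parametric features onto a pixel grid;
`simulateScan()` converts a depth field into a 16-bit RGB scan:
$I_t = I_0\,10^{-\varepsilon_x c d}$ per channel $x$, optional Poisson
shot noise, additive Gaussian sensor noise, rounding to integer counts,
clipping to $[0, 65535]$. The per-channel extinction coefficients default
to an Allura-Red-like red dye: $\varepsilon_B = 5.2\times10^{-4}$,
$\varepsilon_G = \varepsilon_B/2$, $\varepsilon_R = 0$ (the red channel
of such a dye is indistinguishable from background, which is why the
blue channel carries the measurement).

Feature shapes mirror the common fabrication routes:

* `cylinder_chamber` — flat-bottomed cylinder (molded/etched chamber).
* `basin_well` — isotropic wet-etch profile: flat bottom of the mask
  radius $r$, quarter-circle sidewall of radius $d$; closed-form volume
  $\pi\left(r^2 d + \tfrac{\pi}{2} r d^2 + \tfrac{2}{3} d^3\right)$.
* `cone_well` — single-pulse laser-ablated pit, a cone (volume
  $\pi r^2 d/3$; half-depth area exactly ¼ of the mouth).
* `ablated_channel` — straight channel with Gaussian transverse profile
  (single laser stroke), optional per-slice width jitter to emulate power
  fluctuation at the beam's dispersion region, which concentrates
  variance on the sidewalls and leaves the floor quiet.
* `sagging_chamber` — cylinder minus a spherical-cap sag whose volume is
  $k_\mathrm{sag} r^3$. Only the cubic volume scaling is physically
  constrained; the spherical-cap shape is this package's choice of a
  smooth, single-parameter cap (the cap height solves the cubic
  cap-volume equation numerically). Since the designed volume grows as
  $r^2$ and the sag as $r^3$, the fractional deficit grows linearly with
  radius — large laminated chambers lose a substantial fraction of their
  design volume, which is exactly the failure mode the volume check
  targets. $k_\mathrm{sag}$ is treated as dimensionless
  (µm³ of sag per µm³ of $r^3$).

Pixel values take the depth at the pixel centre with no area-weighted
anti-aliasing at feature edges. That makes rendering exactly testable
(volume discretization error shrinks as $p^2$ and is below 1% once
$r/p \gtrsim 20$) at the cost of one-pixel edge roughness, which is far
below the sensor noise the simulator injects anyway.

The noise model is additive Gaussian on transmitted counts (default
sd = 100 counts) applied after the optics and before quantization, with
an optional Poisson term. A real scanner's noise is not published; the
additive model is the simplest one that reproduces the two behaviours
the pipeline relies on — depth noise proportional to
$1/(I_t \ln 10\, \varepsilon c)$ and $1/\sqrt{N}$ averaging across
repeat scans. No gamma/tone curve is applied by default (film-scan mode
is assumed radiometrically linear); a `gamma` parameter exists for
sensitivity studies. The simulator does **not** model optical blur
(scanner MTF), refraction at curved dye/substrate interfaces, dye
photobleaching, or scan-to-scan geometric drift — consequences below.

## Numerical choices

* **Quantization floor.** Counts are integers, so one count of rounding
  bounds the attainable absorbance precision at
  $\sim 0.5/(I_t \ln 10)$. For sub-micrometre depths this exceeds a
  relative 0.5%, so round-trip accuracy statements apply from ~1 µm up;
  blank pixels are checked absolutely (±0.01 µm).
* **Zero counts.** $I_t \le 0$ after dark-floor subtraction would give
  infinite absorbance; such pixels are clamped to one count and flagged
  in the validity mask instead of being dropped, preserving region areas.
* **Negative depths.** Noise drives blank-region absorbance slightly
  negative; reconstructed negative depths are retained (not clipped) so
  population statistics on flat regions stay unbiased. Clipping is left
  to report time.
* **Segmentation.** Pixels at or above a depth threshold (explicit, or an
  Otsu split of the depth histogram) are labelled by 8-connected
  components, small regions (< 10 px by default) discarded, labels
  assigned in row-major centroid order for determinism. Only thresholded
  pixels enter a region's volume: the shallow rim below threshold is
  excluded, which the recovery property bounds at ≤ 1% of total volume
  for a low threshold. Touching features merge — by design; watershed
  splitting is out of scope.
* **Half-depth reference.** The per-region maximum is taken after 3×3
  median smoothing: a raw maximum is biased upward by noise, which would
  bias half-depth areas downward. On sharp cones the smoothing slightly
  *lowers* the reference and admits a thin extra annulus (a few percent);
  the bias is deterministic and identical across wells of one shape, so
  it cancels in population comparisons.
* **Averaging and registration.** Repeat flatbed scans are assumed
  pixel-aligned (`align = "none"`); an integer-shift registration by
  maximum FFT cross-correlation is available for safety. Sub-pixel
  registration is deliberately not offered: interpolation would correlate
  neighbouring pixels and break the $1/\sqrt{N}$ accounting.
* **k-means typing.** Features (volume, half-depth area) are z-scored —
  they differ by orders of magnitude, and unstandardized Lloyd iterations
  would cluster on area alone. Initialization is k-means++, best of 10
  restarts by within-cluster sum of squares, deterministic under a seed.
  Cluster-to-type mapping uses the permutation of the confusion matrix
  minimizing disagreement (exhaustive, $k \le 8$), which is well defined
  for equal label-set cardinalities and invariant to relabeling.
* **Coordinates.** 0-based physical convention: x right, y down, origin
  at the image's top-left corner, coordinates at pixel centres
  ($x = (j - \tfrac12)p$). Cross-sections sample depth by bilinear
  interpolation at one-pitch spacing.

## Reporting conventions

Population summaries report the sample mean, the sample standard
deviation ($n-1$), and the coefficient of variation
$\mathrm{CoV} = 100\,\sigma/\mu$ rounded to two significant figures for
tables. Well-array uniformity tables in this field sometimes label the
σ row "variance" while printing values in nL whose ratio to the mean
equals the printed CoV — i.e. a standard deviation; `summarizeWells()`
computes and labels it as a standard deviation. The Gaussian fit of a
volume distribution is moment-based with a Freedman–Diaconis histogram
and a Shapiro–Wilk diagnostic that is reported, never enforced.

## What the synthetic tests do and do not show

The simulator reproduces the geometry, the optics, the quantization and
an idealized noise process. Tests built on it therefore validate the
*inverse machinery*: calibration recovery to four significant figures,
per-pixel round trips to 0.5%, closed-form volume agreement to 1–2%,
$1/\sqrt{N}$ averaging within ±20% at $N = 4, 9$, and misclassification
counting against brute-force assignment. They do **not** validate optical
effects absent from the forward model: blur at steep sidewalls,
refraction in deep high-index structures, illumination non-uniformity
beyond what a paired blank cancels, or mechanical drift between repeat
scans. Results on real scans depend on those effects; the integer-shift
registration and the intercept diagnostic are the first things to check
when a real dataset misbehaves.

Problem sizes in the test suite are chosen to keep the full run in the
low minutes on one core while leaving discretization comfortably inside
the asserted tolerances: rasters up to ~750×750 px, arrays of 100 wells
for segmentation properties, and the statistical surrogate
(`sampleWellVolumes()`) for the 10,000-well typing study, whose group
means (0.065/0.080/0.095 nL), counts (1000/8000/1000) and spread
(0.0013 nL) are the designed study conditions. At that spread the groups sit
~11σ apart, so k-means typing is expected to misclassify essentially no
wells, comfortably within the ≤ 22/10,000 acceptance bound.

## Known limitations

* Depth range is bracketed by the linear regime ($A < 0.6$) above and
  the quantization floor below; structures spanning both extremes need
  two dye concentrations and two scans.
* Merged (touching) wells segment as one region; no watershed splitting.
* Volumes for doubly-deformed chambers are exact, surface shapes are not.
* The exhaustive cluster-type assignment stops at $k = 8$; beyond that a
  Hungarian-algorithm implementation would be needed.
* TIFF float persistence stores an affine-mapped `[0,1]` raster with the
  scale and offset in a JSON sidecar (portable across TIFF readers that
  clamp floats); the sidecar is required to reload a map.
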