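---
title: "Quantifying the retinal capillary network from OCT angiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the retinal capillary network from OCT angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(octaquant)
```

## Background

Optical coherence tomography angiography (OCT-A) maps retinal blood flow by
comparing repeated B-scans at each cross-section: moving erythrocytes
decorrelate the signal, so perfused vessels appear bright in the en-face
projection while static tissue stays dark. In diabetes, capillary
non-perfusion and foveal avascular zone (FAZ) remodelling are early,
quantifiable signs of microvascular damage. octaquant implements an
automated measurement chain for en-face angiograms of the superficial
capillary plexus and produces six headline metrics per scan:

* **FAZ area** (mm^2) — pixel count of the segmented avascular region
  times the physical pixel area;
* **FAZ circularity** — the isoperimetric quotient `4 * pi * A / P^2`,
  1.0 for a circle, decreasing toward 0 as the terminal capillary ring is
  disrupted;
* **total and parafoveal vessel density** (VD, %) — the percentage of an
  ETDRS zone not covered by qualifying non-perfused areas;
* **fractal dimension** (FD) — the box-counting slope of the vessel
  skeleton, a scale-free measure of branching complexity;
* **vessel diameter index** (VDI, mm) — vessel mask area divided by
  skeleton length, an average calibre.

It also implements the agreement statistics used to validate such
pipelines (ICC, coefficient of repeatability, Bland-Altman limits of
agreement, and ICC precision planning) and a synthetic angiogram
generator with analytic ground truth, so that every stage is testable
without patient data.

## The measurement chain

The stages run in a fixed order; `compute_all()` wires them together.

**Geometry.** A `scan_geometry` ties the pixel grid to physical units.
The standard acquisition covers 3 mm x 3 mm with 320 x 320 A-scans, so
one pixel is 9.375 um and 0.02 mm^2 corresponds to 227.6 pixels. All
areas are pixel counts times the exact pixel area; nothing is interpolated.

**Quality gate.** Scans carry an optional device quality score (0-100);
scores below 40 flag the record as failing QC. The gate is metadata-only —
an absent score never blocks processing.

**Denoising.** A non-local means (NLM) filter replaces each pixel by a
weight-normalised average of the pixels in its search window, weighted by
the similarity of the surrounding intensity patches
(`w = exp(-d2 / h^2)`, `d2` the mean squared patch difference). Because
weights are positive and sum to one, the output never leaves the convex
hull of the input intensities, and flat regions are exact fixed points.
Defaults: 5x5 patches, 15x15 search window, `h = 0.08` of the dynamic
range — strong enough to suppress decorrelation speckle without erasing
single-capillary strokes at 320 x 320 resolution.

**Binarization.** Phansalkar adaptive local thresholding classifies a
pixel as vessel iff its intensity strictly exceeds
`t = m (1 + p e^{-q m} + k (s / r - 1))`, with `m`, `s` the local window
mean and standard deviation. The exponential term raises the threshold
where the neighbourhood is dark, which is what makes the method usable on
OCT-A: a global threshold either drowns the low-SNR parafoveal capillaries
or floods the FAZ with speckle. Constants default to the original
formulation (`k = 0.25`, `r = 0.5` on the [0,1] scale, `p = 2`, `q = 10`)
with a 15 px window radius (~0.28 mm), wide enough that every window mixes
vessel and background. Both NLM and the thresholder use mirror-reflection
padding at the borders; zero padding would bias border thresholds dark.

**FAZ segmentation.** Region growing from a seed at the scan centre
(scans are fovea-centred; an explicit seed is accepted) collects the
4-connected component of background pixels. 4-connectivity prevents the
region escaping diagonally through single-pixel junctions in the
capillary ring; if the ring is genuinely breached the leak is reported,
not silently repaired. A seed landing on a vessel is moved to the nearest
background pixel with a warning.

**Perimeter and circularity.** The region boundary is traced as a closed
8-connected chain (Moore neighbour tracing) and the perimeter is the sum
of step lengths — one pixel pitch for axial steps, the pixel diagonal for
diagonal steps. Local chain length systematically overestimates smooth
curves: a digital step at an intermediate orientation is up to 8% longer
than the curve beneath it, about +5% averaged over orientations, which
would depress the circularity of a perfect circle to ~0.90. The default
estimator therefore applies the classical isotropic correction factor
0.948 to the chain length, after which digitized circles measure to
within ~1%; the uncorrected chain is available as `method = "chain"`.
The equivalent circle of the circularity index is evaluated in closed
form (`P^2 / 4 pi`) rather than re-rasterized — the closed form is the
limit of the rasterization procedure and removes grid-orientation
artifacts. Rasterization can still push the quotient of a near-perfect
disk a few percent above 1; values above 1 are clipped to 1.0 (the raw
value is kept as an attribute) and only overshoots beyond 1.05 warn.

**Vessel density.** Masks for the ETDRS central circle (1 mm), the
parafoveal annulus (1-3 mm) and the total 3 mm disk are built around the
FAZ centroid (the fovea proxy; falls back to the image centre if the
3 mm circle does not fit). A pixel belongs to a zone iff its centre lies
inside the defining circles. Non-perfused regions are 8-connected
components of background strictly larger than 0.02 mm^2, clipped to the
zone before the area test; sub-threshold dark areas (normal
intercapillary spacing) count as perfused. VD is the percentage of zone
area not covered by qualifying components. The strict inequality makes
the rule discontinuous at exactly 227 vs 228 pixels at the standard
geometry — tested at that boundary.

**Skeleton metrics.** The mask is thinned to one-pixel-wide centrelines
with the Guo-Hall two-subiteration algorithm (topology-preserving; the
skeleton is a subset of the mask). Skeleton length counts each undirected
8-neighbour link once. FD is the least-squares slope of `log N(s)` vs
`log(1/s)` over box sizes `s = 2, 4, 8, ...` up to a quarter of the
smaller image dimension, grid anchored at the origin without offset
averaging (at least 3 scales are required; a line calibrates to 1.00 and
a filled plane to 2.00 within 0.05). FD is computed on the skeleton by
default; `fd_source = "binary"` preserves the alternative reading on the
mask itself. VDI is mask area over skeleton length.

## Reliability statistics

`icc_two_way()` computes the single-measurement intraclass correlation
from the two-way ANOVA mean squares. The default is ICC(A,1) — absolute
agreement, the right choice for test-retest of a single device, since a
systematic shift between sessions should count against reliability:

    ICC(A,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))

with confidence bounds from the McGraw-Wong F construction. ICC(C,1)
(consistency) is available behind `type = "consistency"`.

`coefficient_of_repeatability()` returns `1.96 * SD` of the paired
session differences — the value below which 95% of repeat differences
are expected to fall — with chi-square confidence bounds on the
difference SD; the `2.77 s_w` within-subject convention is available as
`method = "within_sd"`. `bland_altman()` gives the bias and the 95%
limits of agreement `mean(d) +/- 1.96 SD(d)`.

For study planning, `icc_ci_width(n, k, icc)` evaluates the Bonett
(2002) large-sample approximation

    Var(ICC) ~ 2 (1 - rho)^2 (1 + (k-1) rho)^2 / (k (k-1) (n - 1))

and `icc_for_width(n, k, width)` inverts it: at `n = 30`, `k = 2` and a
target 95% CI width of 0.2 the detectable ICC evaluates to 0.852 (for
`k > 2` the width is not monotone in rho and the inversion returns the
upper root). The 2.77/`s_w` and ICC(C,1) alternatives, like every other
convention switch in the package, change the estimator, not the data.

## The synthetic generator

`generate_scene()` builds an en-face angiogram with known truth:

* **FAZ**: the boundary is `r(theta) = R (1 + sum_{m=2..6} a_m cos(m theta + phi_m))`
  with total relative amplitude `faz_irregularity` (0 = perfect circle).
  Truth area, perimeter and circularity are computed from this continuous
  curve by quadrature at 4096 angles — independent of any pixel
  processing, which is what makes them legitimate oracles for the
  pipeline.
* **Vessels**: a terminal capillary ring follows the boundary (inner edge
  at the boundary, so the rasterized FAZ matches the continuous one), and
  branching trees root on the rim and grow outward as biased random
  walks. At a branch, calibre divides between trunk (x0.9) and branch
  (x0.7), which keeps total tree size bounded at any branch probability.
  Short capillaries are then seeded into residual gaps outside the FAZ
  (`capillary_infill`), emulating the near-uniform macular capillary
  mesh; without this the tree trunks alone would leave dark areas far
  larger than any real angiogram shows.
* **Rendering**: strokes are drawn as capsules with a crisp half-pixel
  edge ramp centred on the geometric boundary (flow decorrelation
  saturates, so real vessel edges are sharp); the truth vessel mask is
  coverage > 0.5, i.e. exactly the geometric stroke outline.
* **Intensity**: background 0.08, vessels 0.85, multiplicative speckle
  (`speckle_strength`, default 0.15) plus additive Gaussian noise
  (`noise_sigma`, default 0.05), clipped to [0, 1].
* **Determinism**: one integer seed drives the scene; the global RNG
  state is saved and restored. A separate `noise_seed` reproduces the
  same anatomy under independent noise — the test-retest situation —
  and `generate_repeatability_set()` builds whole cohorts with
  subject-level anatomical variation on top.

Defaults (3 mm / 320 px, FAZ radius 0.35 mm giving ~0.38 mm^2, calibre
3 px = 28 um, branch probability 0.12) emulate a healthy-to-mild
diabetic superficial-plexus scan.

What the generator does *not* emulate: physical speckle statistics and
decorrelation noise, projection artifacts from overlying vasculature,
motion artifacts, media opacity blur, or cystoid spaces (which a real
angiogram cannot distinguish from non-perfusion — a known limitation of
the dark-area VD definition). Passing recovery tests on synthetic scenes
therefore demonstrates the measurement chain's correctness on images of
this class, not clinical performance on device output.

## Numerical choices and known behaviour

* Intensities are normalized by declared bit depth, never per-image
  min/max, so thresholds are comparable across scans.
* Vessel classification uses strict `>`; the non-perfusion rule uses
  strict `> 0.02 mm^2`; tests pin both boundaries.
* All window operators mirror-reflect at borders.
* The local standard deviation in the thresholder is the population SD.
* An all-background mask grows to the whole image ("FAZ unbounded",
  warned); an all-vessel neighbourhood around the seed is an error.
* Regions touching the image border are measured along the clipped
  contour, with a warning.
* Adaptive thresholding is deliberately generous in dark windows (that is
  why the method sees low-SNR capillaries), so on synthetic scenes the
  pipeline over-reads VD by roughly +3 to +5 percentage points relative
  to geometric truth in sparse networks, and recovers it to well under a
  point at realistic densities. The recovery tests assert the
  per-condition mean over seeds for this reason.
* At coarse resolutions (e.g. 160 px test geometry) the corrected
  perimeter of a small digital circle can undershoot enough to push raw
  circularity a few percent above 1; the clip to 1.0 is the documented
  range of the index.

## Problem sizes in the test suite

Oracle-equivalence tests (NLM, Phansalkar, box counting, region growing
vs brute-force loops) run on 16-32 px instances; calibration tests on
256-320 px images; truth-recovery runs the full pipeline on 320 px
scenes over a 3 x 3 grid of branch density x dropout with 5 seeds per
condition; end-to-end repeatability harnesses use 160 px geometry to
keep runtimes in seconds. The acceptance script recomputes the two
headline calibration numbers (circular-FAZ circularity; detectable ICC
at n = 30, k = 2, width 0.2) from scratch at the standard 320 px
geometry.

## Limitations

Only the superficial capillary plexus image class is modelled; deep
plexus slabs need projection-artifact removal first. The package reads
plain PNG/TIFF exports, not vendor formats or DICOM. FAZ area is not
corrected for axial-length magnification. The dark-area VD definition
cannot separate non-perfusion from cystoid spaces. Clinical association
analyses (regression against retinopathy severity and systemic factors)
are outside the package's scope: they need a cohort, not an algorithm.
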