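---
title: "Quantifying titanium micro-particles in micro-PIXE maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying titanium micro-particles in micro-PIXE maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Dental implants shed titanium micro-particles into the surrounding soft
tissue. Micro proton-induced X-ray emission (micro-PIXE) maps a sectioned
biopsy with a focused MeV proton beam and records element-characteristic
X-rays, yielding one count raster per element at micrometre resolution.
Sulfur is present throughout soft tissue and outlines the specimen; titanium
counts are essentially background-free where no metal is present, so bright
Ti blobs are candidate micro-particles.

`tipix` implements the quantification chain for such maps: locate candidate
particles on a fast survey scan, confirm them with high-statistics
re-measurements, calibrate a lower count threshold from the false detections,
segment the survey map into background-free labelled particles, measure each
particle's morphometry and its position relative to two anatomical reference
lines (the implant/tissue interface and the mucosal margin), aggregate
per-region-of-interest densities, and compare paired specimens
(peri-implantitis vs clinically healthy reference implant sites)
nonparametrically.

Because raw clinical maps are not distributable, the package is organised
around a synthetic phantom generator that reproduces the statistical
structure the analysis relies on. Every downstream stage is exercised and
validated against phantom ground truth.

## The phantom model

`phantom_spec()` describes a specimen and an acquisition:

* **Geometry.** A rectangular specimen of configurable width (away from the
  implant/tissue interface, the x axis) and depth (apical from the mucosal
  margin, the y axis), sectioned at a configurable thickness (default 25 um;
  clinical sections are typically 20-50 um). The interface is the left
  outline edge, the margin the top edge, and the scan raster extends a
  100 um frame margin beyond the specimen on every side, as a real mosaic
  scan does — without it, beam blur running off the frame would erode the
  sulfur signal exactly at the specimen boundary and bias the traced
  outline inward. Real biopsies are irregular; the rectangle is an
  idealisation that keeps zone areas analytic, and the outline is
  nevertheless re-estimated from the sulfur map downstream, so the pipeline
  never "knows" the true shape.
* **Particle field.** Particle counts in each distance band from the
  interface ([0,1), [1,2), [2,Inf) mm) are Poisson with mean
  `density x band area x thickness`; centres are uniform in the band. The
  default densities (260/159/152 per mm^3) mirror reported peri-implantitis
  zone means, i.e. most particles lie within 2 mm of the interface.
* **Size.** True equivalent diameters are log-normal with meanlog 2.563 and
  sdlog 0.664, obtained by moment-matching a reported mean of 16.17 um and
  sd of 12.03 um. Under this model the analytic fraction of particles at or
  below 15 um is 58.7%, consistent with roughly 60% of particles being
  small.
* **Shape.** Footprints are rough ellipses: an ellipse with axis ratio
  uniform on [0.25, 1], modulated radially by cosine harmonics 2-8 with
  amplitudes `amp * u / sqrt(h)` (u uniform, amp uniform on
  [0, 0.45]), rescaled to the sampled area. These two ranges were calibrated
  once, by simulation on true polygons, to give mean footprint circularity
  0.72 and sd 0.16.
* **Signal.** Expected Ti counts per pixel are
  `(footprint coverage x particle_intensity + background_rate) x
  (fluence / 200 nC/mm^2)`, convolved with a Gaussian beam of 4.5 um FWHM
  (typical microprobe beams are 4-5 um across; a Gaussian is the standard
  approximation), then Poisson-sampled. Coverage is computed by 6x6
  sub-pixel sampling of the true polygon (integrated-signal error below
  0.3%). The blur uses zero padding: signal scanned past the frame edge is
  lost, never wrapped. The default intensity scale (50 counts/um^2 at the
  survey fluence) and background (0.05 counts/pixel) are free parameters of
  the generator — no publication states its survey count scale — chosen so
  that a particle at the 1.5 um detectability floor still integrates ~90
  survey counts while stray background pixels rarely exceed 1-2 counts.
* **Confusers.** Non-Ti false sources are modelled as Gaussian blobs whose
  expected amplitude (2-4 counts at the peak) does *not* scale with fluence.
  This is the operational property that makes false detections identifiable:
  on a 100x higher-dose confirmation scan a genuine particle's counts grow
  100-fold while a confuser stays at survey brightness and disappears into
  the (now much larger) background fluctuation.
* **Sulfur.** A uniform tissue rate (3 counts/pixel at survey fluence)
  inside the outline and near-zero outside, same blur and noise model.

Identical spec + seed gives bit-identical truth and maps. The mosaic
renderer tiles the frame (default 1 mm tiles, matching the calibration
reference of one tile edge = 1 mm) by cropping the full-frame render, so
stitching is exactly the identity regardless of tiling.

What the phantom does **not** model: PIXE physics (cross-sections, matrix
absorption, detector response), spectrum fitting, non-rectangular specimen
shapes, spatially varying tissue composition, or particle agglomeration.
Passing recovery tests on phantoms therefore demonstrates the correctness of
the image-analysis chain under the stated statistical assumptions, not the
fidelity of any spectral pre-processing.

## Detection

`detect_candidates()` is a circular matched-filter ("blob of revolution")
voter: the survey map is smoothed at the beam scale, convolved with
normalised disk kernels across the radius range (default 0.75-20 um, the
lower bound being half the 1.5 um detectability floor reported for metal
particles in organic matrices), and the vote at each pixel is the best
response over radii. Candidates are local vote maxima above a floor, with
non-maximum suppression at the candidate scale. The floor is the
`sensitivity` quantile (default 0.995) of the *noise-dominated* vote
population — positive votes below a robust ceiling (median + 8 MAD) — so a
few very bright particles cannot drag the floor above the noise tail; a
relative epsilon (1e-6 of the top vote) additionally discards FFT residue
on noise-free maps. The stage is deliberately tuned for recall: false
positives are expected and useful, because they are what calibrates the
threshold.

`confirm_candidates()` integrates high-statistics counts over each
candidate's support and confirms when the excess over the expected
background exceeds `min_snr` (default 5) background standard deviations
(Poisson). `calibrate_threshold()` then sets the lower concentration
threshold to the largest survey peak among rejected candidates plus one
count: every false detection is removed by construction. If a confirmed
particle nevertheless falls at or below the threshold, the "keep all
particles" guarantee is unattainable on that map and the function warns
rather than silently dropping the conflict. `segment_particles()` applies
the threshold strictly (ties are background), labels 8-connected
components, and discards components below a 1.5 um equivalent diameter.

## Morphometry

Area is pixel count times pixel area; "diameter" is the equivalent-circle
diameter `2 sqrt(A/pi)` — deliberately distinct from the Feret caliper set,
since reported mean diameter (16.2 um) is below the reported mean caliper
(18.2 um), which identifies the convention. The perimeter comes from the
traced pixel-edge ("crack") boundary simplified by Douglas-Peucker at 1 px
tolerance before measuring length: the staircase of a smooth boundary
deviates from the ideal contour by up to about one pixel, so this tolerance
removes discretisation steps while preserving true corners; it is exact for
axis-aligned rectangles and within ~1% for rasterised disks. Circularity is
the isoperimetric factor `4 pi A / P^2` clamped to [0, 1] (the clamp is
flagged per particle and can only trigger within discretisation error).
Feret calipers are min/mean/max extents of the convex hull of the boundary
corner points over 180 directions (1 degree steps); under this corner
convention a single pixel measures `pixel_size` by `sqrt(2) pixel_size`.
Particles are classified small when the equivalent diameter is at or below
15 um (boundary inclusive on small).

## Zones, positions, densities

The specimen outline is re-extracted from the sulfur map (smoothing, Otsu
threshold, largest 8-connected component, morphological closing, boundary
trace). Each in-outline pixel and each particle centroid is assigned a zone
by its minimum Euclidean distance to the interface polyline, with half-open
bands [0,1), [1,2), [2,Inf) mm — the band edges are nowhere defined to a
boundary convention in the source material, so the half-open choice is
fixed here to make every assignment deterministic (a centroid at exactly
1.000 mm is zone 2). Membership of straddling particles is decided by the
centroid, and both horizontal and vertical distances are measured from the
centroid; the alternative (nearest-edge) reading is not used. ROI volume is
area times section thickness; volumetric density is count over volume.
Densities are computed per sample and then averaged across samples for
tables, so a tabulated mean density is generally not mean count divided by
mean volume.

## Statistics

The paired comparison is the Wilcoxon signed-rank test implemented with the
conventions spelled out here: zero differences dropped, mid-ranks on ties,
W = sum of positive ranks, exact two-sided p by enumeration of all 2^m sign
patterns for m <= 12 non-zero pairs, tie-corrected normal approximation
without continuity correction otherwise. Mann-Whitney U follows the same
pattern (exact by labeling enumeration when the pooled n <= 12 and tie-free).
Group regression is ordinary least squares with treatment coding
(`stats::lm`), with a helper that groups implant systems into
Astra Osseospeed / Nobel TiUnite / Others. The Ti-high/Ti-low split labels a
sample high when its density strictly exceeds the mean (equality is low);
the threshold is a parameter because the source material reports a grouping
threshold (190/mm^3) that matches the entire-specimen mean rather than the
inflamed-zone mean (222/mm^3) it nominally derives from — an inconsistency
the package does not try to resolve by hard-coding either number.

## Validation campaigns and problem sizes

The test-suite and acceptance campaigns use deliberately scaled phantoms:

* *Count exactness*: 30 phantoms of 2.4 x 2 mm at 2 um/px with zone
  densities (70, 30, 10)/mm^3 and 2 confusers/mm^2. At these densities
  particle footprints essentially never merge under the 4.5 um blur, so
  "detected count equals true count" is a meaningful per-seed check of the
  detector rather than of overlap physics. Merging of nearly touching
  particles is a real and accepted limitation at high densities.
* *Recovery and gradient*: 30 phantoms of 3 x 2 mm at 2.5 um/px with
  configured densities (500, 200, 50)/mm^3, chosen to give roughly 30/12/3
  expected particles per zone so each replicate supports a per-zone density
  estimate. Pooled recovered densities are required to sit within 3 Poisson
  standard errors of the configured values, and the configured decreasing
  gradient must re-emerge as strictly decreasing zone estimates in at least
  90% of replicates.
* *Cohort*: six simulated patients with paired peri-implantitis
  (3.6-4.6 x 2.6-3.4 mm) and reference (2.4-3.2 x 1.9-2.5 mm) specimens at
  2.5 um/px — about two-thirds the linear scale of typical clinical
  specimens, preserving the area asymmetry between conditions.

## Numerical choices and degenerate inputs

* Threshold granularity is one count and thresholding is strict, so
  segmentation is reproducible to the bit.
* The exact signed-rank enumeration is limited to m <= 12 (4096 patterns);
  beyond that the normal approximation is within 0.02 of exact on tie-free
  data (verified in the suite for m = 10-12).
* An all-zero difference vector makes the paired test undefined and is an
  error, not a p-value.
* A distance band with zero area but positive configured density generates
  zero particles with a warning.
* Maps whose counts exceed 65535 fall back to exact 32-bit float TIFF
  storage; counts at or beyond 2^24 are refused rather than silently
  rounded.
* An empty candidate set gives an empty confirmation result; threshold
  calibration without candidates is an error.

## Known limitations

* No spectral physics: inputs are count rasters, not fitted concentration
  maps; absolute ppm quantification is out of scope.
* Beam blur merges particles closer than roughly one beam FWHM plus their
  radii; at clinical densities this is rare but it biases counts low and
  sizes high at extreme densities.
* Measured sizes are optically broadened: a 1.5 um particle reconstructs
  with an apparent diameter of several um at survey blur and pixel pitch.
  Size statistics of detected particles are therefore not deconvolved
  estimates of true size statistics.
* The inflammation masks are inputs (in practice traced from stained serial
  sections); the package does not segment inflammation from images.
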