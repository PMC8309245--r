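---
title: "Methods: SEM surface morphometry of plastic debris"
author: "plastimorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SEM surface morphometry of plastic debris}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastimorph)
```

# Scope and model

`plastimorph` quantifies the surface geometry of weathered micro- and
nanoplastic debris from 2D SEM micrographs. The underlying measurement
model is deliberately simple and fully stated:

* a micrograph is a grid of luminance integers in [0, 255] with one
  explicit physical calibration, the pixel edge length in nanometres —
  every length is a pixel count times that calibration, every area a pixel
  count times its square;
* surface *complexity* is measured through detected edges (length per area,
  length per region perimeter);
* surface *texture* and *ageing* are measured through luminance statistics
  (histogram spread) and periodicity (autocorrelation), never through any
  claim about absolute height — SEM luminance has no z calibration, so the
  3D reconstruction is explicitly a normalized, unitless proxy.

The package assumes micrographs that are already flat-field and
single-channel (RGB inputs are collapsed with the classic 0.299/0.587/0.114
luminance weights; 16-bit inputs are linearly rescaled over the full
container range so histogram semantics on the 0–255 axis are preserved, no
percentile stretching). Scale bars burned into vendor images are never
parsed: calibration is an explicit input because bar parsing is
vendor-specific and silently error-prone.

# Edge metrics

Edges are detected with a Canny pipeline: Gaussian smoothing (σ, default
2 px), Sobel-style gradients, non-maximum suppression, and double-threshold
hysteresis in which pixels between the thresholds survive only if
8-connected to a pixel above the high threshold.

Numerical choices that matter:

* **Hysteresis thresholds are fractions of the per-image maximum gradient**
  (defaults 0.1 and 0.2). Absolute gradient values depend on detector
  settings; fractions transfer across images. Whatever set is chosen must
  be held fixed across a comparison series — `characterizeNiches()`
  enforces this by accepting exactly one parameter set for all regions.
* **Non-maximum suppression samples the gradient magnitude by bilinear
  interpolation one pixel forward and backward along the true gradient
  direction.** Quantizing the direction to 8 neighbours leaves 2-px-thick
  bands on 45° boundaries, which inflate length metrics. Ties are broken
  deterministically (≥ forward, > backward), so a flat two-pixel maximum
  keeps exactly one pixel and the detector is bit-reproducible.
* **Thinning** combines parallel Zhang–Suen passes with a final sequential
  simple-point pass (deleting pixels with Yokoi 8-connectivity number 1 and
  degree ≥ 2). Zhang–Suen alone cannot reduce 2-px diagonal staircase
  bands — both pixels have crossing number 2 — while sequential
  simple-point removal reduces them to single diagonal chains without
  breaking connectivity, endpoints, junctions or loops.
* **Length is chain-code stepping** on the thinned map: orthogonal
  adjacencies count one pixel size, diagonal adjacencies √2. A raw pixel
  count would overestimate diagonal chains by up to √2.
* A constant image yields an empty edge map (a result, not an error); a
  guard treats gradient magnitudes below 10⁻³ luminance levels/px as flat,
  since FFT-based filtering leaves rounding dust on constant inputs.

Two conventions are worth stating. "Percent edges" is the edge-pixel
fraction of region pixels on the *thinned* map — the only definition
consistent with the paired length-per-area column under a single pixel
size; the two columns reconcile through a factor between 1 and √2 (the
diagonal correction), which the test suite asserts on seeded fixtures.
Second, a physical ridge or crack excites the detector on both of its
sides, so the metrics report raw detected length by default ("edges" as
seen), and `halved = TRUE` gives the per-ridge centreline convention used
for ground-truth comparison.

The validation suite measures the accuracy of the halved convention on
synthetic crack fields of known centreline length: the median relative
error is around +5%, composed of chain-code digitization bias (up to +8.3%
for a straight line at 22.5°, ~+4% averaged over angles), crack end caps
(~+0.5 µm per segment), and a small negative contribution where cracks
cross. This bias is intrinsic to the stated length definition and sits well
inside the 10% band the recovery tests use.

# Particles, fibres, pores

Particle detection is the three-step protocol: greyscale (guaranteed by
ingestion), global threshold (Otsu on the region histogram by default, or a
fixed level), connected-component labelling. Labelling is 8-connected;
since the EBImage labeller is 4-connected, components touching only
diagonally are merged by union-find afterwards. Touching objects are
reported as one — no watershed splitting, a documented limitation of the
simple protocol. Components under `minAreaPx` (default 10) are noise
specks and dropped. Sphere volumes use the equivalent-area radius of the
2D projection, so the closed form (4/3)πr³ holds exactly by construction.
Border-touching particles are flagged, excluded from the grain-size
distribution by default (their diameters are censored by the field of
view), but kept in total detected area.

Fibre diameters are 2d−1 pixels at medial-axis skeleton pixels, where d is
the Euclidean distance-transform value; the −1 accounts for the centre
pixel itself and makes a w-pixel stripe read w exactly for odd w (±1 px for
even w). Modal diameters are local maxima of the 1-px-binned histogram
ordered by prominence with a minimum peak separation of 3 px. Inter-fibre
spacing is twice the local maxima of the background distance transform —
the largest inscribed gaps; maxima closer to the image border than their
own distance value are flagged `boundary_dominated` (a single fibre in an
empty field yields only such samples).

Pores are dark connected components within a size window (default
[10 px, 10% of the region]); pores crossing the region boundary count
toward count and area. The identity density × mean area = fraction/100 is
enforced by construction rather than estimated twice. The module computes
each pore statistic independently and makes no attempt to reconcile
published hole-density and coverage figures that are mutually inconsistent.

# Histogram roughness

Spread statistics — population standard deviation (the headline ordering
key), inter-quartile range (tie-break), Shannon entropy — are the numerical
surrogates for visual histogram "broadening". Comparison is only meaningful
under identical acquisition parameters; that fact is not recoverable from
the images, so `compareRoughness()` requires the caller to assert it
explicitly and refuses otherwise. The indistinguishability tolerance
(default 10⁻⁶ luminance levels) is a module decision; no published
threshold for "broader" exists.

# Texture periodicity

Periods come from the normalized circular 2D autocorrelation of the
mean-subtracted image, searched independently along rows and columns for
the smallest off-origin local maximum with correlation ≥ 0.5 of the
zero-lag value (ties toward the smaller lag). Autocorrelation was chosen
over spectral peak-picking for its direct pixel-unit interpretation.
Axis-aligned periodicity only: oblique lattices appear through their axis
projections. An image qualifies as periodic only if **both** axes have a
qualifying peak; a constant or genuinely aperiodic surface returns an
"aperiodic" result distinguished from an error. The unit template is the
per-cell **median** across all full tiles (robust to adsorbed-particle
outliers on individual cells); element dimensions are the in-plane
bounding box of the mid-range-thresholded template, measured under the
circular roll that wraps the longest background run across the tile
boundary so elements straddling the boundary are boxed tightly. Reported
"height"/"width" are in-plane extents, not out-of-plane profile heights.

# Height maps

`heightMap()` applies optional Gaussian smoothing (default σ 1 px, to keep
shot noise out of the normalization extremes) and min–max normalizes to
[0, 1]. A constant image maps to all zeros — the convention that keeps the
"max = 1 unless constant" invariant testable. The map is monotone (brighter
never lower) and exactly invariant to positive affine luminance changes.
No operation integrates surface area over z: without z calibration such a
number would be meaningless. OBJ was chosen as the mesh dialect for
universal viewer support; x/y are emitted in micrometres.

# The synthetic generator

The generator emulates the image *classes* the metrics target: crack
networks of exact analytic centreline length, disjoint dark pores of exact
count and area, bright fibre meshes of known widths and gaps, bump
lattices of known periods, and disjoint spherical particles of known radii
— all rasterized hard (pixel centre in shape, no anti-aliasing) so
pixel-count oracles stay exact, then degraded with additive Gaussian noise
(default σ 8 luminance levels against 120-level contrasts, SNR 15) and
optional signal-dependent shot noise. Every generator takes an explicit
integer seed, runs in a private RNG stream (the caller's `.Random.seed` is
untouched), and is bit-reproducible.

Fixture scales were chosen once: crack fields 512 px at 100 nm/px (a
51.2 µm field; segments sized ~20 µm so end-cap overhead stays small
relative to length, crack width 3 px), fibre fields 768 px at 100 nm/px
(9.5/5 µm fractions are 95/50 px), texture fields 200–260 px, particle
fields 1536 px so fifty 2–10 µm-radius disks pack at ~27% density without
overlap. These sizes keep the full validation suite within a couple of
minutes on one CPU while leaving every feature ≥ 10 px, the scale at which
analytic and rasterized geometry agree within 2%.

What the generator does **not** emulate — and hence what passing tests do
not show about real micrographs: beam–specimen interaction, charging
artefacts and detector-specific response; focus gradients and
astigmatism; overlapping translucent structures; organic overburden and
biofilm; and real weathering morphology, which is far less regular than
line segments and disks. Recovery results on fixtures bound algorithmic
error, not real-world measurement error.

# Configuration and provenance

Every CLI run resolves its configuration deterministically (flags over
config file over defaults, unknown keys rejected) and writes the resolved
set alongside its outputs, so any metric file can be regenerated from its
sidecar plus the input image. Calibration has no default on purpose;
physical metrics without it are refused with an actionable message.

# Known limitations

* Chain-code length carries the angle-dependent digitization bias discussed
  above; results should be compared under a fixed convention, not across
  conventions.
* No watershed splitting: touching particles and merged pores read as one
  object.
* Oblique texture lattices are reported through axis projections only.
* The histogram is an *indicator* of roughness under fixed acquisition,
  not a calibrated roughness (no Ra/Sq claims).
* Physical reproduction of published edge-density values from real
  micrographs requires their pixel sizes, which published figures often
  omit; the package therefore validates against synthetic ground truth.
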