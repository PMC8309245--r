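# plastimorph

Quantitative surface morphometry of micro- and nanoplastic debris from
scanning electron micrographs.

Environmental plastic debris weathers: UV, salt water and abrasion cover it
with cracks, perforations, adsorbed particles and delamination zones. That
roughened surface — the *Plastisphere* — is the substrate on which biofilms
settle and onto which pollutants adsorb, so its geometry is ecologically
meaningful. `plastimorph` turns calibrated SEM micrographs of such debris
into reproducible physical numbers, and ships a seeded synthetic micrograph
generator with analytic ground truth so every metric is validated end to end
without any external image data.

## Metrics

For an image with pixel size *p* (nm/px) and a region *R* of area *A* (µm²)
and perimeter *P* (µm):

* **Edge metrics** (Canny detector with fixed σ and hysteresis fractions of
  the maximum gradient; maps thinned to 1-px chains): total edge length
  *L* = (N<sub>orth</sub> + √2 N<sub>diag</sub>) · *p*, edge density
  *L*/*A* (µm per µm², the surface-complexity metric), percent edge pixels,
  and the fragmentation index *L*/*P* (heavily weathered fragments exceed
  5). A ridge is detected on both sides; `halved = TRUE` reports the
  per-ridge centreline convention.
* **Particle metrics** — threshold → 8-connected labelling → per-object
  area *a* = n<sub>px</sub>·*p*², equivalent diameter *d* = 2√(*a*/π),
  sphere volume (4/3)π(*d*/2)³ for nurdles/microspheres, and fixed-width
  grain-size distributions.
* **Fibre morphometry** — local diameter 2·DT−1 sampled on the medial-axis
  skeleton (DT = Euclidean distance transform), modal diameters per
  fraction, and inter-fibre spacing from the largest inscribed background
  gaps.
* **Pore metrics** — dark connected components in a size window: count,
  density (holes/µm²), covered-area percent, mean pore area
  (density × mean area ≡ fraction/100).
* **Histogram roughness** — 256-bin luminance histograms with std/IQR/
  entropy; under fixed acquisition parameters a broader histogram indicates
  a rougher, more aged surface.
* **Texture unit** — periods of a repeating surface element from the
  normalized 2D autocorrelation, per-cell median template ("the original
  puzzle"), and pattern reconstruction by tiling.
* **3D proxy** — min-max normalized luminance-as-height surface exported as
  an OBJ mesh; the z axis is explicitly unitless (SEM luminance carries no
  absolute height calibration).

All calibration is explicit: every physical metric requires nanometres per
pixel as input; scale bars are never parsed.

## Worked example

```r
library(plastimorph)

# a 51.2 x 51.2 um weathered surface with exactly 80 um of cracks
syn   <- genCrackField(totalLengthUm = 80, nSegments = 4, sizePx = 512,
                       pixelSizeNm = 100, seed = 42)
img   <- synthImage(syn)
edges <- detectEdges(img, cannyParams(sigma = 2, lowFrac = 0.1,
                                      highFrac = 0.2))
edgeMetricsForROI(edges, halved = TRUE)
#>  total_edge_length_um edge_density_um_per_um2 edge_pixel_percent
#>              87.18255               0.0332575          0.5889893
#>  edge_to_perimeter_ratio
#>                 0.425696
sum(groundTruth(syn)$length_um)
#> [1] 80
```

The detected centreline length (87.2 µm) recovers the analytic 80 µm within
9% — the residual is the known positive bias of chain-code digitization
plus crack end caps. Pore statistics work the same way:

```r
pores <- genPoreField(25, poreAreaUm2 = 0.05, fieldAreaUm2 = 6,
                      sizePx = 256, seed = 7)
poreMetrics(detectPores(synthImage(pores)))
#>  count density_per_um2 area_fraction_percent mean_pore_area_um2
#>     25        4.166667              20.80994         0.04994385
```

All 25 perforations on the 6 µm² field are found; the density (4.17
holes/µm²) and covered fraction follow directly.

A command-line interface over the same functions is installed at
`inst/cli/plastimorph` (subcommands `edges`, `niches`, `particles`,
`fibres`, `pores`, `histogram`, `texture`, `reconstruct3d`, `synth`); every
run writes its fully resolved configuration next to its outputs, and
identical input + configuration gives byte-identical metric files.

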