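Package: plastimorph
Title: Surface Morphometry of Micro- and Nanoplastic Debris from SEM Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative description of the surfaces of weathered micro- and
    nanoplastic debris ("the Plastisphere") from scanning electron micrographs.
    Provides physically calibrated Canny edge-length metrics (edge density,
    percent edge pixels, edge-to-perimeter ratio), three-step particle
    segmentation with grain-size distributions and sphere-volume estimates,
    fibre diameter and inter-fibre spacing morphometry for glass-fibre
    filters, surface-perforation (pore) statistics, luminance-histogram
    spread profiling as a first-pass ageing indicator, repeating texture-unit
    extraction by autocorrelation, and normalized luminance-as-height 3D
    surface export. Includes a seeded synthetic micrograph generator with
    analytic ground truth and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils-internal.R'
    'calibration.R'
    'canny.R'
    'synthetic.R'
    'surface.R'
    'texture.R'
    'histogram.R'
    'pores.R'
    'particles.R'
    'cli.R'
    'plastimorph-package.R'
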