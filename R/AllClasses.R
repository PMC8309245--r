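#' @import methods
NULL

#' Calibrated SEM micrograph
#'
#' A greyscale luminance grid together with its physical pixel size. This is
#' the substrate of every metric in the package: all reported lengths and
#' areas derive from pixel counts multiplied by \code{pixelSizeNm}.
#'
#' Luminance values are integers in \code{[0, 255]} regardless of the source
#' bit depth (16-bit inputs are linearly rescaled over the full container
#' range). The matrix is row-major in image terms: rows run down the image,
#' columns across, so \code{dim()} is \code{c(height_px, width_px)}.
#'
#' @slot pixels numeric matrix of integer luminance values in \code{[0, 255]}.
#' @slot pixelSizeNm positive scalar, physical edge length of one pixel in
#'   nanometres. The physical width of the image is
#'   \code{ncol(pixels) * pixelSizeNm}.
#'
#' @seealso [loadImage()], [calibratedImage()], [denoise()], [cropImage()]
#' @export
setClass("CalibratedImage",
  representation(pixels = "matrix", pixelSizeNm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@pixelSizeNm) != 1L || !is.finite(object@pixelSizeNm) ||
        object@pixelSizeNm <= 0)
      msg <- c(msg, "pixelSizeNm must be a single positive finite number")
    if (!is.numeric(object@pixels) || length(dim(object@pixels)) != 2L)
      msg <- c(msg, "pixels must be a 2D numeric matrix")
    else {
      if (any(!is.finite(object@pixels)))
        msg <- c(msg, "pixels must be finite")
      else if (min(object@pixels) < 0 || max(object@pixels) > 255)
        msg <- c(msg, "luminance values must lie in [0, 255]")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Rectangular region of interest
#'
#' A half-open rectangle in 0-based pixel coordinates: rows
#' \code{[row0, row0 + heightPx)}, columns \code{[col0, col0 + widthPx)}.
#' Validity against a particular image is checked at the point of use.
#'
#' @slot row0,col0 0-based top-left corner (non-negative integers).
#' @slot heightPx,widthPx positive integer extent.
#'
#' @seealso [roi()], [cropImage()], [edgeMetricsForROI()]
#' @export
setClass("ROI",
  representation(row0 = "integer", col0 = "integer",
                 heightPx = "integer", widthPx = "integer"),
  validity = function(object) {
    msg <- NULL
    for (s in c("row0", "col0", "heightPx", "widthPx"))
      if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
        msg <- c(msg, sprintf("%s must be a single integer", s))
    if (is.null(msg)) {
      if (object@row0 < 0L || object@col0 < 0L)
        msg <- c(msg, "row0 and col0 must be non-negative")
      if (object@heightPx < 1L || object@widthPx < 1L)
        msg <- c(msg, "heightPx and widthPx must be positive")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Canny detector parameters
#'
#' The three parameters of the Canny edge detector: the standard deviation of
#' its Gaussian smoothing stage and the two hysteresis thresholds, expressed
#' as fractions of the per-image maximum gradient magnitude so that one
#' parameter set transfers across a series of related micrographs. A set,
#' once chosen, should be held fixed across any series that is to be compared
#' quantitatively; [characterizeNiches()] enforces this by accepting a single
#' set for all regions.
#'
#' @slot sigma positive scalar, Gaussian blur standard deviation in pixels.
#' @slot lowFrac,highFrac hysteresis thresholds in \code{(0, 1)} with
#'   \code{lowFrac < highFrac}: gradient magnitudes below
#'   \code{lowFrac * max} are never edges, above \code{highFrac * max}
#'   always are, and pixels in between survive only if 8-connected to a
#'   strong edge.
#'
#' @seealso [cannyParams()], [detectEdges()]
#' @export
setClass("CannyParams",
  representation(sigma = "numeric", lowFrac = "numeric", highFrac = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
        object@sigma <= 0)
      msg <- c(msg, "sigma must be a single positive number")
    ok <- length(object@lowFrac) == 1L && length(object@highFrac) == 1L &&
      is.finite(object@lowFrac) && is.finite(object@highFrac)
    if (!ok)
      msg <- c(msg, "lowFrac and highFrac must be single finite numbers")
    else if (!(0 < object@lowFrac && object@lowFrac < object@highFrac &&
               object@highFrac < 1))
      msg <- c(msg, "need 0 < lowFrac < highFrac < 1")
    if (is.null(msg)) TRUE else msg
  })

#' Binary edge map
#'
#' The output of [detectEdges()]: a binary mask congruent with its source
#' image, carrying the source calibration. \code{skeletonized} records
#' whether the mask has been thinned to 1-pixel chains (required for the
#' chain-code length metric; [edgeLength()] thins on the fly when needed).
#'
#' @slot mask logical matrix, \code{TRUE} at edge pixels.
#' @slot pixelSizeNm positive scalar calibration inherited from the source.
#' @slot skeletonized logical flag.
#'
#' @seealso [detectEdges()], [edgeLength()], [thinEdges()]
#' @export
setClass("EdgeMap",
  representation(mask = "matrix", pixelSizeNm = "numeric",
                 skeletonized = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!is.logical(object@mask) || length(dim(object@mask)) != 2L)
      msg <- c(msg, "mask must be a logical matrix")
    if (length(object@pixelSizeNm) != 1L || !is.finite(object@pixelSizeNm) ||
        object@pixelSizeNm <= 0)
      msg <- c(msg, "pixelSizeNm must be a single positive number")
    if (length(object@skeletonized) != 1L || is.na(object@skeletonized))
      msg <- c(msg, "skeletonized must be TRUE or FALSE")
    if (is.null(msg)) TRUE else msg
  })

#' Labelled object mask
#'
#' Connected components (8-connectivity) of a thresholded image, with labels
#' as consecutive positive integers and background 0, plus the physical
#' calibration needed to turn pixel counts into areas.
#'
#' @slot labels integer matrix, 0 = background.
#' @slot pixelSizeNm positive scalar calibration.
#'
#' @seealso [segmentParticles()], [detectPores()], [particleStats()]
#' @export
setClass("LabelMask",
  representation(labels = "matrix", pixelSizeNm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.numeric(object@labels) || length(dim(object@labels)) != 2L)
      msg <- c(msg, "labels must be a 2D integer matrix")
    else if (any(object@labels < 0))
      msg <- c(msg, "labels must be non-negative")
    if (length(object@pixelSizeNm) != 1L || !is.finite(object@pixelSizeNm) ||
        object@pixelSizeNm <= 0)
      msg <- c(msg, "pixelSizeNm must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' Luminance histogram profile
#'
#' The 256-bin luminance histogram of an image or region together with its
#' spread statistics. Histogram broadening under fixed acquisition
#' parameters is the first-pass surface roughness / ageing indicator:
#' an ideally flat surface gives constant luminescence, hence a single
#' occupied bin and zero spread.
#'
#' Statistics are always computed from the raw counts; \code{normalized}
#' only affects display (densities summing to 1).
#'
#' @slot counts integer vector of length 256, counts for luminance 0..255.
#' @slot totalPixels positive integer, \code{sum(counts)}.
#' @slot mean,std,iqr spread statistics in luminance units (population
#'   standard deviation; quartiles by inverse-CDF on the discrete counts).
#' @slot entropyBits Shannon entropy of the luminance distribution, bits
#'   (at most 8).
#' @slot normalized logical display flag.
#'
#' @seealso [luminanceHistogram()], [compareRoughness()]
#' @export
setClass("HistogramProfile",
  representation(counts = "integer", totalPixels = "integer",
                 mean = "numeric", std = "numeric", iqr = "numeric",
                 entropyBits = "numeric", normalized = "logical"),
  validity = function(object) {
    msg <- NULL
    if (length(object@counts) != 256L || any(object@counts < 0L))
      msg <- c(msg, "counts must be 256 non-negative integers")
    else if (sum(object@counts) != object@totalPixels)
      msg <- c(msg, "sum(counts) must equal totalPixels")
    if (object@totalPixels < 1L)
      msg <- c(msg, "totalPixels must be positive")
    if (is.finite(object@entropyBits) &&
        object@entropyBits > 8 + 1e-9)
      msg <- c(msg, "entropyBits cannot exceed 8")
    if (is.null(msg)) TRUE else msg
  })

#' Grain-size distribution
#'
#' Fixed-width histogram of particle equivalent diameters, the desk-scale
#' replacement for a dynamic light scattering size measurement.
#'
#' @slot binEdgesUm increasing numeric bin edges starting at 0, in
#'   micrometres.
#' @slot counts non-negative integer counts, one per bin; their sum equals
#'   the number of particles binned.
#'
#' @seealso [grainSizeDistribution()]
#' @export
setClass("GrainSizeDistribution",
  representation(binEdgesUm = "numeric", counts = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@binEdgesUm) != length(object@counts) + 1L)
      msg <- c(msg, "need one more bin edge than counts")
    if (is.unsorted(object@binEdgesUm, strictly = TRUE))
      msg <- c(msg, "bin edges must be strictly increasing")
    if (any(object@counts < 0L))
      msg <- c(msg, "counts must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' Fibre morphometry statistics
#'
#' Local fibre diameters sampled along the medial-axis skeleton (twice the
#' distance-transform value, corrected for the centre pixel), the modal
#' diameters of their histogram (decreasing prominence), and inter-fibre
#' spacing samples from the largest inscribed gaps of the background.
#'
#' @slot diameterSamplesUm positive reals, per-skeleton-pixel diameters (um).
#' @slot modalDiametersUm local maxima of the diameter histogram, ordered by
#'   decreasing prominence (um).
#' @slot spacingSamplesUm inter-fibre gap widths (um); empty unless filled
#'   by [interFibreSpacing()].
#' @slot spacingBoundaryDominated logical flags, parallel to
#'   \code{spacingSamplesUm}: \code{TRUE} where the inscribed gap is limited
#'   by the image border rather than by two fibres.
#'
#' @seealso [fibreDiameters()], [interFibreSpacing()]
#' @export
setClass("FibreStats",
  representation(diameterSamplesUm = "numeric", modalDiametersUm = "numeric",
                 spacingSamplesUm = "numeric",
                 spacingBoundaryDominated = "logical"),
  validity = function(object) {
    if (length(object@spacingBoundaryDominated) > 0L &&
        length(object@spacingBoundaryDominated) !=
        length(object@spacingSamplesUm))
      "spacingBoundaryDominated must parallel spacingSamplesUm"
    else TRUE
  })

#' Repeating texture unit
#'
#' The minimal repeating element ("original puzzle") of a periodic surface
#' texture: axis-aligned periods from the normalized 2D autocorrelation, and
#' (after [extractUnit()]) the per-cell median template with the in-plane
#' bounding-box extent of its foreground element.
#'
#' An image without a qualifying autocorrelation peak on both axes is
#' reported as aperiodic (\code{periodic = FALSE}, periods \code{NA});
#' that is a result, not an error.
#'
#' @slot periodic logical; \code{FALSE} means no repeating unit was found.
#' @slot periodRowsPx,periodColsPx integer periods in pixels (NA if
#'   aperiodic).
#' @slot pixelSizeNm calibration; \code{period_um = period_px * pixelSizeNm
#'   / 1000} exactly.
#' @slot template numeric matrix (empty until [extractUnit()]), luminance of
#'   one unit cell.
#' @slot unitHeightUm,unitWidthUm in-plane bounding-box extent of the
#'   thresholded template element (NA until extracted); never exceeds the
#'   cell period.
#'
#' @seealso [estimatePeriod()], [extractUnit()], [reconstructPattern()]
#' @export
setClass("TextureUnit",
  representation(periodic = "logical",
                 periodRowsPx = "integer", periodColsPx = "integer",
                 pixelSizeNm = "numeric", template = "matrix",
                 unitHeightUm = "numeric", unitWidthUm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@periodic) != 1L || is.na(object@periodic))
      msg <- c(msg, "periodic must be TRUE or FALSE")
    if (isTRUE(object@periodic)) {
      if (is.na(object@periodRowsPx) || is.na(object@periodColsPx) ||
          object@periodRowsPx < 1L || object@periodColsPx < 1L)
        msg <- c(msg, "periodic unit needs positive integer periods")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Normalized height map
#'
#' Luminance-as-height surface for 3D visualization. x/y carry the physical
#' calibration; z is the min-max normalized luminance in \code{[0, 1]} and is
#' explicitly unitless — SEM luminance lacks absolute height calibration, so
#' no physical height or z-integrated surface area is ever claimed. A
#' constant source maps to an all-zero height map by convention.
#'
#' @slot z numeric matrix in \code{[0, 1]}; \code{min = 0}, \code{max = 1}
#'   unless the source was constant.
#' @slot pixelSizeNm x/y calibration (nm per pixel).
#' @slot smoothingSigmaPx Gaussian sigma applied before normalization.
#'
#' @seealso [heightMap()], [exportSurface()]
#' @export
setClass("HeightMap",
  representation(z = "matrix", pixelSizeNm = "numeric",
                 smoothingSigmaPx = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.numeric(object@z) || length(dim(object@z)) != 2L)
      msg <- c(msg, "z must be a numeric matrix")
    else if (min(object@z) < 0 || max(object@z) > 1)
      msg <- c(msg, "z must lie in [0, 1]")
    if (length(object@pixelSizeNm) != 1L || object@pixelSizeNm <= 0)
      msg <- c(msg, "pixelSizeNm must be a single positive number")
    if (length(object@smoothingSigmaPx) != 1L || object@smoothingSigmaPx < 0)
      msg <- c(msg, "smoothingSigmaPx must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' Synthetic micrograph with analytic ground truth
#'
#' A generated SEM-like image paired with the exact geometry of every
#' primitive drawn into it (fibres, disks, crack segments, pores, texture
#' bumps). Regeneration with the same seed and parameters is bit-identical.
#' These fixtures stand in for real micrographs, which are not publicly
#' archived, and power every end-to-end recovery test.
#'
#' @slot image a [CalibratedImage-class].
#' @slot truth data.frame, one row per primitive; columns depend on
#'   \code{kind} (always present: \code{kind}; geometry in px and physical
#'   units, analytic lengths/areas where defined).
#' @slot seed integer seed used for generation.
#' @slot noiseSigma Gaussian noise standard deviation applied (luminance
#'   levels).
#' @slot shotNoise logical, whether signal-dependent noise was added.
#'
#' @seealso [genCrackField()], [genPoreField()], [genFibreMesh()],
#'   [genTexture()], [genSpheres()], [addSemNoise()]
#' @export
setClass("SyntheticMicrograph",
  representation(image = "CalibratedImage", truth = "data.frame",
                 seed = "integer", noiseSigma = "numeric",
                 shotNoise = "logical"))
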