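#' @include AllClasses.R
NULL

#' Access the luminance matrix
#'
#' @param object a [CalibratedImage-class] (or object carrying pixels).
#' @return numeric matrix of luminance values in \code{[0, 255]},
#'   \code{dim = c(height_px, width_px)}.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "CalibratedImage", function(object) object@pixels)

#' Physical pixel size in nanometres
#'
#' @param object an object carrying a calibration (image, edge map, label
#'   mask, texture unit, height map).
#' @return positive scalar, nanometres per pixel edge.
#' @export
setGeneric("pixelSizeNm", function(object) standardGeneric("pixelSizeNm"))

#' @rdname pixelSizeNm
#' @export
setMethod("pixelSizeNm", "CalibratedImage", function(object) object@pixelSizeNm)
#' @rdname pixelSizeNm
#' @export
setMethod("pixelSizeNm", "EdgeMap", function(object) object@pixelSizeNm)
#' @rdname pixelSizeNm
#' @export
setMethod("pixelSizeNm", "LabelMask", function(object) object@pixelSizeNm)
#' @rdname pixelSizeNm
#' @export
setMethod("pixelSizeNm", "TextureUnit", function(object) object@pixelSizeNm)
#' @rdname pixelSizeNm
#' @export
setMethod("pixelSizeNm", "HeightMap", function(object) object@pixelSizeNm)

#' Binary edge mask
#'
#' @param object an [EdgeMap-class].
#' @return logical matrix, \code{TRUE} at edge pixels.
#' @export
setGeneric("edgeMask", function(object) standardGeneric("edgeMask"))

#' @rdname edgeMask
#' @export
setMethod("edgeMask", "EdgeMap", function(object) object@mask)

#' Label matrix of a segmentation
#'
#' @param object a [LabelMask-class].
#' @return integer matrix; 0 is background, objects are 1..n.
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))

#' @rdname labelMatrix
#' @export
setMethod("labelMatrix", "LabelMask", function(object) object@labels)

#' Number of labelled objects
#'
#' @param object a [LabelMask-class].
#' @return non-negative integer count of objects.
#' @export
setGeneric("nObjects", function(object) standardGeneric("nObjects"))

#' @rdname nObjects
#' @export
setMethod("nObjects", "LabelMask", function(object) as.integer(max(object@labels)))

#' Histogram counts and statistics accessors
#'
#' @param object a [HistogramProfile-class].
#' @return \code{histCounts}: integer vector of length 256 (raw counts, or
#'   densities if the profile was built with \code{normalize = TRUE});
#'   \code{histStats}: named numeric vector with \code{mean}, \code{std},
#'   \code{iqr}, \code{entropy_bits}, \code{total_pixels}.
#' @export
setGeneric("histCounts", function(object) standardGeneric("histCounts"))

#' @rdname histCounts
#' @export
setMethod("histCounts", "HistogramProfile", function(object) {
  if (object@normalized) object@counts / object@totalPixels
  else object@counts
})

#' @rdname histCounts
#' @export
setGeneric("histStats", function(object) standardGeneric("histStats"))

#' @rdname histCounts
#' @export
setMethod("histStats", "HistogramProfile", function(object)
  c(mean = object@mean, std = object@std, iqr = object@iqr,
    entropy_bits = object@entropyBits,
    total_pixels = as.numeric(object@totalPixels)))

#' Ground-truth table of a synthetic micrograph
#'
#' @param object a [SyntheticMicrograph-class].
#' @return \code{groundTruth}: data.frame of primitive records;
#'   \code{synthImage}: the generated [CalibratedImage-class].
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "SyntheticMicrograph", function(object) object@truth)

#' @rdname groundTruth
#' @export
setGeneric("synthImage", function(object) standardGeneric("synthImage"))

#' @rdname groundTruth
#' @export
setMethod("synthImage", "SyntheticMicrograph", function(object) object@image)

#' @describeIn CalibratedImage-class dimensions as c(height_px, width_px)
#' @param x a CalibratedImage
#' @export
setMethod("dim", "CalibratedImage", function(x) dim(x@pixels))

setMethod("show", "CalibratedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "CalibratedImage: %d x %d px @ %g nm/px (%.3f x %.3f um)\n",
    d[1], d[2], object@pixelSizeNm,
    d[1] * object@pixelSizeNm / 1000, d[2] * object@pixelSizeNm / 1000))
  cat(sprintf("  luminance range [%d, %d], mean %.1f\n",
              min(object@pixels), max(object@pixels), mean(object@pixels)))
})

setMethod("show", "ROI", function(object) {
  cat(sprintf("ROI: origin (%d, %d), %d x %d px (half-open, 0-based)\n",
              object@row0, object@col0, object@heightPx, object@widthPx))
})

setMethod("show", "CannyParams", function(object) {
  cat(sprintf("CannyParams: sigma = %g px, thresholds %g / %g of max gradient\n",
              object@sigma, object@lowFrac, object@highFrac))
})

setMethod("show", "EdgeMap", function(object) {
  d <- dim(object@mask)
  cat(sprintf("EdgeMap: %d x %d px @ %g nm/px, %d edge pixels (%.2f%%)%s\n",
              d[1], d[2], object@pixelSizeNm, sum(object@mask),
              100 * mean(object@mask),
              if (object@skeletonized) ", skeletonized" else ""))
})

setMethod("show", "LabelMask", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelMask: %d x %d px @ %g nm/px, %d objects\n",
              d[1], d[2], object@pixelSizeNm, max(object@labels)))
})

setMethod("show", "HistogramProfile", function(object) {
  cat(sprintf(
    "HistogramProfile: %d px, mean %.2f, std %.2f, IQR %.1f, entropy %.2f bits\n",
    object@totalPixels, object@mean, object@std, object@iqr,
    object@entropyBits))
})

setMethod("show", "GrainSizeDistribution", function(object) {
  cat(sprintf("GrainSizeDistribution: %d bins of %g um, %d particles\n",
              length(object@counts), diff(object@binEdgesUm[1:2]),
              sum(object@counts)))
})

setMethod("show", "FibreStats", function(object) {
  cat(sprintf("FibreStats: %d diameter samples, modal diameters [%s] um\n",
              length(object@diameterSamplesUm),
              paste(signif(object@modalDiametersUm, 3), collapse = ", ")))
  if (length(object@spacingSamplesUm))
    cat(sprintf("  %d spacing samples, median %.2f um\n",
                length(object@spacingSamplesUm),
                stats::median(object@spacingSamplesUm)))
})

setMethod("show", "TextureUnit", function(object) {
  if (!object@periodic) {
    cat("TextureUnit: aperiodic (no qualifying autocorrelation peak)\n")
  } else {
    cat(sprintf("TextureUnit: period (%d, %d) px = (%.3f, %.3f) um\n",
                object@periodRowsPx, object@periodColsPx,
                object@periodRowsPx * object@pixelSizeNm / 1000,
                object@periodColsPx * object@pixelSizeNm / 1000))
    if (length(object@template))
      cat(sprintf("  element extent %.3f x %.3f um (in-plane bounding box)\n",
                  object@unitHeightUm, object@unitWidthUm))
  }
})

setMethod("show", "HeightMap", function(object) {
  d <- dim(object@z)
  cat(sprintf(
    "HeightMap: %d x %d px @ %g nm/px, z normalized to [0, 1] (unitless)\n",
    d[1], d[2], object@pixelSizeNm))
})

setMethod("show", "SyntheticMicrograph", function(object) {
  cat(sprintf("SyntheticMicrograph (seed %d): %s\n", object@seed,
              paste(sprintf("%d %s", table(object@truth$kind),
                            names(table(object@truth$kind))),
                    collapse = ", ")))
  show(object@image)
})
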