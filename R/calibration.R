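#' @include AllClasses.R AllGenerics.R utils-internal.R
NULL

#' Construct a CalibratedImage from a luminance matrix
#'
#' @param pixels numeric matrix of luminance values in \code{[0, 255]}
#'   (rows = image rows); values are rounded to integers.
#' @param pixelSizeNm positive scalar, nanometres per pixel edge.
#' @return a [CalibratedImage-class].
#' @examples
#' img <- calibratedImage(matrix(128, 64, 64), pixelSizeNm = 10)
#' dim(img)
#' @export
calibratedImage <- function(pixels, pixelSizeNm) {
  if (!is.numeric(pixelSizeNm) || length(pixelSizeNm) != 1L ||
      !is.finite(pixelSizeNm) || pixelSizeNm <= 0)
    stop("pixelSizeNm must be a single positive number")
  new("CalibratedImage", pixels = round(pixels), pixelSizeNm = pixelSizeNm)
}

#' Construct a region of interest
#'
#' Coordinates are 0-based and the extent is half-open: the ROI covers rows
#' \code{row0 .. row0 + heightPx - 1}. Its physical perimeter is
#' \code{2 * (heightPx + widthPx) * pixelSizeNm}.
#'
#' @param row0,col0 0-based top-left corner.
#' @param heightPx,widthPx positive integer extent.
#' @return a [ROI-class].
#' @export
roi <- function(row0, col0, heightPx, widthPx) {
  new("ROI", row0 = as.integer(row0), col0 = as.integer(col0),
      heightPx = as.integer(heightPx), widthPx = as.integer(widthPx))
}

#' Full-image region of interest
#'
#' @param img a [CalibratedImage-class] or [EdgeMap-class].
#' @return a [ROI-class] covering the whole image.
#' @export
fullROI <- function(img) {
  d <- if (is(img, "EdgeMap")) dim(img@mask) else dim(pixels(img))
  roi(0L, 0L, d[1], d[2])
}

# Stop unless the ROI lies entirely inside a height x width grid.
checkROI <- function(r, heightPx, widthPx) {
  stopifnot(is(r, "ROI"))
  if (r@row0 + r@heightPx > heightPx || r@col0 + r@widthPx > widthPx)
    stop(sprintf("ROI (%d,%d)+%dx%d exceeds image extent %dx%d",
                 r@row0, r@col0, r@heightPx, r@widthPx, heightPx, widthPx))
  invisible(TRUE)
}

# Index vectors (1-based) covered by an ROI.
roiRows <- function(r) seq.int(r@row0 + 1L, r@row0 + r@heightPx)
roiCols <- function(r) seq.int(r@col0 + 1L, r@col0 + r@widthPx)

#' Load a micrograph from TIFF or PNG
#'
#' Reads an 8- or 16-bit, single- or 3-channel raster and returns a
#' calibrated 8-bit luminance image. 3-channel input is reduced with the
#' classic luminance weights 0.299/0.587/0.114; 16-bit input is linearly
#' rescaled over the full container range to \code{[0, 255]} (no percentile
#' stretching, so the fixed 0-255 histogram semantics are preserved).
#'
#' The physical pixel size must be supplied explicitly: SEM vendors embed
#' the scale only in burned-in scale bars, which this package deliberately
#' does not parse.
#'
#' @param path path to a TIFF or PNG file.
#' @param pixelSizeNm positive scalar, nanometres per pixel edge.
#' @return a [CalibratedImage-class].
#' @seealso [writeCalibratedImage()]
#' @export
loadImage <- function(path, pixelSizeNm) {
  if (!is.numeric(pixelSizeNm) || length(pixelSizeNm) != 1L ||
      !is.finite(pixelSizeNm) || pixelSizeNm <= 0)
    stop("pixelSizeNm must be a single positive number")
  if (!file.exists(path)) stop("cannot read image file: ", path)
  im <- EBImage::readImage(path)   # values scaled to [0, 1] at any bit depth
  a <- EBImage::imageData(im)
  d <- dim(a)
  if (length(d) == 3L) {
    if (d[3] == 1L) a <- a[, , 1]
    else if (d[3] %in% c(3L, 4L)) {
      if (d[3] == 4L) a <- a[, , 1:3]         # drop alpha
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else stop("unsupported channel count: ", d[3])
  } else if (length(d) != 2L) stop("unsupported image dimensionality")
  # EBImage stores (x, y); transpose to (row, col)
  px <- round(t(a) * 255)
  calibratedImage(px, pixelSizeNm)
}

#' Write a CalibratedImage as 8-bit greyscale
#'
#' @param img a [CalibratedImage-class].
#' @param path output path; format from extension (.tif/.tiff or .png).
#' @return the path, invisibly.
#' @export
writeCalibratedImage <- function(img, path) {
  stopifnot(is(img, "CalibratedImage"))
  EBImage::writeImage(EBImage::Image(t(pixels(img)) / 255), path,
                      bits.per.sample = 8L)
  invisible(path)
}

#' Gaussian denoising
#'
#' Conventional pre-metric denoising: a Gaussian blur of the stated standard
#' deviation, re-rounded and clamped to \code{[0, 255]}. A sigma of zero
#' returns the input unchanged.
#'
#' @param img a [CalibratedImage-class].
#' @param sigmaPx non-negative blur standard deviation in pixels.
#' @return a [CalibratedImage-class] of the same size and calibration.
#' @export
denoise <- function(img, sigmaPx) {
  stopifnot(is(img, "CalibratedImage"))
  if (!is.numeric(sigmaPx) || length(sigmaPx) != 1L || !is.finite(sigmaPx) ||
      sigmaPx < 0)
    stop("sigmaPx must be a single non-negative number")
  if (sigmaPx == 0) return(img)
  calibratedImage(clamp255(gaussBlur(pixels(img), sigmaPx)),
                  pixelSizeNm(img))
}

#' Crop to a region of interest
#'
#' @param img a [CalibratedImage-class].
#' @param r a [ROI-class] lying inside the image.
#' @return the sub-image, carrying the same calibration.
#' @export
cropImage <- function(img, r) {
  stopifnot(is(img, "CalibratedImage"))
  px <- pixels(img)
  checkROI(r, nrow(px), ncol(px))
  calibratedImage(px[roiRows(r), roiCols(r), drop = FALSE], pixelSizeNm(img))
}

#' Physical area of an image or ROI in square micrometres
#'
#' @param x a [CalibratedImage-class], [EdgeMap-class] or [ROI-class].
#' @param pixelSizeNm required when \code{x} is a bare ROI.
#' @return area in um^2.
#' @export
physicalAreaUm2 <- function(x, pixelSizeNm = NULL) {
  if (is(x, "ROI")) {
    if (is.null(pixelSizeNm)) stop("pixelSizeNm needed for a bare ROI")
    npx <- as.numeric(x@heightPx) * x@widthPx
    p <- pixelSizeNm
  } else {
    d <- if (is(x, "EdgeMap")) dim(x@mask) else dim(pixels(x))
    npx <- as.numeric(d[1]) * d[2]
    p <- pixelSizeNm(x)
  }
  npx * (p / 1000)^2
}
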