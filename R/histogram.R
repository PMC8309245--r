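#' @include AllClasses.R AllGenerics.R utils-internal.R calibration.R
NULL

#' Luminance histogram of an image or region
#'
#' 256 fixed bins over the full greyscale range 0-255 (the full range is
#' always preserved — no stretching), with spread statistics computed from
#' the raw counts: mean, population standard deviation, inter-quartile
#' range, and Shannon entropy in bits. Under fixed acquisition parameters,
#' a rougher / more aged surface scatters electrons from more edges and its
#' histogram broadens; an ideally flat surface has constant luminescence
#' and a single occupied bin. \code{normalize = TRUE} only switches display
#' ([histCounts()]) to densities; statistics are unaffected.
#'
#' @param img a [CalibratedImage-class].
#' @param r a [ROI-class] (default: whole image).
#' @param normalize display counts as densities.
#' @return a [HistogramProfile-class].
#' @examples
#' img <- calibratedImage(matrix(128, 100, 100), 10)
#' histStats(luminanceHistogram(img))["std"]  # exactly 0
#' @export
luminanceHistogram <- function(img, r = fullROI(img), normalize = FALSE) {
  stopifnot(is(img, "CalibratedImage"))
  px <- pixels(cropImage(img, r))
  counts <- tabulate(as.integer(px) + 1L, nbins = 256L)
  total <- sum(counts)
  v <- 0:255
  mu <- sum(v * counts) / total
  sd <- sqrt(sum(counts * (v - mu)^2) / total)
  cum <- cumsum(counts)
  qAt <- function(p) v[which(cum >= p * total)[1]]
  iqr <- qAt(0.75) - qAt(0.25)
  pr <- counts[counts > 0] / total
  ent <- -sum(pr * log2(pr))
  new("HistogramProfile", counts = counts, totalPixels = as.integer(total),
      mean = mu, std = sd, iqr = as.numeric(iqr), entropyBits = ent,
      normalized = isTRUE(normalize))
}

#' Compare surface roughness via histogram broadening
#'
#' Orders two luminance profiles by spread — the first-pass quantitative
#' indicator of surface ageing: the broader histogram belongs to the
#' rougher, more worn surface. The ordering key is the standard deviation,
#' with the inter-quartile range as tie-break; if both agree within
#' \code{tol} the profiles are reported as \code{"indistinguishable"}.
#'
#' Histogram comparison is only meaningful for images acquired under the
#' same apparatus parameters; that fact lives outside the image, so the
#' caller must assert it via \code{sameAcquisition = TRUE} or the
#' comparison refuses to run.
#'
#' @param a,b [HistogramProfile-class] objects.
#' @param sameAcquisition caller's assertion that both images were acquired
#'   under identical apparatus parameters.
#' @param tol spread difference (luminance levels) below which profiles are
#'   indistinguishable.
#' @return list with \code{ordering} (\code{"a_broader"},
#'   \code{"b_broader"} or \code{"indistinguishable"}) and \code{stats}, a
#'   2-row data.frame of std/IQR/entropy for a and b.
#' @export
compareRoughness <- function(a, b, sameAcquisition = FALSE, tol = 1e-6) {
  stopifnot(is(a, "HistogramProfile"), is(b, "HistogramProfile"))
  if (!isTRUE(sameAcquisition))
    stop("roughness comparison requires images acquired under the same ",
         "apparatus parameters; assert this with sameAcquisition = TRUE")
  stats <- data.frame(
    profile = c("a", "b"),
    std = c(a@std, b@std), iqr = c(a@iqr, b@iqr),
    entropy_bits = c(a@entropyBits, b@entropyBits))
  dStd <- a@std - b@std
  ordering <- if (abs(dStd) >= tol) {
    if (dStd > 0) "a_broader" else "b_broader"
  } else {
    dIqr <- a@iqr - b@iqr
    if (abs(dIqr) >= tol) {
      if (dIqr > 0) "a_broader" else "b_broader"
    } else "indistinguishable"
  }
  list(ordering = ordering, stats = stats)
}
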