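#' @include AllClasses.R AllGenerics.R utils-internal.R calibration.R
NULL

#' Detect surface perforations
#'
#' Pores (holes) are dark connected components within a region of interest,
#' found by global thresholding, 8-connected labelling, and a size window
#' \code{[minAreaPx, maxAreaPx]} that rejects noise specks and large dark
#' zones that are not perforations. Pores crossing the ROI boundary count
#' toward count and area. On heavily weathered beach debris the resulting
#' holes are the habitat relevant for settlement, so their density and
#' covered-area fraction are the metrics of interest (see [poreMetrics()]).
#'
#' @param img a [CalibratedImage-class].
#' @param r a [ROI-class] (default: whole image); analysis is restricted to
#'   it.
#' @param threshold \code{"otsu"} or a numeric level in \code{[0, 255]}.
#' @param minAreaPx,maxAreaPx inclusive size window in pixels;
#'   \code{maxAreaPx = NULL} defaults to 10\% of the ROI pixel count.
#' @param polarity \code{"dark"} pores on bright surround (default) or
#'   \code{"bright"}.
#' @return a [LabelMask-class] of ROI size.
#' @export
detectPores <- function(img, r = fullROI(img), threshold = "otsu",
                        minAreaPx = 10L, maxAreaPx = NULL,
                        polarity = c("dark", "bright")) {
  stopifnot(is(img, "CalibratedImage"))
  polarity <- match.arg(polarity)
  sub <- cropImage(img, r)
  px <- pixels(sub)
  if (is.null(maxAreaPx)) maxAreaPx <- ceiling(0.1 * length(px))
  if (minAreaPx > maxAreaPx) stop("minAreaPx must not exceed maxAreaPx")
  thr <- resolveThreshold(threshold, px)
  mask <- if (polarity == "dark") px < thr else px > thr
  lab <- filterLabelsBySize(label8(mask), minAreaPx = minAreaPx,
                            maxAreaPx = maxAreaPx)
  new("LabelMask", labels = lab, pixelSizeNm = pixelSizeNm(img))
}

#' Perforation metrics
#'
#' Pore count, surface density (holes per square micrometre of analysed
#' area), percent of the analysed area covered, and mean pore area. The
#' identity \code{density * mean_area = fraction / 100} holds exactly by
#' construction. A pore-free region reports zeros throughout.
#'
#' @param pores a [LabelMask-class] from [detectPores()] (its extent is the
#'   analysed region).
#' @return one-row data.frame with columns \code{count},
#'   \code{density_per_um2}, \code{area_fraction_percent},
#'   \code{mean_pore_area_um2}, \code{analysed_area_um2}.
#' @export
poreMetrics <- function(pores) {
  stopifnot(is(pores, "LabelMask"))
  lab <- pores@labels
  p_um <- pores@pixelSizeNm / 1000
  analysedUm2 <- as.numeric(nrow(lab)) * ncol(lab) * p_um^2
  if (analysedUm2 <= 0) stop("zero-area region")
  n <- max(lab)
  totalPoreUm2 <- sum(lab > 0L) * p_um^2
  data.frame(
    count = as.integer(n),
    density_per_um2 = n / analysedUm2,
    area_fraction_percent = 100 * totalPoreUm2 / analysedUm2,
    mean_pore_area_um2 = if (n > 0L) totalPoreUm2 / n else 0,
    analysed_area_um2 = analysedUm2)
}
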