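#' @include AllClasses.R AllGenerics.R utils-internal.R calibration.R
NULL

#' Three-step particle detection
#'
#' The simple detection protocol for debris particles: greyscale (already
#' guaranteed by ingestion), global thresholding, and connected-component
#' labelling (8-connectivity). Components smaller than \code{minAreaPx} are
#' removed and the survivors relabelled consecutively. Touching or
#' overlapping particles are reported as one object — no watershed
#' splitting is attempted (documented limitation of the protocol).
#'
#' @param img a [CalibratedImage-class] (denoise first if required).
#' @param threshold \code{"otsu"} (default) or a numeric luminance level in
#'   \code{[0, 255]}.
#' @param minAreaPx drop components smaller than this many pixels
#'   (default 10, suppresses noise specks).
#' @param polarity \code{"bright"} objects on dark background (default) or
#'   \code{"dark"}.
#' @return a [LabelMask-class].
#' @seealso [particleStats()], [grainSizeDistribution()]
#' @export
segmentParticles <- function(img, threshold = "otsu", minAreaPx = 10L,
                             polarity = c("bright", "dark")) {
  stopifnot(is(img, "CalibratedImage"))
  polarity <- match.arg(polarity)
  px <- pixels(img)
  thr <- resolveThreshold(threshold, px)
  mask <- if (polarity == "bright") px > thr else px < thr
  lab <- filterLabelsBySize(label8(mask), minAreaPx = minAreaPx)
  new("LabelMask", labels = lab, pixelSizeNm = pixelSizeNm(img))
}

#' Per-particle geometry
#'
#' Physical geometry of every labelled object: pixel count times the squared
#' pixel size gives the area; the equivalent diameter is that of the circle
#' of equal area, \code{2 * sqrt(area / pi)}; for objects assumed spherical
#' (nurdles, microspheres) the volume follows from the equivalent radius of
#' the 2D projection, \code{(4/3) * pi * r^3}.
#'
#' @param mask a [LabelMask-class] from [segmentParticles()].
#' @param assumeSpherical add a \code{volume_um3} column (closed-form sphere
#'   volume from the equivalent radius).
#' @return data.frame with one row per particle: \code{label},
#'   \code{area_px}, \code{area_um2}, \code{equivalent_diameter_um},
#'   \code{centroid_row}, \code{centroid_col}, \code{touches_border}, and
#'   optionally \code{volume_um3}. Total detected area is
#'   \code{sum(area_um2)}.
#' @examples
#' # a sphere of equivalent radius 10 um has volume (4/3)*pi*1000 um^3
#' sphereVolumeUm3(10)
#' @export
particleStats <- function(mask, assumeSpherical = FALSE) {
  stopifnot(is(mask, "LabelMask"))
  lab <- mask@labels
  n <- max(lab)
  p_um <- mask@pixelSizeNm / 1000
  if (n == 0L) {
    out <- data.frame(label = integer(0), area_px = integer(0),
                      area_um2 = numeric(0),
                      equivalent_diameter_um = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      touches_border = logical(0))
    if (assumeSpherical) out$volume_um3 <- numeric(0)
    return(out)
  }
  nz <- which(lab > 0L)
  l <- lab[nz]
  areaPx <- tabulate(l, nbins = n)
  rows <- ((nz - 1L) %% nrow(lab)) + 1L
  cols <- ((nz - 1L) %/% nrow(lab)) + 1L
  cr <- rowsum(as.numeric(rows), l)[, 1] / areaPx
  cc <- rowsum(as.numeric(cols), l)[, 1] / areaPx
  border <- rows == 1L | rows == nrow(lab) | cols == 1L | cols == ncol(lab)
  touches <- logical(n)
  touches[unique(l[border])] <- TRUE
  areaUm2 <- areaPx * p_um^2
  eqd <- 2 * sqrt(areaUm2 / pi)
  out <- data.frame(label = seq_len(n), area_px = areaPx,
                    area_um2 = areaUm2, equivalent_diameter_um = eqd,
                    centroid_row = cr, centroid_col = cc,
                    touches_border = touches)
  if (assumeSpherical) out$volume_um3 <- sphereVolumeUm3(eqd / 2)
  out
}

#' Sphere volume from radius
#'
#' @param radiusUm radius in micrometres (vectorized).
#' @return volume in cubic micrometres, \code{(4/3) * pi * r^3}.
#' @export
sphereVolumeUm3 <- function(radiusUm) (4 / 3) * pi * radiusUm^3

#' Grain-size distribution
#'
#' Fixed-width histogram of particle equivalent diameters starting at 0 —
#' the desk-scale estimate of the size distribution that would otherwise
#' need a dynamic light scattering measurement. Border-touching particles
#' are excluded by default (their area, hence diameter, is censored by the
#' field of view), though they still count toward total detected area in
#' [particleStats()].
#'
#' @param records data.frame from [particleStats()].
#' @param binWidthUm positive bin width in micrometres.
#' @param includeBorder keep border-touching particles.
#' @return a [GrainSizeDistribution-class].
#' @export
grainSizeDistribution <- function(records, binWidthUm, includeBorder = FALSE) {
  if (!is.numeric(binWidthUm) || length(binWidthUm) != 1L || binWidthUm <= 0)
    stop("binWidthUm must be a single positive number")
  d <- records$equivalent_diameter_um
  if (!includeBorder && nrow(records)) d <- d[!records$touches_border]
  if (!length(d)) {
    return(new("GrainSizeDistribution", binEdgesUm = c(0, binWidthUm),
               counts = 0L))
  }
  nBins <- max(1L, ceiling(max(d) / binWidthUm + 1e-9))
  edges <- seq(0, nBins * binWidthUm, by = binWidthUm)
  idx <- pmin(nBins, floor(d / binWidthUm) + 1L)
  new("GrainSizeDistribution", binEdgesUm = edges,
      counts = tabulate(idx, nbins = nBins))
}

#' Fibre diameter morphometry
#'
#' Local fibre diameters for mesh/filter imagery (e.g. glass-fibre filters):
#' the fibre mask is reduced to its medial-axis skeleton, and at each
#' skeleton pixel the local diameter is \code{2 d - 1} pixels, where
#' \code{d} is the Euclidean distance-transform value (distance from the
#' centre pixel to the nearest background pixel). Modal diameters are the
#' local maxima of the 1-px-binned diameter histogram, ordered by
#' decreasing prominence — for a multi-fraction filter these are the
#' fraction diameters.
#'
#' @param img a [CalibratedImage-class] of bright fibres on dark background
#'   (or the reverse with \code{polarity = "dark"}).
#' @param threshold \code{"otsu"} or a numeric level.
#' @param polarity foreground polarity, as in [segmentParticles()].
#' @param minPeakSep minimum separation of modal peaks, in pixels of
#'   diameter (default 3).
#' @return a [FibreStats-class] (spacing slots empty; see
#'   [interFibreSpacing()]).
#' @export
fibreDiameters <- function(img, threshold = "otsu",
                           polarity = c("bright", "dark"), minPeakSep = 3L) {
  stopifnot(is(img, "CalibratedImage"))
  polarity <- match.arg(polarity)
  px <- pixels(img)
  thr <- resolveThreshold(threshold, px)
  mask <- if (polarity == "bright") px > thr else px < thr
  if (!any(mask))
    return(new("FibreStats", diameterSamplesUm = numeric(0),
               modalDiametersUm = numeric(0), spacingSamplesUm = numeric(0),
               spacingBoundaryDominated = logical(0)))
  skel <- thinMask(mask)
  dm <- distanceMap(mask)
  dPx <- 2 * dm[skel] - 1
  dPx <- dPx[dPx >= 1]
  p_um <- pixelSizeNm(img) / 1000
  samplesUm <- dPx * p_um
  modal <- histogramModes(dPx, minSep = minPeakSep) * p_um
  new("FibreStats", diameterSamplesUm = samplesUm,
      modalDiametersUm = modal, spacingSamplesUm = numeric(0),
      spacingBoundaryDominated = logical(0))
}

# Modes of an integer-binned sample: bins beating both neighbours, greedily
# accepted in decreasing count order subject to a minimum separation.
histogramModes <- function(x, minSep = 3L) {
  if (!length(x)) return(numeric(0))
  x <- round(x)
  lo <- min(x)
  cnt <- tabulate(x - lo + 1L)
  k <- length(cnt)
  if (k == 1L) return(as.numeric(lo))
  left <- c(0, cnt[-k]); right <- c(cnt[-1], 0)
  isPeak <- cnt > 0 & cnt >= left & cnt >= right & (cnt > left | cnt > right)
  if (!any(isPeak)) isPeak[which.max(cnt)] <- TRUE
  peaks <- which(isPeak)
  peaks <- peaks[order(-cnt[peaks])]
  keep <- numeric(0)
  for (p in peaks)
    if (!length(keep) || all(abs(keep - p) >= minSep)) keep <- c(keep, p)
  keep + lo - 1
}

#' Inter-fibre spacing
#'
#' Spacing between fibres sampled as twice the local maxima of the
#' background Euclidean distance transform — the diameters of the largest
#' gaps inscribed between fibres. Maxima whose inscribed gap is limited by
#' the image border rather than by fibres on both sides are flagged
#' \code{boundary_dominated} (e.g. a single fibre in an empty field, where
#' the "spacing" merely reflects the field half-width).
#'
#' @param mask logical fibre mask (TRUE = fibre), or a [LabelMask-class].
#' @param pixelSizeNm calibration, required when \code{mask} is a bare
#'   matrix.
#' @return data.frame with columns \code{spacing_um} and
#'   \code{boundary_dominated}; zero rows for an all-foreground mask.
#' @export
interFibreSpacing <- function(mask, pixelSizeNm = NULL) {
  if (is(mask, "LabelMask")) {
    pixelSizeNm <- mask@pixelSizeNm
    mask <- mask@labels > 0L
  }
  if (is.null(pixelSizeNm)) stop("pixelSizeNm needed for a bare mask")
  bg <- !(mask != 0)
  if (!any(bg))
    return(data.frame(spacing_um = numeric(0),
                      boundary_dominated = logical(0)))
  dm <- distanceMap(bg)
  nbrMax <- matrix(-Inf, nrow(dm), ncol(dm))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nbrMax <- pmax(nbrMax, shiftMat(dm, dr, dc, fill = -Inf))
  }
  loc <- which(bg & dm > 0 & dm >= nbrMax)
  if (!length(loc))
    return(data.frame(spacing_um = numeric(0),
                      boundary_dominated = logical(0)))
  rows <- ((loc - 1L) %% nrow(dm)) + 1L
  cols <- ((loc - 1L) %/% nrow(dm)) + 1L
  borderDist <- pmin(rows - 1L, nrow(dm) - rows, cols - 1L, ncol(dm) - cols)
  data.frame(spacing_um = 2 * dm[loc] * pixelSizeNm / 1000,
             boundary_dominated = borderDist < dm[loc])
}
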