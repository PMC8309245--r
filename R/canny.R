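#' @include AllClasses.R AllGenerics.R utils-internal.R calibration.R
NULL

#' Canny parameter set
#'
#' Defaults (\code{sigma = 2}, thresholds 0.1/0.2 of the maximum gradient)
#' work well on detector-noise-level micrographs; whatever values are chosen,
#' hold them fixed across any series of images that will be compared.
#'
#' @param sigma Gaussian smoothing standard deviation in pixels.
#' @param lowFrac,highFrac hysteresis thresholds as fractions of the
#'   per-image maximum gradient magnitude, \code{0 < lowFrac < highFrac < 1}.
#' @return a [CannyParams-class].
#' @export
cannyParams <- function(sigma = 2, lowFrac = 0.1, highFrac = 0.2) {
  new("CannyParams", sigma = sigma, lowFrac = lowFrac, highFrac = highFrac)
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and double-threshold hysteresis: pixels
#' between the two thresholds survive only if 8-connected to a pixel above
#' the high threshold. The result is deterministic for a fixed input and
#' parameter set. A constant image yields an empty edge map (a result, not
#' an error).
#'
#' The single-pixel image border is excluded from the edge map (gradient
#' support is incomplete there).
#'
#' @param img a [CalibratedImage-class], at least 3 x 3.
#' @param params a [CannyParams-class]; see [cannyParams()].
#' @return an [EdgeMap-class] (not yet skeletonized).
#' @examples
#' px <- matrix(0, 64, 64); px[, 33:64] <- 255
#' em <- detectEdges(calibratedImage(px, 10))
#' sum(edgeMask(em))  # one vertical chain at the luminance step
#' @export
detectEdges <- function(img, params = cannyParams()) {
  stopifnot(is(img, "CalibratedImage"), is(params, "CannyParams"))
  x <- pixels(img)
  nr <- nrow(x); nc <- ncol(x)
  if (nr < 3L || nc < 3L) stop("image must be at least 3 x 3")
  xs <- gaussBlur(x, params@sigma)

  # Sobel-style gradients; gx along columns (x), gy along rows (y)
  gx <- shiftMat(xs, 0, -1) - shiftMat(xs, 0, 1)
  gx <- gx + (shiftMat(xs, -1, -1) - shiftMat(xs, -1, 1) +
              shiftMat(xs, 1, -1) - shiftMat(xs, 1, 1)) / 2
  gy <- shiftMat(xs, -1, 0) - shiftMat(xs, 1, 0)
  gy <- gy + (shiftMat(xs, -1, -1) - shiftMat(xs, 1, -1) +
              shiftMat(xs, -1, 1) - shiftMat(xs, 1, 1)) / 2
  mag <- sqrt(gx^2 + gy^2)
  # exclude the border: gradient support incomplete there
  mag[c(1L, nr), ] <- 0; mag[, c(1L, nc)] <- 0
  mmax <- max(mag)
  # guard against FFT rounding dust on flat images: gradients below a
  # thousandth of a luminance level per pixel are not structure
  if (mmax < 1e-3)
    return(new("EdgeMap", mask = matrix(FALSE, nr, nc),
               pixelSizeNm = pixelSizeNm(img), skeletonized = FALSE))

  # non-maximum suppression along the true gradient direction: sample the
  # magnitude one pixel forward and backward along the gradient unit vector
  # by bilinear interpolation (quantizing to 8 directions leaves 2-px-thick
  # bands on 45-degree boundaries). Ties are broken deterministically: >=
  # against the forward sample, > against the backward one, so a flat
  # two-pixel maximum keeps exactly one pixel.
  safeMag <- pmax(mag, .Machine$double.xmin)
  uy <- gy / safeMag; ux <- gx / safeMag
  rIdx <- matrix(seq_len(nr), nr, nc)
  cIdx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  bilinear <- function(fr, fc) {
    r0 <- floor(fr); c0 <- floor(fc)
    wr <- fr - r0; wc <- fc - c0
    cl <- function(r, c) {
      r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
      mag[cbind(as.vector(r), as.vector(c))]
    }
    v <- (1 - wr) * (1 - wc) * cl(r0, c0) + (1 - wr) * wc * cl(r0, c0 + 1) +
      wr * (1 - wc) * cl(r0 + 1, c0) + wr * wc * cl(r0 + 1, c0 + 1)
    matrix(v, nr, nc)
  }
  sFwd <- bilinear(rIdx + uy, cIdx + ux)
  sBwd <- bilinear(rIdx - uy, cIdx - ux)
  nms <- mag > 0 & mag >= sFwd & mag > sBwd

  low <- params@lowFrac * mmax; high <- params@highFrac * mmax
  cand <- nms & mag >= low
  strong <- nms & mag >= high
  if (!any(strong))
    return(new("EdgeMap", mask = matrix(FALSE, nr, nc),
               pixelSizeNm = pixelSizeNm(img), skeletonized = FALSE))
  lab <- label8(cand)
  keep <- unique(lab[strong])
  mask <- matrix(lab %in% keep[keep > 0L], nr, nc)
  new("EdgeMap", mask = mask, pixelSizeNm = pixelSizeNm(img),
      skeletonized = FALSE)
}

#' Thin an edge map to 1-pixel chains
#'
#' Zhang-Suen morphological thinning; idempotent on already-thin maps.
#'
#' @param edges an [EdgeMap-class].
#' @return an [EdgeMap-class] with \code{skeletonized = TRUE}.
#' @export
thinEdges <- function(edges) {
  stopifnot(is(edges, "EdgeMap"))
  if (edges@skeletonized) return(edges)
  new("EdgeMap", mask = thinMask(edges@mask),
      pixelSizeNm = edges@pixelSizeNm, skeletonized = TRUE)
}

#' Physical edge length by chain-code stepping
#'
#' The map is thinned to 1-pixel chains, then the length is accumulated
#' step-wise between 8-adjacent edge pixels: orthogonal steps contribute one
#' pixel size, diagonal steps \code{sqrt(2)} pixel sizes. This avoids the
#' up-to-\code{sqrt(2)} overestimate of a raw pixel count on diagonal
#' chains. An empty map has length 0.
#'
#' A Canny detector responds on both sides of a physical ridge or crack, so
#' the detected length of a thin crack network is about twice its centreline
#' length; set \code{halved = TRUE} to report the per-ridge (centreline)
#' convention when comparing against known geometry.
#'
#' @param edges an [EdgeMap-class].
#' @param halved divide by two (two-boundaries-per-ridge convention).
#' @return total edge length in micrometres.
#' @examples
#' m <- matrix(FALSE, 5, 110); m[3, 5:105] <- TRUE  # 101-px chain
#' em <- new("EdgeMap", mask = m, pixelSizeNm = 10, skeletonized = TRUE)
#' edgeLength(em)  # 100 orthogonal steps of 10 nm = 1 um
#' @export
edgeLength <- function(edges, halved = FALSE) {
  stopifnot(is(edges, "EdgeMap"))
  m <- thinEdges(edges)@mask
  if (!any(m)) return(0)
  nOrth <- sum(m & shiftMat(m, 0, 1)) + sum(m & shiftMat(m, 1, 0))
  nDiag <- sum(m & shiftMat(m, 1, 1)) + sum(m & shiftMat(m, 1, -1))
  len <- (nOrth + sqrt(2) * nDiag) * edges@pixelSizeNm / 1000
  if (halved) len / 2 else len
}

#' Edge metrics for a region of interest
#'
#' The four physical edge metrics of a region: total (thinned, chain-code)
#' edge length; edge density, the length per square micrometre of region
#' area — the core surface-complexity metric; percent of region pixels that
#' are (thinned) edge pixels; and the edge-to-perimeter ratio, total edge
#' length over the region's physical perimeter — the fragmentation index
#' (heavily weathered fragments exceed 5).
#'
#' @param edges an [EdgeMap-class] for the full image.
#' @param r a [ROI-class] inside the map (default: whole image).
#' @param halved report lengths under the per-ridge convention (see
#'   [edgeLength()]).
#' @return one-row data.frame with columns \code{total_edge_length_um},
#'   \code{edge_density_um_per_um2}, \code{edge_pixel_percent},
#'   \code{edge_to_perimeter_ratio}.
#' @export
edgeMetricsForROI <- function(edges, r = fullROI(edges), halved = FALSE) {
  stopifnot(is(edges, "EdgeMap"))
  checkROI(r, nrow(edges@mask), ncol(edges@mask))
  sub <- new("EdgeMap",
             mask = edges@mask[roiRows(r), roiCols(r), drop = FALSE],
             pixelSizeNm = edges@pixelSizeNm, skeletonized = FALSE)
  sub <- thinEdges(sub)
  p_um <- edges@pixelSizeNm / 1000
  areaUm2 <- as.numeric(r@heightPx) * r@widthPx * p_um^2
  if (areaUm2 <= 0) stop("zero-area ROI")
  perimUm <- 2 * (as.numeric(r@heightPx) + r@widthPx) * p_um
  len <- edgeLength(sub, halved = halved)
  nEdge <- sum(sub@mask)
  data.frame(
    total_edge_length_um = len,
    edge_density_um_per_um2 = len / areaUm2,
    edge_pixel_percent = 100 * nEdge / (as.numeric(r@heightPx) * r@widthPx),
    edge_to_perimeter_ratio = len / perimUm)
}

#' Characterize niches by edge metrics
#'
#' Computes the edge-metric row for each region of a micrograph under one
#' fixed Canny parameter set — the discipline required for quantitative
#' comparison across a series is enforced by the interface: a single
#' \code{params} applies to every region. Overlapping regions are allowed.
#' The output mirrors a niche-characterization table: percent edges, edge
#' length per square micrometre, edge/perimeter.
#'
#' @param img a [CalibratedImage-class].
#' @param rois list of [ROI-class] (at least one).
#' @param params a single [CannyParams-class] for all regions.
#' @param halved per-ridge length convention (see [edgeLength()]).
#' @return data.frame with one row per region (\code{roi} index column plus
#'   the [edgeMetricsForROI()] columns).
#' @export
characterizeNiches <- function(img, rois, params = cannyParams(),
                               halved = FALSE) {
  stopifnot(is(img, "CalibratedImage"), length(rois) >= 1L)
  if (is(rois, "ROI")) rois <- list(rois)
  edges <- detectEdges(img, params)
  rows <- lapply(seq_along(rois), function(i) {
    cbind(data.frame(roi = i),
          edgeMetricsForROI(edges, rois[[i]], halved = halved))
  })
  do.call(rbind, rows)
}
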