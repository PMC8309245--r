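#' @include AllClasses.R AllGenerics.R utils-internal.R calibration.R
NULL

#' Luminance-as-height surface
#'
#' Builds a normalized 3D surface proxy from luminance: optional Gaussian
#' smoothing (default sigma 1 px, suppressing shot noise before
#' normalization), then min-max normalization to \code{[0, 1]}. SEM
#' luminance carries no absolute height calibration, so z is explicitly
#' unitless — the normalized signal is presented, and no total-surface-area
#' integral over z is offered anywhere in the package. A constant image
#' maps to an all-zero height map by convention.
#'
#' The map is affine-invariant in luminance (adding a constant or applying
#' a positive scale changes nothing) and monotone: a brighter pixel (after
#' smoothing) never maps below a darker one.
#'
#' @param img a [CalibratedImage-class].
#' @param smoothingSigmaPx non-negative Gaussian sigma applied before
#'   normalization (default 1).
#' @return a [HeightMap-class].
#' @export
heightMap <- function(img, smoothingSigmaPx = 1) {
  stopifnot(is(img, "CalibratedImage"))
  if (!is.numeric(smoothingSigmaPx) || length(smoothingSigmaPx) != 1L ||
      smoothingSigmaPx < 0)
    stop("smoothingSigmaPx must be a single non-negative number")
  x <- pixels(img)
  if (smoothingSigmaPx > 0) x <- gaussBlur(x, smoothingSigmaPx)
  rng <- range(x)
  z <- if (diff(rng) == 0) matrix(0, nrow(x), ncol(x))
       else (x - rng[1]) / diff(rng)
  new("HeightMap", z = z, pixelSizeNm = pixelSizeNm(img),
      smoothingSigmaPx = smoothingSigmaPx)
}

#' Export a height map as an OBJ triangle mesh
#'
#' Writes the regular-grid surface as a Wavefront OBJ mesh for universal
#' viewer support: one vertex per pixel (x/y in micrometres, z in
#' normalized unitless height) and two triangles per grid cell, i.e.
#' \code{height_px * width_px} vertices and
#' \code{2 * (height_px - 1) * (width_px - 1)} faces.
#'
#' @param hm a [HeightMap-class] with at least 2 x 2 pixels.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportSurface <- function(hm, path) {
  stopifnot(is(hm, "HeightMap"))
  z <- hm@z
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 2L || nc < 2L) stop("height map must be at least 2 x 2")
  p_um <- hm@pixelSizeNm / 1000
  # vertices in column-major pixel order: id = (c-1)*nr + r
  rr <- rep(seq_len(nr), nc)
  cc <- rep(seq_len(nc), each = nr)
  verts <- sprintf("v %.6f %.6f %.8f", (cc - 1) * p_um, (rr - 1) * p_um,
                   as.vector(z))
  r0 <- rep(seq_len(nr - 1L), nc - 1L)
  c0 <- rep(seq_len(nc - 1L), each = nr - 1L)
  v1 <- (c0 - 1L) * nr + r0         # (r, c)
  v2 <- v1 + 1L                     # (r+1, c)
  v3 <- c0 * nr + r0                # (r, c+1)
  v4 <- v3 + 1L                     # (r+1, c+1)
  faces <- c(sprintf("f %d %d %d", v1, v2, v3),
             sprintf("f %d %d %d", v2, v4, v3))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# normalized luminance-as-height surface (z unitless)",
               verts, faces), con)
  invisible(path)
}

#' Read the vertex grid back from an exported OBJ surface
#'
#' Convenience inverse of [exportSurface()] for round-trip checks: parses
#' the vertex lines and restores the z grid.
#'
#' @param path an OBJ file written by [exportSurface()].
#' @param dim integer c(height_px, width_px) of the original map.
#' @return numeric matrix of z values.
#' @export
readSurfaceZ <- function(path, dim) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  z <- vapply(strsplit(vl, " ", fixed = TRUE),
              function(f) as.numeric(f[4]), numeric(1))
  matrix(z, dim[1], dim[2])
}
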