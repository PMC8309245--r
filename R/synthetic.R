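#' @include AllClasses.R AllGenerics.R utils-internal.R calibration.R
NULL

# ---- rasterization primitives (hard edges: pixel centre inside the shape;
# no anti-aliasing, so pixel-count oracles stay exact) ----

# Stamp a filled disk (centre in 1-based pixel coordinates, radius in px).
drawDisk <- function(m, r0, c0, radiusPx, value) {
  nr <- nrow(m); nc <- ncol(m)
  rlo <- max(1, floor(r0 - radiusPx)); rhi <- min(nr, ceiling(r0 + radiusPx))
  clo <- max(1, floor(c0 - radiusPx)); chi <- min(nc, ceiling(c0 + radiusPx))
  if (rlo > rhi || clo > chi) return(m)   # disk entirely outside the field
  rs <- rlo:rhi; cs <- clo:chi
  d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
  sel <- d2 <= radiusPx^2
  m[rs, cs][sel] <- value
  m
}

# Stamp a thick line segment: pixels within widthPx/2 of the segment.
drawSegment <- function(m, r0, c0, r1, c1, widthPx, value) {
  nr <- nrow(m); nc <- ncol(m)
  h <- widthPx / 2
  rs <- max(1L, floor(min(r0, r1) - h)):min(nr, ceiling(max(r0, r1) + h))
  cs <- max(1L, floor(min(c0, c1) - h)):min(nc, ceiling(max(c0, c1) + h))
  if (!length(rs) || !length(cs)) return(m)
  dr <- r1 - r0; dc <- c1 - c0
  len2 <- dr * dr + dc * dc
  pr <- matrix(rs, length(rs), length(cs))
  pc <- matrix(cs, length(rs), length(cs), byrow = TRUE)
  t <- if (len2 > 0) pmin(pmax(((pr - r0) * dr + (pc - c0) * dc) / len2, 0), 1)
       else 0
  d2 <- (pr - (r0 + t * dr))^2 + (pc - (c0 + t * dc))^2
  m[rs, cs][d2 <= h^2] <- value
  m
}

# Stamp an infinite stripe through (r0, c0) with direction angle theta
# (radians, measured from the column axis) and full width widthPx.
drawStripe <- function(m, r0, c0, theta, widthPx, value) {
  nr <- nrow(m); nc <- ncol(m)
  pr <- matrix(seq_len(nr), nr, nc)
  pc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # signed distance to the stripe axis
  d <- abs((pc - c0) * sin(theta) - (pr - r0) * cos(theta))
  m[d <= widthPx / 2] <- value
  m
}

#' Add detector-style noise
#'
#' Additive zero-mean Gaussian noise, optionally followed by
#' signal-dependent shot noise (standard deviation scaling with the square
#' root of the normalized signal), then rounding and clamping to
#' \code{[0, 255]}. With \code{gaussianSigma = 0} and \code{shot = FALSE}
#' the image is returned bit-identical.
#'
#' @param img a [CalibratedImage-class] or a bare luminance matrix.
#' @param gaussianSigma Gaussian noise standard deviation in luminance
#'   levels.
#' @param shot add signal-dependent noise.
#' @param seed integer seed (a private RNG stream; global RNG state is
#'   untouched).
#' @return same type as \code{img}.
#' @export
addSemNoise <- function(img, gaussianSigma = 8, shot = FALSE, seed = 1L) {
  isImg <- is(img, "CalibratedImage")
  px <- if (isImg) pixels(img) else img
  if (gaussianSigma > 0 || shot) {
    px <- withSeed(seed, {
      out <- px
      if (gaussianSigma > 0)
        out <- out + stats::rnorm(length(out), 0, gaussianSigma)
      if (shot)
        out <- out + sqrt(pmax(px, 0) / 255) *
          stats::rnorm(length(out), 0, gaussianSigma)
      out
    })
    px <- round(clamp255(px))
  }
  if (isImg) calibratedImage(px, pixelSizeNm(img)) else px
}

makeSynth <- function(px, pixelSizeNm, truth, seed, noiseSigma, shot = FALSE) {
  new("SyntheticMicrograph",
      image = calibratedImage(px, pixelSizeNm), truth = truth,
      seed = as.integer(seed), noiseSigma = noiseSigma, shotNoise = shot)
}

#' Synthetic crack field
#'
#' Dark polyline cracks of known total centreline length on a mid-grey
#' background — the fixture for weathered-surface edge metrics. Segment
#' lengths are drawn as random proportions of the requested total; each
#' segment's exact analytic endpoints and length are recorded, so the
#' ground-truth lengths sum to \code{totalLengthUm} exactly (up to the last
#' segment being clipped only by resampling, never by drawing).
#'
#' @param totalLengthUm requested total centreline length (um); 0 gives a
#'   blank field.
#' @param nSegments number of straight segments.
#' @param sizePx field edge length in pixels.
#' @param pixelSizeNm calibration (default 100 nm/px, i.e. a 51.2 um field
#'   at the default size).
#' @param seed integer seed.
#' @param crackWidthPx drawn crack thickness in pixels.
#' @param bg,fg background and crack luminance.
#' @param noiseSigma Gaussian noise level (default 8; the default contrast
#'   of 120 levels then gives SNR 15).
#' @return a [SyntheticMicrograph-class]; \code{truth} has one
#'   \code{crack_segment} row per segment with exact endpoints (px) and
#'   \code{length_um}.
#' @export
genCrackField <- function(totalLengthUm, nSegments = 10L, sizePx = 512L,
                          pixelSizeNm = 100, seed = 1L, crackWidthPx = 3,
                          bg = 160, fg = 40, noiseSigma = 8) {
  p_um <- pixelSizeNm / 1000
  px <- matrix(bg, sizePx, sizePx)
  truth <- data.frame(kind = character(0), r0 = numeric(0), c0 = numeric(0),
                      r1 = numeric(0), c1 = numeric(0),
                      length_um = numeric(0))
  if (totalLengthUm > 0 && nSegments > 0) {
    fieldUm <- sizePx * p_um
    maxSegUm <- 0.8 * fieldUm
    if (totalLengthUm / nSegments > maxSegUm)
      stop("requested total length is infeasible for this field size")
    res <- withSeed(seed, {
      w <- stats::runif(nSegments, 0.5, 1.5)
      lensUm <- totalLengthUm * w / sum(w)
      lensUm <- pmin(lensUm, maxSegUm)    # feasibility guard
      segs <- matrix(NA_real_, nSegments, 4)
      for (i in seq_len(nSegments)) {
        lenPx <- lensUm[i] / p_um
        repeat {
          theta <- stats::runif(1, 0, pi)
          r0 <- stats::runif(1, 2, sizePx - 1)
          c0 <- stats::runif(1, 2, sizePx - 1)
          r1 <- r0 + lenPx * sin(theta)
          c1 <- c0 + lenPx * cos(theta) * sample(c(-1, 1), 1)
          if (r1 >= 2 && r1 <= sizePx - 1 && c1 >= 2 && c1 <= sizePx - 1)
            break
        }
        segs[i, ] <- c(r0, c0, r1, c1)
      }
      list(segs = segs, lensUm = lensUm)
    })
    for (i in seq_len(nSegments))
      px <- drawSegment(px, res$segs[i, 1], res$segs[i, 2], res$segs[i, 3],
                        res$segs[i, 4], crackWidthPx, fg)
    truth <- data.frame(kind = "crack_segment",
                        r0 = res$segs[, 1], c0 = res$segs[, 2],
                        r1 = res$segs[, 3], c1 = res$segs[, 4],
                        length_um = res$lensUm)
  }
  px <- addSemNoise(px, noiseSigma, seed = seed + 1L)
  makeSynth(px, pixelSizeNm, truth, seed, noiseSigma)
}

#' Synthetic perforation field
#'
#' Disjoint dark disks ("pores") on a bright surround, rejection-sampled
#' with at least 2 px of clearance between disks and from the border, so
#' exact-count recovery is well-posed. The total pore area must stay below
#' half the field (precondition, not best effort).
#'
#' @param nPores number of pores; 0 gives a blank field.
#' @param poreAreaUm2 analytic area of each pore (um^2).
#' @param fieldAreaUm2 physical field area (um^2); with \code{sizePx} it
#'   determines the pixel size when \code{pixelSizeNm} is NULL.
#' @param sizePx field edge length in pixels.
#' @param pixelSizeNm explicit calibration (overrides the one derived from
#'   \code{fieldAreaUm2}).
#' @param seed integer seed.
#' @param bg,fg surround and pore luminance.
#' @param noiseSigma Gaussian noise level.
#' @return a [SyntheticMicrograph-class]; \code{truth} has one \code{pore}
#'   row per disk with centre (px), \code{radius_px} and analytic
#'   \code{area_um2}.
#' @export
genPoreField <- function(nPores, poreAreaUm2, fieldAreaUm2 = NULL,
                         sizePx = 256L, pixelSizeNm = NULL, seed = 1L,
                         bg = 180, fg = 60, noiseSigma = 8) {
  if (is.null(pixelSizeNm)) {
    if (is.null(fieldAreaUm2))
      stop("supply fieldAreaUm2 or pixelSizeNm")
    pixelSizeNm <- sqrt(fieldAreaUm2) / sizePx * 1000
  }
  p_um <- pixelSizeNm / 1000
  if (nPores > 0 && nPores * poreAreaUm2 >= 0.5 * (sizePx * p_um)^2)
    stop("total pore area must stay below 50% of the field")
  px <- matrix(bg, sizePx, sizePx)
  truth <- data.frame(kind = character(0), row = numeric(0),
                      col = numeric(0), radius_px = numeric(0),
                      area_um2 = numeric(0))
  if (nPores > 0) {
    rPx <- sqrt(poreAreaUm2 / pi) / p_um
    centres <- withSeed(seed, {
      acc <- matrix(NA_real_, 0, 2)
      tries <- 0L
      while (nrow(acc) < nPores) {
        tries <- tries + 1L
        if (tries > 20000L)
          stop("could not place disjoint pores; reduce nPores or area")
        r0 <- stats::runif(1, rPx + 3, sizePx - rPx - 2)
        c0 <- stats::runif(1, rPx + 3, sizePx - rPx - 2)
        if (!nrow(acc) ||
            all((acc[, 1] - r0)^2 + (acc[, 2] - c0)^2 >= (2 * rPx + 2.5)^2))
          acc <- rbind(acc, c(r0, c0))
      }
      acc
    })
    for (i in seq_len(nPores))
      px <- drawDisk(px, centres[i, 1], centres[i, 2], rPx, fg)
    truth <- data.frame(kind = "pore", row = centres[, 1],
                        col = centres[, 2], radius_px = rPx,
                        area_um2 = poreAreaUm2)
  }
  px <- addSemNoise(px, noiseSigma, seed = seed + 1L)
  makeSynth(px, pixelSizeNm, truth, seed, noiseSigma)
}

#' Synthetic fibre mesh
#'
#' Bright fibres on a dark background, emulating glass-fibre filter
#' imagery. Two layouts: randomly oriented full-field stripes with widths
#' cycled from \code{widthsUm} (the default, a loose mesh), or — when
#' \code{spacingUm} is given — parallel fibres with a fixed edge-to-edge
#' gap, the layout used to validate inter-fibre spacing recovery.
#'
#' @param nFibres number of fibres; 0 gives a blank (noise-only) field.
#' @param widthsUm fibre widths in micrometres, recycled across fibres
#'   (e.g. \code{c(9.5, 5)} for a two-fraction filter).
#' @param sizePx field edge length in pixels.
#' @param pixelSizeNm calibration (default 100 nm/px).
#' @param seed integer seed.
#' @param spacingUm if non-NULL, lay fibres parallel (vertical) with this
#'   edge-to-edge gap; an infeasible packing is drawn best-effort and
#'   flagged with a warning.
#' @param bg,fg background and fibre luminance.
#' @param noiseSigma Gaussian noise level.
#' @return a [SyntheticMicrograph-class]; \code{truth} has one
#'   \code{fibre} row per fibre with \code{width_um}, orientation
#'   \code{theta} and an axis point (px).
#' @export
genFibreMesh <- function(nFibres, widthsUm = c(9.5, 5), sizePx = 768L,
                         pixelSizeNm = 100, seed = 1L, spacingUm = NULL,
                         bg = 50, fg = 200, noiseSigma = 8) {
  stopifnot(all(widthsUm > 0), is.null(spacingUm) || spacingUm > 0)
  p_um <- pixelSizeNm / 1000
  px <- matrix(bg, sizePx, sizePx)
  truth <- data.frame(kind = character(0), width_um = numeric(0),
                      theta = numeric(0), axis_row = numeric(0),
                      axis_col = numeric(0))
  if (nFibres > 0) {
    widths <- rep_len(widthsUm, nFibres)
    if (!is.null(spacingUm)) {
      wPx <- widths / p_um
      gapPx <- spacingUm / p_um
      pitch <- c(0, cumsum(wPx[-nFibres] / 2 + gapPx + wPx[-1] / 2))
      start <- (sizePx - (pitch[nFibres] + wPx[1] / 2 + wPx[nFibres] / 2)) / 2
      if (start < 1) {
        warning("spacing/width infeasible for field; fibres clipped")
        start <- max(1, start)
      }
      cols <- start + wPx[1] / 2 + pitch
      for (i in seq_len(nFibres))
        px <- drawStripe(px, 1, cols[i], pi / 2, wPx[i], fg)
      truth <- data.frame(kind = "fibre", width_um = widths,
                          theta = pi / 2, axis_row = NA_real_,
                          axis_col = cols)
    } else {
      geo <- withSeed(seed, {
        data.frame(theta = stats::runif(nFibres, 0, pi),
                   r0 = stats::runif(nFibres, 0.1, 0.9) * sizePx,
                   c0 = stats::runif(nFibres, 0.1, 0.9) * sizePx)
      })
      for (i in seq_len(nFibres))
        px <- drawStripe(px, geo$r0[i], geo$c0[i], geo$theta[i],
                         widths[i] / p_um, fg)
      truth <- data.frame(kind = "fibre", width_um = widths,
                          theta = geo$theta, axis_row = geo$r0,
                          axis_col = geo$c0)
    }
  }
  px <- addSemNoise(px, noiseSigma, seed = seed + 1L)
  makeSynth(px, pixelSizeNm, truth, seed, noiseSigma)
}

#' Synthetic periodic texture
#'
#' An axis-aligned lattice of identical bumps with known periods and a
#' random phase — the fixture for texture-unit recovery. Bumps are hard
#' disks (default) for crisp template comparison, or Gaussian blobs.
#'
#' @param periodPx integer pair \code{c(rows, cols)} of lattice periods.
#' @param bumpShape \code{"disk"} or \code{"gauss"}.
#' @param sizePx field edge length in pixels.
#' @param pixelSizeNm calibration.
#' @param seed integer seed (drives the phase and the noise).
#' @param bumpDiameterPx bump diameter (default: half the smaller period).
#' @param bg,amplitude background level and bump height above it.
#' @param noiseSigma Gaussian noise level (0 = noiseless).
#' @return a [SyntheticMicrograph-class]; \code{truth} has one
#'   \code{texture_bump} summary row with the periods and phase.
#' @export
genTexture <- function(periodPx = c(20L, 17L), bumpShape = c("disk", "gauss"),
                       sizePx = 256L, pixelSizeNm = 100, seed = 1L,
                       bumpDiameterPx = NULL, bg = 60, amplitude = 120,
                       noiseSigma = 0) {
  bumpShape <- match.arg(bumpShape)
  pr <- as.integer(periodPx[1]); pc <- as.integer(periodPx[2])
  stopifnot(pr >= 2L, pc >= 2L)
  if (is.null(bumpDiameterPx)) bumpDiameterPx <- floor(min(pr, pc) / 2)
  phase <- withSeed(seed, c(stats::runif(1, 0, pr), stats::runif(1, 0, pc)))
  px <- matrix(bg, sizePx, sizePx)
  rad <- bumpDiameterPx / 2
  # start one period before the phase so bumps that straddle the field
  # margin are drawn too (tiles must be identical everywhere)
  centresR <- seq(phase[1] - pr, sizePx + pr, by = pr)
  centresC <- seq(phase[2] - pc, sizePx + pc, by = pc)
  if (bumpShape == "disk") {
    for (r0 in centresR) for (c0 in centresC)
      px <- drawDisk(px, r0, c0, rad, bg + amplitude)
  } else {
    pm <- matrix(seq_len(sizePx), sizePx, sizePx)
    cm <- t(pm)
    s <- rad / 1.5
    for (r0 in centresR) for (c0 in centresC) {
      px <- px + amplitude * exp(-((pm - r0)^2 + (cm - c0)^2) / (2 * s^2))
    }
    px <- clamp255(px)
  }
  truth <- data.frame(kind = "texture_bump", period_rows_px = pr,
                      period_cols_px = pc, phase_row = phase[1],
                      phase_col = phase[2],
                      bump_diameter_px = bumpDiameterPx)
  px <- addSemNoise(px, noiseSigma, seed = seed + 1L)
  makeSynth(px, pixelSizeNm, truth, seed, noiseSigma)
}

#' Synthetic spherical particles
#'
#' Disjoint bright disks — the 2D projections of spheres (nurdles,
#' microspheres) — with radii drawn uniformly from \code{radiusUmRange}.
#' Ground truth records each sphere's exact radius, analytic projected
#' area and closed-form volume.
#'
#' @param n number of spheres.
#' @param radiusUmRange length-2 range of radii (um); a single value fixes
#'   the radius.
#' @param sizePx field edge length in pixels.
#' @param pixelSizeNm calibration (default 100 nm/px).
#' @param seed integer seed.
#' @param bg,fg background and sphere luminance.
#' @param noiseSigma Gaussian noise level.
#' @return a [SyntheticMicrograph-class]; \code{truth} has one
#'   \code{disk} row per sphere with centre (px), \code{radius_um},
#'   \code{area_um2} and \code{volume_um3}.
#' @export
genSpheres <- function(n, radiusUmRange = c(2, 10), sizePx = 1536L,
                       pixelSizeNm = 100, seed = 1L, bg = 40, fg = 210,
                       noiseSigma = 8) {
  p_um <- pixelSizeNm / 1000
  if (length(radiusUmRange) == 1L) radiusUmRange <- rep(radiusUmRange, 2)
  px <- matrix(bg, sizePx, sizePx)
  truth <- data.frame(kind = character(0), row = numeric(0),
                      col = numeric(0), radius_um = numeric(0),
                      area_um2 = numeric(0), volume_um3 = numeric(0))
  if (n > 0) {
    placed <- withSeed(seed, {
      acc <- matrix(NA_real_, 0, 3)   # row, col, radius_px
      tries <- 0L
      while (nrow(acc) < n) {
        tries <- tries + 1L
        if (tries > 50000L)
          stop("could not place disjoint spheres; enlarge field or reduce n")
        rUm <- stats::runif(1, radiusUmRange[1], radiusUmRange[2])
        rPx <- rUm / p_um
        r0 <- stats::runif(1, rPx + 3, sizePx - rPx - 2)
        c0 <- stats::runif(1, rPx + 3, sizePx - rPx - 2)
        if (!nrow(acc) ||
            all(sqrt((acc[, 1] - r0)^2 + (acc[, 2] - c0)^2) >=
                acc[, 3] + rPx + 2.5))
          acc <- rbind(acc, c(r0, c0, rPx))
      }
      acc
    })
    for (i in seq_len(n))
      px <- drawDisk(px, placed[i, 1], placed[i, 2], placed[i, 3], fg)
    rUm <- placed[, 3] * p_um
    truth <- data.frame(kind = "disk", row = placed[, 1],
                        col = placed[, 2], radius_um = rUm,
                        area_um2 = pi * rUm^2,
                        volume_um3 = sphereVolumeUm3(rUm))
  }
  px <- addSemNoise(px, noiseSigma, seed = seed + 1L)
  makeSynth(px, pixelSizeNm, truth, seed, noiseSigma)
}
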