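#' @include AllClasses.R
NULL

# Shift a matrix by (dr, dc), zero-padding the vacated border.
shiftMat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

clamp255 <- function(m) pmin(pmax(m, 0), 255)

# Run expr with a private RNG stream: the caller's .Random.seed is untouched.
withSeed <- function(seed, expr) {
  ge <- globalenv()
  had <- exists(".Random.seed", envir = ge, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = ge) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = ge)
    else if (exists(".Random.seed", envir = ge, inherits = FALSE))
      rm(".Random.seed", envir = ge)
  })
  set.seed(as.integer(seed))
  expr
}

# 8-connected labelling. EBImage::bwlabel is 4-connected, so label with it
# and then merge label pairs that touch only diagonally (union-find on the
# small label-equivalence graph).
label8 <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  n <- as.integer(max(lab))
  if (n <= 1L) return(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs: down-right and down-left
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- matrix(0L, nr, nc)
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  out
}

# Drop labelled components outside [minAreaPx, maxAreaPx] and relabel 1..k
# in raster order of first occurrence.
filterLabelsBySize <- function(lab, minAreaPx = 0L, maxAreaPx = Inf) {
  n <- max(lab)
  if (n == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(sizes >= minAreaPx & sizes <= maxAreaPx)
  remap <- integer(n)
  if (length(keep)) {
    # relabel in raster order of first appearance
    idx <- which(lab %in% keep)
    ord <- unique(lab[idx][order(idx)])
    remap[ord] <- seq_along(ord)
  }
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0L
  out[nz] <- remap[lab[nz]]
  out
}

# Zhang-Suen morphological thinning of a binary mask to 1-px-wide,
# 8-connected chains. Vectorized over whole-matrix neighbour shifts.
thinMask <- function(mask) {
  m <- mask != 0
  storage.mode(m) <- "logical"
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- shiftMat(m, -1,  0); p3 <- shiftMat(m, -1,  1)
      p4 <- shiftMat(m,  0,  1); p5 <- shiftMat(m,  1,  1)
      p6 <- shiftMat(m,  1,  0); p7 <- shiftMat(m,  1, -1)
      p8 <- shiftMat(m,  0, -1); p9 <- shiftMat(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (pass == 1L) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  sequentialSimpleThin(m)
}

# Sequential deletion of 8-simple pixels (Yokoi connectivity number == 1,
# degree >= 2 so endpoints survive). Zhang-Suen cannot thin 2-px diagonal
# staircase bands (both pixels have crossing number 2); sequential
# simple-point removal reduces them to single diagonal chains without
# breaking connectivity or eating junctions/loops.
sequentialSimpleThin <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) return(m)
  # neighbour offsets n1..n8 anticlockwise from east, in linear indexing
  off <- c(nr, nr - 1L, -1L, -nr - 1L, -nr, -nr + 1L, 1L, nr + 1L)
  repeat {
    idx <- which(m)
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    interior <- rows > 1L & rows < nr & cols > 1L & cols < nc
    idx <- idx[interior]
    changed <- FALSE
    for (i in idx) {
      x <- m[i + off]
      b <- sum(x)
      if (b < 2L || b > 6L) next
      xb <- !x
      # Yokoi 8-connectivity number over k = 1, 3, 5, 7
      c8 <- sum(vapply(c(1L, 3L, 5L, 7L), function(k) {
        k2 <- k + 1L
        k3 <- if (k == 7L) 1L else k + 2L   # indices wrap mod 8
        xb[k] - xb[k] * xb[k2] * xb[k3]
      }, numeric(1)))
      if (c8 == 1) { m[i] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Otsu threshold on the 0..255 integer luminance scale.
otsuThreshold <- function(px) {
  as.numeric(EBImage::otsu(EBImage::Image(px / 255), range = c(0, 1),
                           levels = 256)) * 255
}

# Resolve a threshold spec ("otsu" or a numeric level) to a numeric level.
resolveThreshold <- function(threshold, px) {
  if (is.character(threshold)) {
    threshold <- match.arg(threshold, "otsu")
    otsuThreshold(px)
  } else {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        threshold < 0 || threshold > 255)
      stop("numeric threshold must lie in [0, 255]")
    threshold
  }
}

# EBImage distmap on a binary matrix (Euclidean distance to background).
distanceMap <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  as.matrix(EBImage::distmap(m, metric = "euclidean"))
}

gaussBlur <- function(px, sigma) {
  if (sigma <= 0) return(px)
  # gblur's brush must fit inside the image; shrink its support for small
  # inputs (gblur's `radius` argument is the odd brush size)
  half <- min(ceiling(3 * sigma), floor((min(dim(px)) - 1) / 2))
  if (half < 1) return(px)
  # replicate boundary: circular wrap-around would fabricate border
  # gradients between opposite image edges
  as.matrix(EBImage::gblur(px, sigma = sigma, radius = 2L * half + 1L,
                           boundary = "replicate"))
}
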