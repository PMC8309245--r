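# Shared fixture helpers: everything is generated in code, no stored images.

mkImg <- function(px, pixelSizeNm = 100) calibratedImage(px, pixelSizeNm)

# A bare EdgeMap around a logical mask (already-thinned chains in tests).
mkEdgeMap <- function(mask, pixelSizeNm = 10, skeletonized = TRUE) {
  new("EdgeMap", mask = mask, pixelSizeNm = pixelSizeNm,
      skeletonized = skeletonized)
}

# Draw helpers re-exported from the package internals for fixture building.
drawDisk <- plastimorph:::drawDisk
drawSegment <- plastimorph:::drawSegment

# Independent discrete-Gaussian convolution oracle (direct tabulation; no
# shared code with the package's blur path beyond base R).
gaussOracleCentre <- function(sigma, half = 15L) {
  k <- outer(-half:half, -half:half,
             function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)))
  k <- k / sum(k)
  k[half + 1L, half + 1L]
}
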