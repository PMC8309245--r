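test_that("constant image yields an empty edge map, not an error", {
  em <- detectEdges(mkImg(matrix(128, 32, 32), 10))
  expect_false(any(edgeMask(em)))
  expect_equal(edgeLength(em), 0)
})

test_that("a luminance step yields one 1-px vertical chain at the step", {
  px <- matrix(0, 64, 64); px[, 33:64] <- 255
  em <- detectEdges(mkImg(px, 10))
  hits <- which(edgeMask(em), arr.ind = TRUE)
  expect_length(unique(hits[, 2]), 1L)          # single column
  expect_gte(nrow(hits), 60)                    # ~64 minus excluded border
  expect_true(unique(hits[, 2]) %in% 31:34)     # at the step
})

test_that("chain-code length is exact on straight and diagonal chains", {
  m <- matrix(FALSE, 7, 110); m[4, 5:105] <- TRUE        # 101 px, 100 steps
  expect_equal(edgeLength(mkEdgeMap(m, 10)), 1.0)
  md <- matrix(FALSE, 110, 110)
  md[cbind(5:105, 5:105)] <- TRUE                        # 100 diagonal steps
  expect_equal(edgeLength(mkEdgeMap(md, 10)), sqrt(2) * 1.0)
  expect_equal(edgeLength(mkEdgeMap(md, 10), halved = TRUE),
               sqrt(2) / 2)
})

test_that("edge detection is deterministic for fixed input and params", {
  syn <- genCrackField(60, 3, 256, 100, seed = 5)
  e1 <- detectEdges(synthImage(syn))
  e2 <- detectEdges(synthImage(syn))
  expect_identical(edgeMask(e1), edgeMask(e2))
})

test_that("edge length is rotation-robust within 10%", {
  sz <- 181L
  horiz <- drawSegment(matrix(160, sz, sz), 91, 21, 91, 161, 3, 40)
  diag45 <- drawSegment(matrix(160, sz, sz), 31, 31, 31 + 99, 31 + 99, 3, 40)
  lenH <- edgeLength(detectEdges(mkImg(horiz, 100)))
  lenD <- edgeLength(detectEdges(mkImg(diag45, 100)))
  # same centreline length (140 px vs 99*sqrt(2) = 140 px)
  expect_lt(abs(lenD - lenH) / lenH, 0.1)
})

test_that("crack-field ground truth is recovered by the two-sided halved convention", {
  # scaled-down version of the full acceptance sweep
  for (s in c(3, 8)) {
    L <- 60 + 20 * s
    syn <- genCrackField(L, max(3, round(L / 20)), 512, 100, seed = s)
    Lt <- sum(groundTruth(syn)$length_um)
    det <- edgeLength(detectEdges(synthImage(syn)), halved = TRUE)
    expect_lt(abs(det - Lt) / Lt, 0.1)
  }
})

test_that("ROI edge metrics satisfy their defining identities", {
  syn <- genCrackField(80, 4, 384, 100, seed = 2)
  em <- detectEdges(synthImage(syn))
  r <- roi(40, 40, 300, 300)
  met <- edgeMetricsForROI(em, r)
  areaUm2 <- 300 * 300 * 0.1^2 / 1  # 0.1 um/px
  expect_equal(met$edge_density_um_per_um2,
               met$total_edge_length_um / areaUm2)
  perim <- 2 * (300 + 300) * 0.1
  expect_equal(met$edge_to_perimeter_ratio,
               met$total_edge_length_um / perim)
  expect_gte(met$edge_pixel_percent, 0)
  expect_lte(met$edge_pixel_percent, 100)
  # edge-free region reports a zero row
  blank <- detectEdges(mkImg(matrix(70, 64, 64), 100))
  met0 <- edgeMetricsForROI(blank)
  expect_equal(unname(unlist(met0)), c(0, 0, 0, 0))
  expect_error(edgeMetricsForROI(em, roi(0, 0, 500, 500)), "exceeds")
})

test_that("niche characterization resolves a 2x crack-density contrast", {
  a <- genCrackField(60, 3, 512, 100, seed = 21)
  b <- genCrackField(120, 6, 512, 100, seed = 22)
  px <- cbind(pixels(synthImage(a)), pixels(synthImage(b)))
  img <- mkImg(px, 100)
  tab <- characterizeNiches(img, list(roi(0, 0, 512, 512),
                                      roi(0, 512, 512, 512)))
  expect_equal(nrow(tab), 2L)
  ratio <- tab$edge_density_um_per_um2[2] / tab$edge_density_um_per_um2[1]
  expect_lt(abs(ratio - 2), 0.1 * 2)   # within 10% of the 2x contrast
  # blank zone gives a zero row
  px2 <- cbind(pixels(synthImage(a)), matrix(160, 512, 512))
  tab2 <- characterizeNiches(mkImg(px2, 100),
                             list(roi(10, 522, 400, 400)))
  expect_equal(tab2$total_edge_length_um, 0)
})

test_that("thinning is idempotent and leaves 1-px chains", {
  syn <- genCrackField(60, 3, 256, 100, seed = 9)
  th <- thinEdges(detectEdges(synthImage(syn)))
  expect_true(th@skeletonized)
  expect_identical(edgeMask(thinEdges(th)), edgeMask(th))
})
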