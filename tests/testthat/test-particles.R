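test_that("segmentation counts disjoint objects and merges touching ones", {
  expect_equal(nObjects(segmentParticles(mkImg(matrix(20, 64, 64), 100),
                                         threshold = 128)), 0L)
  px <- matrix(20, 128, 128)
  px <- drawDisk(px, 30, 30, 10, 220)
  px <- drawDisk(px, 30, 90, 8, 220)
  px <- drawDisk(px, 95, 60, 12, 220)
  expect_equal(nObjects(segmentParticles(mkImg(px, 100))), 3L)
  # overlapping disks form one 8-connected component (no watershed split)
  ov <- drawDisk(drawDisk(matrix(20, 64, 64), 32, 26, 10, 220),
                 32, 40, 10, 220)
  expect_equal(nObjects(segmentParticles(mkImg(ov, 100))), 1L)
  # diagonal contact still merges (8-connectivity)
  dg <- matrix(0, 16, 16); dg[4:7, 4:7] <- 255; dg[8:11, 8:11] <- 255
  expect_equal(nObjects(segmentParticles(mkImg(dg, 100), threshold = 128,
                                         minAreaPx = 1)), 1L)
  expect_error(segmentParticles(mkImg(px, 100), threshold = 300), "0, 255")
})

test_that("particle geometry matches analytic circle area and sphere volume", {
  px <- drawDisk(matrix(10, 128, 128), 64, 64, 50, 240)
  st <- particleStats(segmentParticles(mkImg(px, 100)),
                      assumeSpherical = TRUE)
  expect_equal(nrow(st), 1L)
  # pixel-count area vs analytic pi * (5 um)^2 within 2%
  expect_lt(abs(st$area_um2 - pi * 25) / (pi * 25), 0.02)
  expect_equal(st$equivalent_diameter_um, 2 * sqrt(st$area_um2 / pi))
  expect_equal(st$volume_um3,
               (4 / 3) * pi * (st$equivalent_diameter_um / 2)^3)
  expect_equal(sphereVolumeUm3(10), (4 / 3) * pi * 1000)
})

test_that("area is conserved across labelled components", {
  syn <- genSpheres(12, c(2, 8), 768, 100, seed = 4)
  mask <- segmentParticles(synthImage(syn))
  st <- particleStats(mask)
  expect_equal(sum(st$area_px), sum(labelMatrix(mask) > 0))
})

test_that("border-touching particles are flagged and censored from the distribution", {
  px <- matrix(10, 96, 96)
  px <- drawDisk(px, 48, 48, 15, 240)     # interior
  px <- drawDisk(px, 3, 48, 10, 240)      # clipped at top border
  st <- particleStats(segmentParticles(mkImg(px, 100)))
  expect_equal(sum(st$touches_border), 1L)
  gsd <- grainSizeDistribution(st, 1)
  expect_equal(sum(gsd@counts), 1L)       # border particle excluded
  gsdAll <- grainSizeDistribution(st, 1, includeBorder = TRUE)
  expect_equal(sum(gsdAll@counts), 2L)
})

test_that("grain-size distribution bins equivalent diameters from zero", {
  empty <- grainSizeDistribution(particleStats(
    segmentParticles(mkImg(matrix(0, 32, 32), 100), threshold = 128)), 1)
  expect_equal(sum(empty@counts), 0L)
  rec <- data.frame(equivalent_diameter_um = c(rep(5.3, 20), rep(9.4, 10)),
                    touches_border = FALSE)
  gsd <- grainSizeDistribution(rec, 1)
  expect_equal(gsd@counts[6], 20L)        # bin [5, 6)
  expect_equal(gsd@counts[10], 10L)       # bin [9, 10)
  expect_equal(sum(gsd@counts), 30L)
  expect_error(grainSizeDistribution(rec, 0), "positive")
})

test_that("synthetic disk diameters are recovered within 5% on average", {
  syn <- genSpheres(25, c(2, 10), 1024, 100, seed = 17)
  st <- particleStats(segmentParticles(synthImage(syn)))
  expect_equal(nrow(st), 25L)
  truth <- sort(2 * groundTruth(syn)$radius_um)
  est <- sort(st$equivalent_diameter_um)
  expect_lt(mean(abs(est - truth) / truth), 0.05)
})
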