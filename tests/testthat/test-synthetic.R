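test_that("generation is bit-identical under a fixed seed and leaves global RNG alone", {
  a <- genCrackField(60, 4, 256, 100, seed = 7)
  b <- genCrackField(60, 4, 256, 100, seed = 7)
  expect_identical(pixels(synthImage(a)), pixels(synthImage(b)))
  expect_identical(groundTruth(a), groundTruth(b))
  expect_false(identical(pixels(synthImage(a)),
                         pixels(synthImage(genCrackField(60, 4, 256, 100,
                                                         seed = 8)))))
  # the generator must not disturb the caller's RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(genPoreField(5, 0.05, 36, 128, seed = 1))
  expect_identical(runif(3), before)
})

test_that("analytic and rasterized geometry agree within 2% for features >= 10 px", {
  syn <- genSpheres(8, c(1.5, 6), 640, 100, seed = 2, noiseSigma = 0)
  tr <- groundTruth(syn)
  lab <- labelMatrix(segmentParticles(synthImage(syn), threshold = 128,
                                      minAreaPx = 1))
  pxArea <- tabulate(lab[lab > 0]) * 0.1^2
  expect_equal(length(pxArea), 8L)
  relerr <- abs(sort(pxArea) - sort(tr$area_um2)) / sort(tr$area_um2)
  expect_true(all(relerr <= 0.02))
})

test_that("crack ground-truth lengths sum to the requested total", {
  syn <- genCrackField(100, 7, 512, 100, seed = 3)
  tr <- groundTruth(syn)
  expect_equal(sum(tr$length_um), 100, tolerance = 1e-9)
  # stored endpoints reproduce the stored lengths
  geo <- sqrt((tr$r1 - tr$r0)^2 + (tr$c1 - tr$c0)^2) * 0.1
  expect_equal(geo, tr$length_um, tolerance = 1e-9)
  blank <- genCrackField(0, 0, 128, 100, seed = 1)
  expect_equal(nrow(groundTruth(blank)), 0L)
})

test_that("noise model contracts hold", {
  px <- matrix(sample(0:255, 4096, TRUE), 64, 64)
  expect_identical(addSemNoise(px, 0, shot = FALSE, seed = 1), px)
  noisy <- addSemNoise(px, 8, seed = 1)
  expect_true(all(noisy >= 0 & noisy <= 255))
  expect_identical(noisy, addSemNoise(px, 8, seed = 1))
  shotty <- addSemNoise(px, 8, shot = TRUE, seed = 1)
  expect_false(identical(shotty, noisy))
})

test_that("infeasible pore packings are rejected before drawing", {
  expect_error(genPoreField(100, 1, fieldAreaUm2 = 100, sizePx = 128,
                            seed = 1), "50%")
  blank <- genPoreField(0, 0.05, fieldAreaUm2 = 36, sizePx = 128, seed = 1)
  expect_equal(nrow(groundTruth(blank)), 0L)
})

test_that("fibre mesh records one truth row per fibre and honours widths", {
  syn <- genFibreMesh(6, c(9.5, 5), 512, 100, seed = 11)
  tr <- groundTruth(syn)
  expect_equal(nrow(tr), 6L)
  expect_equal(sort(unique(tr$width_um)), c(5, 9.5))
  blank <- genFibreMesh(0, c(5), 128, 100, seed = 1)
  expect_equal(nrow(groundTruth(blank)), 0L)
})
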