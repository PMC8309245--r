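test_that("histogram of a constant region is a single bin with zero spread", {
  prof <- luminanceHistogram(mkImg(matrix(128, 100, 100), 10))
  expect_equal(prof@counts[129], 10000L)
  expect_equal(sum(prof@counts), 10000L)
  st <- histStats(prof)
  expect_equal(unname(st["std"]), 0)      # ideally flat surface
  expect_equal(unname(st["iqr"]), 0)
  expect_equal(unname(st["entropy_bits"]), 0)
})

test_that("checkerboard histogram has two equal bins and mean 127.5", {
  px <- outer(1:40, 1:40, function(r, c) ifelse((r + c) %% 2 == 0, 0, 255))
  prof <- luminanceHistogram(mkImg(px, 10))
  expect_equal(prof@counts[1], 800L)
  expect_equal(prof@counts[256], 800L)
  expect_equal(unname(histStats(prof)["mean"]), 127.5)
  expect_equal(unname(histStats(prof)["entropy_bits"]), 1)
})

test_that("the profile is invariant to pixel permutation", {
  px <- matrix(sample(0:255, 900, TRUE), 30, 30)
  shuf <- matrix(sample(as.vector(px)), 30, 30)
  expect_identical(luminanceHistogram(mkImg(px, 10))@counts,
                   luminanceHistogram(mkImg(shuf, 10))@counts)
})

test_that("Gaussian luminance noise of sigma 10 appears as std within 10%", {
  img <- addSemNoise(mkImg(matrix(128, 300, 300), 10), gaussianSigma = 10,
                     seed = 42)
  st <- histStats(luminanceHistogram(img))
  expect_lt(abs(st["std"] - 10) / 10, 0.1)
})

test_that("normalize only changes display, never the statistics", {
  px <- matrix(sample(0:255, 400, TRUE), 20, 20)
  raw <- luminanceHistogram(mkImg(px, 10))
  nrm <- luminanceHistogram(mkImg(px, 10), normalize = TRUE)
  expect_equal(histStats(raw), histStats(nrm))
  expect_equal(sum(histCounts(nrm)), 1)
})

test_that("roughness comparison orders by spread and enforces comparability", {
  px <- matrix(sample(0:255, 400, TRUE), 20, 20)
  a <- luminanceHistogram(mkImg(px, 10))
  expect_error(compareRoughness(a, a), "apparatus")
  expect_equal(compareRoughness(a, a, sameAcquisition = TRUE)$ordering,
               "indistinguishable")
  flat <- luminanceHistogram(mkImg(matrix(100, 20, 20), 10))
  expect_equal(compareRoughness(a, flat, sameAcquisition = TRUE)$ordering,
               "a_broader")
  expect_equal(compareRoughness(flat, a, sameAcquisition = TRUE)$ordering,
               "b_broader")
})

test_that("cracked surfaces broaden the histogram relative to their base", {
  wins <- 0L
  for (s in 1:20) {
    base <- addSemNoise(matrix(160, 200, 200), 8, seed = s + 1L)
    crk <- genCrackField(40, 3, 200, 100, seed = s)
    sCrk <- histStats(luminanceHistogram(synthImage(crk)))["std"]
    sBase <- histStats(luminanceHistogram(mkImg(base, 100)))["std"]
    if (sCrk > sBase) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})
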