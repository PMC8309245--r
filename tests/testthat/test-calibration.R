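test_that("8-bit greyscale ingestion is the identity and round-trips", {
  px <- matrix(sample(0:255, 64 * 48, replace = TRUE), 48, 64)
  f <- tempfile(fileext = ".tif")
  writeCalibratedImage(mkImg(px, 10), f)
  img <- loadImage(f, pixelSizeNm = 10)
  expect_identical(pixels(img), px + 0)
  expect_identical(dim(img), c(48L, 64L))
  # write-reload is bit-identical (ingestion idempotence)
  f2 <- tempfile(fileext = ".tif")
  writeCalibratedImage(img, f2)
  expect_identical(pixels(loadImage(f2, 10)), pixels(img))
  # physical width
  expect_equal(ncol(pixels(img)) * pixelSizeNm(img) / 1000, 0.64)
})

test_that("16-bit input rescales linearly over the container range", {
  x <- matrix(c(0, 65535, 32768, 16384) / 65535, 2, 2)
  f <- tempfile(fileext = ".tif")
  EBImage::writeImage(EBImage::Image(x), f, bits.per.sample = 16L)
  img <- loadImage(f, 25)
  # oracle: v * 255 / 65535, rounded
  expect_equal(sort(as.vector(pixels(img))),
               sort(round(c(0, 65535, 32768, 16384) * 255 / 65535)))
})

test_that("RGB reduces to 0.299/0.587/0.114 luminance", {
  g <- EBImage::Image(matrix(100 / 255, 8, 8))
  f <- tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::rgbImage(g, g, g), f)
  img <- loadImage(f, 10)
  expect_true(all(pixels(img) == 100))  # equal channels: weights sum to 1
  # distinct channels
  r <- EBImage::Image(matrix(200 / 255, 8, 8))
  b <- EBImage::Image(matrix(50 / 255, 8, 8))
  EBImage::writeImage(EBImage::rgbImage(r, g, b), f)
  expect_true(all(pixels(loadImage(f, 10)) ==
                  round(0.299 * 200 + 0.587 * 100 + 0.114 * 50)))
})

test_that("loadImage rejects bad inputs", {
  expect_error(loadImage(tempfile(), 10), "cannot read")
  f <- tempfile(fileext = ".png")
  EBImage::writeImage(EBImage::Image(matrix(0.5, 4, 4)), f)
  expect_error(loadImage(f, 0), "positive")
  expect_error(loadImage(f, -3), "positive")
})

test_that("denoise matches a tabulated discrete Gaussian and honours sigma 0", {
  # constant image is a fixed point of any blur
  cimg <- mkImg(matrix(77, 32, 32), 10)
  expect_identical(pixels(denoise(cimg, 2.5)), pixels(cimg))
  # single bright pixel: centre equals the discrete kernel peak of mass 255
  px <- matrix(0, 31, 31); px[16, 16] <- 255
  out <- denoise(mkImg(px, 10), 1.5)
  expect_equal(pixels(out)[16, 16], round(255 * gaussOracleCentre(1.5)),
               tolerance = 0, ignore_attr = TRUE)
  # sigma 0 is a bit-identical no-op
  img <- mkImg(matrix(sample(0:255, 400, TRUE), 20, 20), 10)
  expect_identical(pixels(denoise(img, 0)), pixels(img))
  expect_error(denoise(img, -1), "non-negative")
})

test_that("crop honours half-open 0-based ROIs and keeps calibration", {
  px <- matrix(seq_len(30 * 40) %% 256, 30, 40)
  img <- mkImg(px, 10)
  expect_identical(pixels(cropImage(img, fullROI(img))), pixels(img))
  one <- cropImage(img, roi(0, 0, 1, 1))
  expect_identical(dim(pixels(one)), c(1L, 1L))
  expect_equal(pixels(one)[1, 1], px[1, 1])
  sub <- cropImage(img, roi(5, 8, 10, 20))
  expect_identical(pixels(sub), px[6:15, 9:28] + 0)
  expect_equal(physicalAreaUm2(sub), 10 * 20 * (10 / 1000)^2)  # 0.02 um^2
  expect_error(cropImage(img, roi(25, 0, 10, 10)), "exceeds")
})

test_that("physical metrics scale linearly with the calibration", {
  px <- matrix(40, 64, 64)
  px <- drawDisk(px, 32, 32, 12, 200)
  for (mult in c(1, 2)) {
    img <- mkImg(px, 100 * mult)
    st <- particleStats(segmentParticles(img), assumeSpherical = TRUE)
    if (mult == 1) base <- st
  }
  expect_equal(st$area_um2, 4 * base$area_um2)
  expect_equal(st$equivalent_diameter_um, 2 * base$equivalent_diameter_um)
  expect_equal(st$volume_um3, 8 * base$volume_um3)
  em <- mkEdgeMap(matrix(c(rep(FALSE, 45), rep(TRUE, 5)), 5, 10),
                  pixelSizeNm = 10)
  em2 <- mkEdgeMap(em@mask, pixelSizeNm = 20)
  expect_equal(edgeLength(em2), 2 * edgeLength(em))
})
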