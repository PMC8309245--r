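test_that("constant and structureless images are reported aperiodic", {
  u <- estimatePeriod(mkImg(matrix(90, 64, 64), 100))
  expect_false(u@periodic)
  expect_true(is.na(u@periodRowsPx))
  expect_error(extractUnit(mkImg(matrix(90, 64, 64), 100), u), "aperiodic")
})

test_that("lattice periods are recovered and physically consistent", {
  tx <- genTexture(c(20, 17), sizePx = 256, seed = 2)
  u <- estimatePeriod(synthImage(tx))
  expect_true(u@periodic)
  expect_lte(abs(u@periodRowsPx - 20L), 1L)
  expect_lte(abs(u@periodColsPx - 17L), 1L)
  # physical consistency: period_um / period_px = pixel size, exactly
  expect_equal(u@periodRowsPx * pixelSizeNm(u) / 1000,
               u@periodRowsPx * 0.1)
})

test_that("period estimation is invariant to circular translation", {
  tx <- genTexture(c(16, 24), sizePx = 240, seed = 6)
  px <- pixels(synthImage(tx))
  u0 <- estimatePeriod(mkImg(px, 100))
  for (off in list(c(5, 0), c(0, 9), c(11, 7))) {
    shifted <- px[c((off[1] + 1):240, seq_len(off[1]))[1:240],
                  c((off[2] + 1):240, seq_len(off[2]))[1:240]]
    u <- estimatePeriod(mkImg(shifted, 100))
    expect_identical(c(u@periodRowsPx, u@periodColsPx),
                     c(u0@periodRowsPx, u0@periodColsPx))
  }
})

test_that("the extracted template reproduces the generating bump", {
  tx <- genTexture(c(20, 20), sizePx = 260, seed = 3, bumpDiameterPx = 10,
                   noiseSigma = 0)
  img <- synthImage(tx)
  u <- extractUnit(img, estimatePeriod(img))
  # per-cell median template matches one source tile within 2 levels
  tile <- pixels(img)[1:20, 1:20]
  expect_lte(max(abs(u@template - tile)), 2)
  # disks of 10 px in 20 px cells at 100 nm/px: unit extent 1.0 um, +/- 1 px
  expect_lte(abs(u@unitWidthUm - 1.0), 0.1 + 1e-9)
  expect_lte(abs(u@unitHeightUm - 1.0), 0.1 + 1e-9)
  # element always fits its cell
  expect_lte(u@unitHeightUm, u@periodRowsPx * 0.1)
  expect_lte(u@unitWidthUm, u@periodColsPx * 0.1)
})

test_that("a single-tile unit returns the image itself as template", {
  px <- matrix(sample(0:255, 24 * 24, TRUE), 24, 24)
  img <- mkImg(px, 100)
  unit <- new("TextureUnit", periodic = TRUE, periodRowsPx = 24L,
              periodColsPx = 24L, pixelSizeNm = 100,
              template = matrix(numeric(0), 0, 0),
              unitHeightUm = NA_real_, unitWidthUm = NA_real_)
  u <- extractUnit(img, unit)
  expect_equal(u@template, px, ignore_attr = TRUE)
})

test_that("pattern reconstruction tiles exactly and correlates with the source", {
  tx <- genTexture(c(20, 17), sizePx = 255, seed = 4, noiseSigma = 0)
  img <- synthImage(tx)
  u <- extractUnit(img, estimatePeriod(img))
  one <- reconstructPattern(u, 1, 1)
  expect_equal(pixels(one), round(u@template), ignore_attr = TRUE)
  rec <- reconstructPattern(u, 3, 3)
  expect_identical(dim(pixels(rec)), c(3L * u@periodRowsPx,
                                       3L * u@periodColsPx))
  expect_identical(pixels(rec)[1:u@periodRowsPx, 1:u@periodColsPx],
                   pixels(rec)[(u@periodRowsPx + 1):(2 * u@periodRowsPx),
                               (u@periodColsPx + 1):(2 * u@periodColsPx)])
  full <- reconstructPattern(u, 255 %/% u@periodRowsPx,
                             255 %/% u@periodColsPx)
  src <- pixels(img)[seq_len(nrow(pixels(full))), seq_len(ncol(pixels(full)))]
  expect_gte(stats::cor(as.vector(pixels(full)), as.vector(src)), 0.8)
  expect_error(reconstructPattern(u, 0, 2), "positive")
})
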