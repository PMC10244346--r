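test_that("image round trips preserve intensities within quantization", {
  withSeed(1L, img <- WellImage(matrix(runif(64 * 64), 64), wellId = "A01"))
  tf <- withr::local_tempfile(fileext = ".tif")
  writeWellImage(img, tf)
  back <- readWellImage(tf, wellId = "A01")
  expect_lt(max(abs(pixels(back) - pixels(img))), 1 / 65535 + 1e-9)

  pf <- withr::local_tempfile(fileext = ".png")
  writeWellImage(img, pf)
  back8 <- readWellImage(pf)
  expect_lte(max(abs(pixels(back8) - pixels(img))), 1 / 255)

  # full-scale 16-bit value maps to intensity 1.0
  tiff::writeTIFF(matrix(1, 4, 4), tf, bits.per.sample = 16L)
  expect_equal(max(pixels(readWellImage(tf))), 1.0)
})

test_that("RGB inputs are converted to luminance with a warning", {
  pf <- withr::local_tempfile(fileext = ".png")
  withSeed(2L, png::writePNG(array(runif(8 * 8 * 3), c(8, 8, 3)), pf))
  expect_warning(img <- readWellImage(pf), "luminance")
  expect_equal(length(dim(pixels(img))), 2L)
})

test_that("mask round trip preserves the palette exactly", {
  pal <- maskPalette()
  withSeed(3L, lab <- matrix(sample(pal, 100, replace = TRUE), 10))
  mk <- RegionMask(lab, wellId = "m1")
  pf <- withr::local_tempfile(fileext = ".png")
  writeRegionMask(mk, pf)
  expect_identical(maskLabels(readRegionMask(pf)), maskLabels(mk))
})

test_that("tiling matches the stride-with-edge-re-anchor convention", {
  # 2816-px side, 512 patch, 50% overlap: 10 origins per axis, 100 patches
  t1 <- cropPatches(matrix(0, 2816, 2816), 512, 0.5, originsOnly = TRUE)
  expect_equal(length(unique(t1$origins[, 1])), 10L)
  expect_equal(nrow(t1$origins), 100L)
  expect_equal(sort(unique(t1$origins[, 1])), seq(0, 2304, by = 256))

  # 5120-px side: 19 origins per axis (brute-force coverage check below)
  t2 <- cropPatches(matrix(0, 5120, 5120), 512, 0.5, originsOnly = TRUE)
  o <- sort(unique(t2$origins[, 1]))
  expect_equal(length(o), 19L)
  covered <- logical(5120)
  for (r in o) covered[(r + 1):(r + 512)] <- TRUE
  expect_true(all(covered))

  # patch = image side: exactly one patch at (0,0)
  t3 <- cropPatches(matrix(0, 64, 64), 64, 0.5)
  expect_equal(nrow(t3$origins), 1L)
  expect_equal(unname(t3$origins[1, ]), c(0L, 0L))

  expect_error(cropPatches(matrix(0, 32, 32), 64), "patch")
})

test_that("crop then reconstruct(mean) is the exact inverse", {
  withSeed(4L, img <- matrix(runif(100 * 100), 100))
  tl <- cropPatches(img, 32, 0.5)
  rec <- reconstructPatches(tl$patches, tl$origins, dim(img), "mean")
  expect_equal(rec, img)
})

test_that("reconstruction aggregators behave as named", {
  # identical constant patches, mean -> constant output
  tl <- cropPatches(matrix(0.7, 48, 48), 16, 0.5)
  rec <- reconstructPatches(tl$patches, tl$origins, c(48, 48), "mean")
  expect_true(all(rec == 0.7))

  # binary patches, any_positive == logical OR in overlaps
  withSeed(5L, img <- matrix(rbinom(48 * 48, 1, 0.2), 48))
  tb <- cropPatches(img, 16, 0.5)
  recB <- reconstructPatches(tb$patches, tb$origins, c(48, 48), "any_positive")
  expect_identical(recB, img > 0)

  # max aggregator against a pixelwise brute-force loop (full coverage plus
  # one overlapping center patch)
  withSeed(6L, imgs <- lapply(1:5, function(i) matrix(runif(16 * 16), 16)))
  origins <- rbind(c(0, 0), c(16, 0), c(0, 16), c(16, 16), c(8, 8))
  recM <- reconstructPatches(imgs, origins, c(32, 32), "max")
  oracle <- matrix(-Inf, 32, 32)
  for (i in 1:5)
    for (r in 1:16) for (cc in 1:16) {
      rr <- origins[i, 1] + r; ccc <- origins[i, 2] + cc
      oracle[rr, ccc] <- max(oracle[rr, ccc], imgs[[i]][r, cc])
    }
  expect_equal(recM, oracle)

  # uncovered pixel is an error naming the gap
  expect_error(reconstructPatches(imgs[1], origins[1, , drop = FALSE],
                                  c(32, 32), "mean"),
               "uncovered pixel")
})

test_that("acquisition-plan arithmetic matches the plate layouts", {
  expect_equal(acquisitionPlan(96, 5, 3)$total, 7200)
  expect_equal(acquisitionPlan(384, 3, 1)$total, 3456)
  p <- acquisitionPlan(1, 1, 1)
  expect_equal(p$total, 1)
  expect_equal(nrow(p$tiles), 1L)
  p2 <- acquisitionPlan(2, 3, 2)
  expect_equal(nrow(p2$tiles), p2$total)
})

test_that("resizing uses nearest neighbor for masks", {
  pal <- maskPalette()
  lab <- matrix(pal[["black"]], 64, 64)
  lab[1:32, ] <- pal[["dark_gray"]]
  rs <- resizeWell(RegionMask(lab), 32L)
  expect_true(all(maskLabels(rs) %in% pal))
  expect_equal(dim(rs), c(32L, 32L))
})
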