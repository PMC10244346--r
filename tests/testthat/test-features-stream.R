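test_that("local entropy matches a histogram oracle and thresholds at 3 bits", {
  # constant image: zero entropy everywhere, empty mask
  m <- cellRegionMask(matrix(0.5, 64, 64))
  expect_false(any(m))
  expect_lte(max(abs(attr(m, "entropy"))), 1e-9)

  # uniform noise: center-pixel entropy equals the direct disc histogram
  withSeed(41L, img <- matrix(runif(101 * 101), 101))
  m2 <- cellRegionMask(img, radius = 10)
  ent <- attr(m2, "entropy")
  ctr <- 51L
  off <- expand.grid(dy = -10:10, dx = -10:10)
  off <- off[off$dy^2 + off$dx^2 <= 100, ]
  vals <- img[cbind(ctr + off$dy, ctr + off$dx)]
  counts <- table(round(pmin(pmax(vals, 0), 1) * 255))
  pr <- counts / sum(counts)
  oracle <- -sum(pr * log2(pr))
  expect_equal(ent[ctr, ctr], oracle, tolerance = 1e-10)
  expect_gt(oracle, 7)      # near the 8-bit ceiling
  expect_true(all(m2))      # noise is fully "cell-covered"

  # the default threshold is 3 bits
  expect_equal(formals(cellRegionMask)$entropyThreshold, 3)
})

test_that("fractal dimension matches a brute-force box counter and stays in [2,3]", {
  withSeed(42L, img <- matrix(runif(486 * 486), 486))
  fd <- fractalDimension(img)
  expect_gte(fd, 2.8)
  expect_lte(fd, 3)

  # independent double-loop differential box counter on the same schedule
  k <- 243^(1 / 15)
  widths <- as.integer(round(2 * k^(0:15)))
  G <- 256
  bruteN <- vapply(widths, function(r) {
    h <- r * G / 486
    total <- 0
    for (by in seq(1, 486, by = r)) for (bx in seq(1, 486, by = r)) {
      cell <- img[by:min(by + r - 1, 486), bx:min(bx + r - 1, 486)] * (G - 1)
      total <- total + (ceiling(max(cell) / h) - ceiling(min(cell) / h) + 1)
    }
    total
  }, numeric(1))
  fdBrute <- -unname(coef(lm(log(bruteN) ~ log(widths)))[2])
  expect_equal(fd, fdBrute, tolerance = 1e-10)

  # constant image collapses to the planar dimension
  expect_equal(suppressWarnings(fractalDimension(matrix(0.5, 486, 486))), 2,
               tolerance = 0.02)
  expect_error(fractalDimension(matrix(0, 100, 100)), ">= 486")
})

test_that("fractal dimension lies in [2,3] across image types", {
  withSeed(43L, {
    for (i in 1:25) {
      img <- switch(i %% 3 + 1,
        matrix(runif(486 * 486), 486),
        pscdiff:::.clip01(0.5 + 0.2 * pscdiff:::.smoothNoise(486, 3)),
        pscdiff:::.clip01(matrix(rep(sin(1:486 / 5), 486), 486) * 0.3 + 0.5))
      fd <- suppressWarnings(fractalDimension(img))
      expect_gte(fd, 2)
      expect_lte(fd, 3)
    }
  })
})

test_that("colony statistics follow the normalized-geometry definitions", {
  p <- matrix(0.5, 120, 120)
  expect_equal(unname(colonyStats(p, matrix(TRUE, 120, 120))["Area"]), 1)

  # centered filled square of side s: circumference ~ 4 s / L
  mask <- matrix(FALSE, 120, 120)
  mask[31:90, 31:90] <- TRUE
  cs <- colonyStats(p, mask)
  expect_equal(unname(cs["Circumference"]), 4 * 60 / 120, tolerance = 0.05)
  expect_equal(unname(cs["Area"]), 3600 / 14400)
  expect_equal(unname(cs["ACRatio"]), unname(cs["Area"] / cs["Circumference"]))

  expect_warning(z <- colonyStats(p, matrix(FALSE, 120, 120)), "empty")
  expect_true(all(z == 0))
})

test_that("block-matching flow recovers planted rigid shifts within 15%", {
  base <- textureField(220, 2, seed = 44L)
  expect_equal(as.numeric(opticalFlowFeature(base, base)), 0)
  for (sh in c(5L, 8L, 12L, 16L)) {
    prev <- base[1:160, 1:160]
    nxt <- base[(1 + sh):(160 + sh), 1:160]
    est <- as.numeric(opticalFlowFeature(prev, nxt))
    expect_lt(abs(est - sh) / sh, 0.15)
  }
  # sub-threshold motion is discarded entirely (cutoff default 4)
  expect_equal(formals(opticalFlowFeature)$minMagnitude, 4)
  prev <- base[1:160, 1:160]
  nxt3 <- base[4:163, 1:160]
  expect_equal(as.numeric(opticalFlowFeature(prev, nxt3)), 0)
  expect_error(opticalFlowFeature(base, base[1:100, 1:100]), "shape")
})

test_that("stream feature vector has the 21-entry contract", {
  plan <- syntheticPlan(seed = 45L)
  s <- generateStream(plan, 8, seed = 45L)
  fv <- streamFeatureVector(s)
  expect_length(fv, 21L)
  expect_named(fv)
  expect_true(all(fv[grepl("FractalDimension", names(fv))] >= 2 &
                    fv[grepl("FractalDimension", names(fv))] <= 3))
  # contraction: post-phase normalized area below pre-phase
  expect_lt(fv[["Area.post"]], fv[["Area.pre"]])
})

test_that("a static stream normalizes to exactly one and zero flow", {
  frame <- WellImage(pscdiff:::.clip01(0.5 + 0.1 * textureField(486, 2, 46L)))
  s <- ImageStream(rep(list(frame), 10L))
  fv <- streamFeatureVector(s)
  for (nm in c("Area", "Circumference", "ACRatio"))
    expect_equal(unname(fv[paste(nm, c("pre", "mid", "post"), sep = ".")]),
                 c(1, 1, 1))
  expect_equal(unname(fv[paste0("OpticalFlow.", c("pre", "mid", "post"))]),
               c(0, 0, 0))
  expect_true("OpticalFlow" %in% attr(fv, "unnormalized"))
})

test_that("phase pooling preserves the sequence mean under phase weights", {
  plan <- syntheticPlan(seed = 47L)
  s <- generateStream(plan, 6, seed = 47L)
  raw <- vapply(frames(s), function(f) fractalDimension(pixels(f)), numeric(1))
  fv <- streamFeatureVector(s)
  pooled <- fv[paste0("FractalDimension.", c("pre", "mid", "post"))]
  expect_equal(unname(sum(pooled * c(3, 4, 3)) / 10), mean(raw),
               tolerance = 1e-12)
})
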