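test_that("shape statistics match analytic geometry on reference shapes", {
  # filled disc: near-perfect solidity and circularity, tight CCD spread
  m <- matrix(FALSE, 120, 120)
  m[(row(m) - 60)^2 + (col(m) - 60)^2 <= 40^2] <- TRUE
  disc <- shapeStats(m)$imageLevel
  expect_gte(disc[["Solidity"]], 0.98)
  expect_lt(abs(disc[["Circularity"]] - 1), 0.05)
  expect_lte(disc[["StdCCD"]] / disc[["MeanCCD"]], 0.05)

  # convex filled square: solidity exactly 1
  sq <- matrix(FALSE, 100, 100)
  sq[20:80, 20:80] <- TRUE
  expect_equal(shapeStats(sq)$imageLevel[["Solidity"]], 1)

  # plus-sign polygon versus a vertex-coordinate oracle
  pl <- matrix(FALSE, 120, 120)
  pl[41:80, 21:100] <- TRUE
  pl[21:100, 41:80] <- TRUE
  plus <- shapeStats(pl)$imageLevel
  areaTrue <- 80 * 40 + 80 * 40 - 40 * 40
  hullAreaTrue <- 80 * 80 - 4 * (20 * 20 / 2)  # octagonal hull
  solidityTrue <- areaTrue / hullAreaTrue
  hullPerimTrue <- 4 * 40 + 4 * sqrt(2 * 20^2)
  perimTrue <- 4 * 40 + 8 * 20
  convexityTrue <- hullPerimTrue / perimTrue
  expect_lt(plus[["Solidity"]], 1)
  expect_lt(plus[["Convexity"]], 1)
  expect_equal(plus[["Solidity"]], solidityTrue, tolerance = 0.05)
  expect_equal(plus[["Convexity"]], convexityTrue, tolerance = 0.05)

  expect_warning(z <- shapeStats(matrix(FALSE, 10, 10))$imageLevel, "shape stats")
  expect_true(all(z == 0))
})

test_that("CCD statistics satisfy their ordering identities per component", {
  withSeed(71L, {
    for (i in 1:5) {
      m <- pscdiff:::.smoothNoise(100, 6) > 0.4
      comp <- pscdiff:::.componentShapes(m, minComponent = 50L)
      if (is.null(comp)) next
      expect_true(all(comp$minCCD <= comp$meanCCD + 1e-9))
      expect_true(all(comp$meanCCD <= comp$maxCCD + 1e-9))
      expect_equal(comp$minMaxCCD, comp$minCCD / comp$maxCCD)
      expect_true(all(comp$circularity <= 1.05))
      expect_true(all(comp$solidity > 0 & comp$solidity <= 1))
      expect_true(all(comp$convexity > 0 & comp$convexity <= 1))
    }
  })
})

test_that("spacing measures half the gap between regions", {
  # two filled half-planes split by a 20-px band: spacing ~ 10
  m <- matrix(TRUE, 100, 100)
  m[, 41:60] <- FALSE
  expect_equal(colonySpacing(m), 10, tolerance = 0.1)

  # nearly full mask: sub-pixel spacing
  m2 <- matrix(TRUE, 50, 50)
  m2[25, 25] <- FALSE
  expect_lte(colonySpacing(m2), 1.5)

  # transpose symmetry (thinning is near-symmetric, not bitwise identical)
  m3 <- matrix(TRUE, 80, 80)
  m3[, 31:46] <- FALSE
  expect_equal(colonySpacing(m3), colonySpacing(t(m3)), tolerance = 0.05)

  expect_warning(expect_equal(colonySpacing(matrix(TRUE, 10, 10)), 0), "full")
})

test_that("the colony profile is 343-D, named, and deterministic", {
  cb <- fixtureCodebooks()
  p <- pixels(fixtureWell()$bright)
  fv <- colonyFeatureVector(p, cb$sift, cb$orb)
  expect_length(fv, 343L)
  expect_equal(names(fv)[1:4], c("LocalEntropy", "CellBrightness",
                                 "CellContrast", "TotalVariation"))
  expect_equal(sum(grepl("^SIFT", names(fv))), 256L)
  expect_equal(sum(grepl("^ORB", names(fv))), 64L)
  expect_equal(names(fv)[343], "Spacing")
  expect_identical(fv, colonyFeatureVector(p, cb$sift, cb$orb))

  # constant image: flat texture features and empty histograms
  expect_warning(fvc <- colonyFeatureVector(matrix(0.5, 256, 256),
                                            cb$sift, cb$orb))
  expect_equal(unname(fvc[c("CellContrast", "TotalVariation")]), c(0, 0))
  expect_equal(sum(fvc[grepl("^SIFT|^ORB", names(fvc))]), 0)

  expect_error(colonyFeatureVector(p, cb$orb, cb$orb), "k = 256")
  expect_error(colonyFeatureVector(p), "codebooks")
})

test_that("Hu moments are invariant to 90-degree rotation", {
  p <- pixels(fixtureWell()$bright)
  h1 <- pscdiff:::.huMoments(p)
  h2 <- pscdiff:::.huMoments(t(p[nrow(p):1, ]))  # 90-degree rotation
  expect_equal(h1, h2, tolerance = 1e-3)
})

test_that("random forests expose importances and clipped predictions", {
  withSeed(72L, {
    X <- matrix(rnorm(200 * 10), 200)
    colnames(X) <- paste0("f", 1:10)
    y <- pmin(pmax(0.5 + 0.4 * X[, 7] + rnorm(200, 0, 0.05), 0), 1)
  })
  fi <- fitForest(X, y, mode = "importance", seed = 3L)
  expect_equal(fi$fit$num.trees, 1000L)
  expect_equal(which.max(fi$importances), c(f7 = 7L))
  expect_equal(sum(fi$importances), 1, tolerance = 1e-9)

  fp <- fitForest(X, y, mode = "prediction", seed = 3L)
  expect_equal(fp$fit$num.trees, 20L)
  pr <- predictEfficiency(fp, X)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_gte(cor(predictEfficiency(fi, X), y), 0.95)  # deep forest overfits train

  # constant target: constant predictions
  fc <- fitForest(X, rep(0.4, 200), mode = "prediction", seed = 1L)
  expect_true(all(abs(predictEfficiency(fc, X) - 0.4) < 1e-9))

  Xbad <- X; Xbad[3, 2] <- NaN
  expect_error(fitForest(Xbad, y), "f2")
  Xren <- X; colnames(Xren)[1] <- "zzz"
  expect_error(predictEfficiency(fp, Xren), "feature names")
  expect_error(fitForest(X[1:5, ], y[1:5]), "10 samples")
})
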