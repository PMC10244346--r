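test_that("patch labeling follows the dark-gray / only-black rule", {
  pal <- maskPalette()
  mkMask <- function(fracDark, rest = pal[["black"]]) {
    m <- matrix(rest, 10, 10)
    if (fracDark > 0) m[seq_len(round(100 * fracDark))] <- pal[["dark_gray"]]
    m
  }
  img <- matrix(0.5, 10, 10)
  # 35% dark gray -> positive; all black -> negative; 10% dark -> discarded
  ds <- buildPatchDataset(list(img, img, img),
                          list(mkMask(0.35), mkMask(0), mkMask(0.10)),
                          patch = 10)
  expect_equal(as.character(ds$labels), c("positive", "negative"))
  expect_length(ds$patches, 2L)

  # definitive-endoderm variant: 20% threshold against a binary mask,
  # negatives are patches with no positive pixel at all
  deMask <- function(frac) {
    m <- matrix(pal[["black"]], 10, 10)
    if (frac > 0) m[seq_len(round(100 * frac))] <- pal[["white"]]
    m
  }
  de <- buildPatchDataset(list(img, img, img),
                          list(deMask(0.25), deMask(0), deMask(0.05)),
                          patch = 10, positiveFrac = 0.20,
                          positiveCode = pal[["white"]],
                          negativeRule = "no_positive")
  expect_equal(as.character(de$labels), c("positive", "negative"))

  expect_error(buildPatchDataset(list(img), list(matrix(0L, 8, 8)), patch = 8),
               "shapes differ")
})

test_that("fluorescence masks close nearby nuclei into one region", {
  expect_equal(sum(maskLabels(maskFromFluorescence(matrix(0, 50, 50)))), 0)

  # two nuclear blobs whose gap is smaller than the disc diameter merge
  f <- matrix(0, 60, 60)
  f[27:33, 22:27] <- 1; f[27:33, 32:37] <- 1  # 4-px gap, radius-5 closing
  expect_equal(max(pscdiff:::.label8(f > 0.5)), 2)  # separate before closing
  mk <- maskFromFluorescence(f, closingRadius = 5L)
  bin <- maskLabels(mk) > 0
  expect_equal(max(pscdiff:::.label8(bin)), 1)

  # closing is idempotent
  once <- maskLabels(maskFromFluorescence(f, closingRadius = 5L))
  f2 <- once / 255
  twice <- maskLabels(maskFromFluorescence(f2, threshold = 0.5,
                                           closingRadius = 5L))
  expect_identical(once, twice)
})

test_that("class-activation maps equal the explicit-loop oracle", {
  # fixed tiny network with hand-set weights: conv(1->2) -> relu -> GAP ->
  # dense(2); the 8x8 input equals the feature-map size, so no upsampling
  net <- pscdiff:::.buildSequential(list(
    list("conv", out = 2L, k = 3L), list("relu"),
    list("gap"), list("dense", out = 2L)), inC = 1L)
  W1 <- matrix(seq(-0.4, 0.4, length.out = 18), 2, 9)
  b1 <- c(0.05, -0.02)
  W2 <- matrix(c(-0.3, 0.6, 0.2, -0.5), 2, 2)
  b2 <- c(0, 0.4)  # bias the positive class so the patch is predicted positive
  net$layers[[1]]$W <- W1; net$layers[[1]]$b <- b1
  net$layers[[4]]$W <- W2; net$layers[[4]]$b <- b2
  model <- structure(list(net = net, camLayer = 2L,
                          classes = c("negative", "positive"), inputSide = 8L),
                     class = "patchClassifier")
  patch <- matrix(seq(0, 1, length.out = 64), 8, 8)
  cam <- gradCAM(model, patch)
  expect_equal(cam$predicted, "positive")

  # oracle: explicit convolution loops, closed-form gradient of the
  # positive pre-softmax score through GAP + dense
  A <- array(0, c(8, 8, 2))
  for (k in 1:2) for (i in 1:8) for (j in 1:8) {
    acc <- b1[k]
    for (dj in -1:1) for (di in -1:1) {
      ii <- i + di; jj <- j + dj
      v <- if (ii >= 1 && ii <= 8 && jj >= 1 && jj <= 8) patch[ii, jj] else 0
      acc <- acc + W1[k, (di + 2) + 3 * (dj + 1)] * v
    }
    A[i, j, k] <- max(acc, 0)
  }
  Z <- 64
  alpha <- numeric(2)
  for (k in 1:2) {
    s <- 0
    for (i in 1:8) for (j in 1:8) s <- s + W2[2, k] / Z  # d y+ / d A^k_ij
    alpha[k] <- s / Z
  }
  heat <- matrix(0, 8, 8)
  for (k in 1:2) heat <- heat + alpha[k] * A[, , k]
  heat[heat < 0] <- 0
  expect_lt(max(abs(cam$heatmap - heat)), 1e-6)

  # normalization and binarization contract (threshold 10 on 0-255)
  if (max(heat) > 0)
    expect_equal(cam$normalized8, 255 * heat / max(heat), tolerance = 1e-6)
  expect_identical(cam$binary, cam$normalized8 > 10)
  expect_true(all(cam$heatmap >= 0))
})

test_that("negative-predicted patches give an all-zero map", {
  net <- pscdiff:::.buildSequential(list(
    list("conv", out = 2L, k = 3L), list("relu"),
    list("gap"), list("dense", out = 2L)), inC = 1L)
  net$layers[[4]]$b <- c(5, 0)  # force the negative class
  model <- structure(list(net = net, camLayer = 2L,
                          classes = c("negative", "positive"), inputSide = 8L),
                     class = "patchClassifier")
  cam <- gradCAM(model, matrix(0.5, 8, 8))
  expect_equal(cam$predicted, "negative")
  expect_true(all(cam$heatmap == 0))
  expect_false(any(cam$binary))
})

test_that("training on separable textures drives the loss down", {
  withSeed(81L, {
    flat <- lapply(1:20, function(i) matrix(runif(1, 0.4, 0.6), 32, 32) +
                     matrix(rnorm(1024, 0, 0.01), 32))
    tex <- lapply(1:20, function(i)
      pscdiff:::.clip01(0.5 + 0.2 * pscdiff:::.smoothNoise(32, 1)))
  })
  ds <- structure(list(
    patches = c(flat, tex),
    labels = factor(rep(c("negative", "positive"), each = 20),
                    levels = c("negative", "positive")),
    well = rep("w", 40), origins = NULL, patch = 32L,
    positiveFrac = 0.3, positiveCode = 192L, negativeRule = "only_black"),
    class = "PatchDataset")
  cfg <- patchTrainConfig("desk")
  cfg$inputSide <- 32L; cfg$epochs <- 10L
  model <- trainPatchClassifier(ds, config = cfg)
  h <- model$history
  expect_lt(h$train_loss[10], h$train_loss[1])
  expect_gte(h$val_accuracy[10], 0.9)
  # probabilities are a proper 2-class distribution
  pr <- predictPatch(model, tex[[1]])
  expect_equal(sum(pr), 1)
  expect_named(pr, c("negative", "positive"))

  dsOne <- ds; dsOne$labels <- factor(rep("positive", 24),
                                      levels = c("negative", "positive"))
  expect_error(trainPatchClassifier(dsOne, config = cfg), "both labels")

  # the published training preset is carried as configuration
  paper <- patchTrainConfig("paper")
  expect_equal(paper$epochs, 300L)
  expect_equal(paper$batch, 6L)
  expect_equal(paper$lr, 3e-5)
})

test_that("segmentation metrics follow the printed formulas", {
  # hand confusion: TP=50, FP=10, FN=40, TN=100 on a 200-px layout
  pred <- matrix(FALSE, 10, 20)
  gt <- matrix(0L, 10, 20)
  pred[1:60] <- TRUE                # 60 positive predictions
  gt[1:50] <- 255L                  # TP = 50, FP = 10
  gt[61:100] <- 255L                # FN = 40; rest TN = 100
  m <- segmentationMetrics(pred, gt, mode = "binary")
  expect_equal(m$precision, 5 / 6)
  expect_equal(m$recall, 5 / 9)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$iou, 0.5)
  expect_equal(m$specificity, 10 / 11)
  expect_equal(m$accuracy, 0.75)

  # perfect prediction
  mp <- segmentationMetrics(gt > 0, gt, mode = "binary")
  expect_equal(unlist(mp[c("accuracy", "precision", "recall", "f1",
                           "specificity", "iou")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1,
                 specificity = 1, iou = 1))

  # CPC mode: dark and light gray both count as ground truth
  pal <- maskPalette()
  g <- matrix(pal[["black"]], 8, 8)
  g[1:8] <- pal[["dark_gray"]]; g[9:16] <- pal[["light_gray"]]
  mc <- segmentationMetrics(matrix(TRUE, 8, 8)[, , drop = FALSE] &
                              col(g) <= 2, g, mode = "cpc")
  expect_equal(mc$recall, 1)
  expect_false(mc$discarded)
  expect_true(segmentationMetrics(matrix(FALSE, 8, 8), matrix(0L, 8, 8))$discarded)
  expect_error(segmentationMetrics(matrix(TRUE, 4, 4), matrix(0L, 5, 5)),
               "shapes")
})

test_that("F1 and IoU obey their algebraic identity on random masks", {
  withSeed(82L, {
    for (i in 1:200) {
      pred <- matrix(runif(400) < runif(1, 0.2, 0.8), 20)
      gt <- matrix((runif(400) < runif(1, 0.2, 0.8)) * 255L, 20)
      m <- segmentationMetrics(pred, gt, mode = "binary")
      if (m$discarded || is.na(m$iou)) next
      expect_equal(m$f1, 2 * m$iou / (1 + m$iou), tolerance = 1e-12)
      # accuracy is a prevalence-weighted mix of recall and specificity
      if (!is.na(m$recall) && !is.na(m$specificity)) {
        expect_gte(m$accuracy, min(m$recall, m$specificity) - 1e-12)
        expect_lte(m$accuracy, max(m$recall, m$specificity) + 1e-12)
      }
    }
  })
})

test_that("well ranking uses descending fractions with documented tie-breaks", {
  fr <- c(w3 = 0.5, w1 = 0.5, w2 = 0.9, ctlP = 0.95, ctlN = 0.05, w4 = 0.2)
  rk <- rankWells(fr, controls = c("ctlP", "ctlN"), k = 2,
                  candidateThreshold = 0.40)
  ranked <- rk[!is.na(rk$rank), ]
  expect_equal(ranked$well, c("w2", "w1", "w3", "w4"))  # ties by well id
  expect_equal(ranked$top_k, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ranked$candidate, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(is.na(rk$rank[rk$well %in% c("ctlP", "ctlN")])))
  # defaults carry the screening conventions
  expect_equal(formals(rankWells)$k, 40L)
  expect_equal(formals(rankWells)$candidateThreshold, 0.40)
})
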