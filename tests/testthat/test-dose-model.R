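test_that("dose labeling implements the 20% optimal-range rule", {
  rec <- data.frame(chir_um = rep(c(4, 6, 8, 10), each = 3),
                    chir_h = 24,
                    positive_fraction = rep(c(0.05, 0.25, 0.30, 0.10), each = 3))
  expect_equal(formals(labelDoses)$efficiencyThreshold, 0.20)
  lab <- labelDoses(rec, 24)
  expect_equal(lab$c1, 6)
  expect_equal(lab$c2, 8)
  expect_equal(doseClass(lab, 4), "low")
  expect_equal(deltaChir(lab, 4), -2)
  expect_equal(deltaChir(lab, 7), 0)
  expect_equal(doseClass(lab, 10), "high")
  expect_equal(deltaChir(lab, 10), 2)

  recNone <- transform(rec, positive_fraction = 0.01)
  expect_error(labelDoses(recNone, 24), "no optimal range")

  recGap <- data.frame(chir_um = c(4, 6, 8), chir_h = 24,
                       positive_fraction = c(0.3, 0.1, 0.3))
  expect_warning(labGap <- labelDoses(recGap, 24), "non-contiguous")
  expect_equal(c(labGap$c1, labGap$c2), c(4, 8))
})

test_that("delta-CHIR sign always agrees with the class over a dose grid", {
  lab <- structure(list(c1 = 6, c2 = 8), class = "DoseLabeling")
  grid <- seq(0.5, 20, by = 0.25)
  cls <- doseClass(lab, grid)
  d <- deltaChir(lab, grid)
  expect_true(all((d == 0) == (cls == "optimal")))
  expect_true(all((d < 0) == (cls == "low")))
  expect_true(all((d > 0) == (cls == "high")))
  expect_equal(d[grid < 6], grid[grid < 6] - 6)
  expect_equal(d[grid > 8], grid[grid > 8] - 8)
})

test_that("the classifier fits separable classes and weights by inverse frequency", {
  withSeed(51L, {
    y <- sample(c("low", "optimal", "high"), 200, replace = TRUE)
    mu <- c(low = -3, optimal = 0, high = 3)[y]
    X <- cbind(f1 = mu + rnorm(200, 0, 0.3),
               f2 = rnorm(200), f3 = rnorm(200))
  })
  m <- trainDoseClassifier(X, y, dosePreset("21feat-24h"))
  expect_gte(mean(predict(m, X) == y), 0.95)
  expect_error(trainDoseClassifier(X, rep("low", 200)), "2 classes")

  # a class with half the samples gets double weight
  y2 <- rep(c("a", "b", "b"), 60)
  X2 <- cbind(rnorm(180), rnorm(180))
  m2 <- trainDoseClassifier(X2, y2, dosePreset("4feat"))
  expect_equal(unname(m2$classWeights["a"] / m2$classWeights["b"]), 2)

  # preset registry carries the published settings
  expect_equal(dosePreset("21feat-24h")$strength, 1 / 4)
  expect_equal(dosePreset("21feat-36h")$strength, 1 / 8)
  expect_equal(dosePreset("4feat")[c("kind", "strength")],
               list(kind = "l2", strength = 0.1))
  en <- dosePreset("cross-batch")
  expect_equal(en$alpha, 0.1)      # l1-ratio
  expect_equal(en$strength, 0.05)  # weight
})

test_that("ANOVA selection finds planted signal with stable tie-breaking", {
  withSeed(52L, {
    y <- rep(c("low", "optimal", "high"), each = 30)
    X <- matrix(rnorm(90 * 6), 90)
    X[, 4] <- as.integer(factor(y)) + rnorm(90, 0, 0.05)
  })
  sel <- selectFeaturesAnova(X, y, k = 1)
  expect_equal(sel[1], 4L)
  expect_equal(as.integer(selectFeaturesAnova(X, y, k = 6)), order(-attr(selectFeaturesAnova(X, y, 6), "F")))
  # k = n_features returns all; k beyond errors
  expect_length(selectFeaturesAnova(X, y, 6), 6L)
  expect_error(selectFeaturesAnova(X, y, 7), "exceeds")
  # exact ties break toward the lower index
  Xt <- cbind(X[, 4], X[, 4])
  expect_equal(as.integer(selectFeaturesAnova(Xt, y, 1)), 1L)
})

test_that("deviation scores follow (high - low)/N_c and stay in [-1, 1]", {
  expect_equal(deviationScores(rep("high", 10), rep(6, 10))$score, 1)
  expect_equal(deviationScores(rep("low", 10), rep(6, 10))$score, -1)
  expect_equal(deviationScores(rep("optimal", 10), rep(6, 10))$score, 0)
  expect_equal(deviationScores(c("high", "high", "high", "low"), rep(6, 4))$score,
               0.5)
  # exhaustive enumeration for N_c <= 6
  for (n in 1:6) {
    combos <- expand.grid(nl = 0:n, no = 0:n)
    combos <- combos[combos$nl + combos$no <= n, ]
    for (i in seq_len(nrow(combos))) {
      nl <- combos$nl[i]; no <- combos$no[i]; nh <- n - nl - no
      pred <- c(rep("low", nl), rep("optimal", no), rep("high", nh))
      sc <- deviationScores(pred, rep(1, n))$score
      expect_equal(sc, (nh - nl) / n)
      expect_gte(sc, -1); expect_lte(sc, 1)
    }
  }
  # concentrations with no wells are simply absent
  ds <- deviationScores(c("low", "high"), c(2, 8))
  expect_equal(ds$chir_um, c(2, 8))
})

test_that("classification metrics match hand-worked values", {
  # perfect predictions
  withSeed(53L, {
    y <- rep(c("low", "optimal", "high"), each = 20)
    prob <- matrix(0, 60, 3, dimnames = list(NULL, c("high", "low", "optimal")))
    prob[cbind(seq_len(60), match(y, colnames(prob)))] <- 1
  })
  mPerf <- classificationMetrics(y, y, prob)
  expect_equal(unlist(mPerf), c(accuracy = 1, precision = 1, recall = 1,
                                f1 = 1, auc = 1))

  # hand-worked 3x3 confusion matrix:
  #           pred a  b  c
  # true a        5  3  2    (10)
  # true b        1  8  1    (10)
  # true c        0  2  8    (10)
  yh <- rep(c("a", "b", "c"), each = 10)
  ph <- c(rep("a", 5), rep("b", 3), rep("c", 2),
          rep("a", 1), rep("b", 8), rep("c", 1),
          rep("b", 2), rep("c", 8))
  m <- classificationMetrics(yh, ph)
  expect_equal(m$accuracy, 21 / 30)
  precA <- 5 / 6; precB <- 8 / 13; precC <- 8 / 11
  recA <- 0.5; recB <- 0.8; recC <- 0.8
  expect_equal(m$precision, mean(c(precA, precB, precC)))
  expect_equal(m$recall, mean(c(recA, recB, recC)))
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(m$f1, mean(c(f1(precA, recA), f1(precB, recB), f1(precC, recC))))

  # random predictions on balanced classes sit near chance
  withSeed(54L, {
    yr <- rep(c("a", "b", "c"), each = 400)
    pr <- sample(c("a", "b", "c"), 1200, replace = TRUE)
  })
  expect_lt(abs(classificationMetrics(yr, pr)$accuracy - 1 / 3), 0.05)

  # absent class is skipped with a warning
  expect_warning(classificationMetrics(c("a", "a"), c("a", "b"),
                                       classes = c("a", "b", "c")),
                 "absent")
})

test_that("leave-one-batch-out validation recovers a shared dose-response", {
  mkBatch <- function(seed) {
    withSeed(seed, {
      conc <- rep(c(2, 4, 6, 8, 10), each = 8)
      dch <- ifelse(conc < 6, conc - 6, ifelse(conc > 6, conc - 6, 0))
      cls <- ifelse(dch < 0, "low", ifelse(dch > 0, "high", "optimal"))
      data.frame(f1 = dch + rnorm(40, 0, 0.4),
                 f2 = 0.5 * dch + rnorm(40, 0, 0.8),
                 f3 = rnorm(40), f4 = rnorm(40), f5 = rnorm(40),
                 chir_um = conc, class = cls, delta_chir = dch)
    })
  }
  tables <- list(b1 = mkBatch(61L), b2 = mkBatch(62L), b3 = mkBatch(63L))
  cv <- crossBatchValidate(tables, nFeatures = 2L)
  expect_gte(cv$pearson, 0.8)
  expect_setequal(unique(cv$pairs$batch), c("b1", "b2", "b3"))
  # two batches give exactly two rounds
  cv2 <- crossBatchValidate(tables[1:2], nFeatures = 2L)
  expect_equal(length(unique(cv2$pairs$batch)), 2L)
  expect_error(crossBatchValidate(tables[1]), "2 batches")
})

test_that("duration choice minimizes |score| with ties to the shorter duration", {
  expect_equal(chooseDuration(c("24" = -0.6, "36" = 0.1, "48" = 0.7)), 36)
  expect_equal(chooseDuration(c("24" = 0.4)), 24)
  expect_equal(chooseDuration(c("24" = -0.2, "36" = 0.2)), 24)
})
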