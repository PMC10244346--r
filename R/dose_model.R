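# CHIR-dose assessment: optimal-range labeling, the regularized logistic
# dose classifier on stream features, Deviation Scores and leave-one-batch-
# out validation.

#' Label CHIR concentrations against the optimal range
#'
#' For one CHIR duration, concentrations whose mean percentage of positive
#' cells (the \code{valueCol} column, an image-based positive fraction by
#' default) reaches \code{efficiencyThreshold} form the optimal range
#' [c1, c2]; every concentration is then classed low / optimal / high, with
#' the signed distance to the range as its delta-CHIR concentration:
#' c - c1 below the range, 0 inside, c - c2 above.
#'
#' @param records data.frame with columns \code{chir_um}, \code{chir_h} and
#'   \code{valueCol}
#' @param duration CHIR duration (h) to label
#' @param efficiencyThreshold qualifying mean value, default 0.20
#' @param valueCol efficiency column, default \code{"positive_fraction"}
#' @return Object of class \code{DoseLabeling}: list with \code{c1},
#'   \code{c2}, \code{duration} and a per-concentration \code{table}
#'   (chir_um, mean_value, class, delta_chir).
#' @export
labelDoses <- function(records, duration = records$chir_h[1],
                       efficiencyThreshold = 0.20,
                       valueCol = "positive_fraction") {
  stopifnot(valueCol %in% names(records))
  r <- records[records$chir_h == duration, , drop = FALSE]
  if (nrow(r) == 0) stop("no records at duration ", duration)
  conc <- sort(unique(r$chir_um))
  mv <- vapply(conc, function(cc) mean(r[[valueCol]][r$chir_um == cc]), numeric(1))
  qual <- conc[mv >= efficiencyThreshold]
  if (length(qual) == 0)
    stop(sprintf("no optimal range: no concentration reaches mean %s >= %.2f at %g h",
                 valueCol, efficiencyThreshold, duration))
  c1 <- min(qual); c2 <- max(qual)
  inside <- conc[conc >= c1 & conc <= c2]
  if (!all(inside %in% qual))
    warning("qualifying concentrations are non-contiguous; range spans min..max")
  cls <- ifelse(conc < c1, "low", ifelse(conc > c2, "high", "optimal"))
  dch <- ifelse(conc < c1, conc - c1, ifelse(conc > c2, conc - c2, 0))
  structure(list(c1 = c1, c2 = c2, duration = duration,
                 table = data.frame(chir_um = conc, mean_value = mv,
                                    class = cls, delta_chir = dch)),
            class = "DoseLabeling")
}

#' @export
print.DoseLabeling <- function(x, ...) {
  cat(sprintf("DoseLabeling (%g h): optimal range [%g, %g] uM\n",
              x$duration, x$c1, x$c2))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Class and delta-CHIR of concentrations under a labeling
#'
#' @param labeling a \code{DoseLabeling}
#' @param conc concentrations (micromolar)
#' @return \code{doseClass}: character classes; \code{deltaChir}: signed
#'   distances (micromolar).
#' @export
doseClass <- function(labeling, conc) {
  ifelse(conc < labeling$c1, "low", ifelse(conc > labeling$c2, "high", "optimal"))
}

#' @rdname doseClass
#' @export
deltaChir <- function(labeling, conc) {
  ifelse(conc < labeling$c1, conc - labeling$c1,
         ifelse(conc > labeling$c2, conc - labeling$c2, 0))
}

#' Regularization presets for the dose classifier
#'
#' Named presets: \code{"21feat-24h"} (l1, 1/4), \code{"21feat-36h"} and
#' \code{"21feat-48h"} (l1, 1/8), \code{"4feat"} (l2, 0.1) and
#' \code{"cross-batch"} (elastic net, l1-ratio 0.1, weight 0.05).
#'
#' @param name preset name
#' @return List with \code{kind}, \code{alpha} (glmnet mixing) and
#'   \code{strength}.
#' @export
dosePreset <- function(name = c("21feat-24h", "21feat-36h", "21feat-48h",
                                "4feat", "cross-batch")) {
  name <- match.arg(name)
  switch(name,
    "21feat-24h" = list(name = name, kind = "l1", alpha = 1, strength = 1 / 4),
    "21feat-36h" = list(name = name, kind = "l1", alpha = 1, strength = 1 / 8),
    "21feat-48h" = list(name = name, kind = "l1", alpha = 1, strength = 1 / 8),
    "4feat" = list(name = name, kind = "l2", alpha = 0, strength = 0.1),
    "cross-batch" = list(name = name, kind = "elastic-net", alpha = 0.1,
                         strength = 0.05))
}

#' Train the multinomial dose classifier
#'
#' A linear multinomial logistic model with inverse-class-frequency
#' observation weights (so each class contributes equally) and the preset's
#' regularization; the per-observation penalty is \code{strength / n}.
#'
#' @param X feature matrix (samples x features)
#' @param y class labels (low / optimal / high; >= 2 classes required)
#' @param reg preset from \code{\link{dosePreset}} or a compatible list
#' @return Object of class \code{doseClassifier}.
#' @export
trainDoseClassifier <- function(X, y, reg = dosePreset("21feat-24h")) {
  X <- as.matrix(X); y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need at least 2 classes")
  n <- nrow(X)
  freq <- table(y)
  w <- as.numeric(n / (nlevels(y) * freq[y]))
  lam <- reg$strength / n
  fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = reg$alpha,
                        lambda = lam, weights = w, standardize = TRUE)
  cw <- n / (nlevels(y) * as.numeric(freq)); names(cw) <- names(freq)
  structure(list(fit = fit, lambda = lam, classes = levels(y),
                 featureNames = colnames(X), preset = reg, classWeights = cw),
            class = "doseClassifier")
}

#' @export
print.doseClassifier <- function(x, ...) {
  cat(sprintf("doseClassifier: %s regularization (%s), %d features, classes: %s\n",
              x$preset$kind, x$preset$name %||% "custom",
              length(x$featureNames), paste(x$classes, collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict dose classes or probabilities
#'
#' @param object a \code{doseClassifier}
#' @param newX feature matrix
#' @param type \code{"class"} or \code{"prob"}
#' @param ... unused
#' @return Character vector of classes or a probability matrix.
#' @export
predict.doseClassifier <- function(object, newX, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newX <- as.matrix(newX)
  pr <- predict(object$fit, newX, s = object$lambda, type = "response")[, , 1]
  if (is.null(dim(pr))) pr <- matrix(pr, 1, dimnames = list(NULL, object$classes))
  if (type == "prob") pr else colnames(pr)[max.col(pr, ties.method = "first")]
}

#' One-way ANOVA feature selection
#'
#' Ranks features by the one-way ANOVA F statistic across the classes and
#' returns the indices of the k largest (ties broken toward the lower
#' index).
#'
#' @param X feature matrix
#' @param y class labels
#' @param k number of features to keep (default 4)
#' @return Integer indices of the selected features, F statistics attached
#'   as attribute \code{"F"}.
#' @export
selectFeaturesAnova <- function(X, y, k = 4L) {
  X <- as.matrix(X); y <- as.factor(y)
  if (k > ncol(X)) stop("k exceeds the number of features")
  n <- nrow(X); g <- nlevels(y)
  gm <- rowsum(X, y) / as.numeric(table(y))
  mu <- colMeans(X)
  ssb <- colSums(as.numeric(table(y)) * sweep(gm, 2, mu)^2)
  ssw <- colSums((X - gm[y, , drop = FALSE])^2)
  Fv <- (ssb / (g - 1)) / (ssw / (n - g))
  Fv[!is.finite(Fv)] <- Inf  # zero within-class variance: maximally discriminative
  idx <- order(-Fv)[seq_len(k)]  # order() is stable: ties keep lower index
  attr(idx, "F") <- Fv
  idx
}

#' Deviation Scores per CHIR concentration
#'
#' For each concentration c with N_c predicted wells, of which N_c^low /
#' N_c^optimal / N_c^high are predicted low / optimal / high, the Deviation
#' Score is (N_c^high - N_c^low) / N_c, in [-1, 1].
#'
#' @param predictions predicted class per well
#' @param concentrations CHIR concentration per well (micromolar)
#' @return Object of class \code{DeviationResult}: data.frame with columns
#'   chir_um, n, n_low, n_optimal, n_high, score.
#' @export
deviationScores <- function(predictions, concentrations) {
  stopifnot(length(predictions) == length(concentrations))
  conc <- sort(unique(concentrations))
  rows <- lapply(conc, function(cc) {
    p <- predictions[concentrations == cc]
    nl <- sum(p == "low"); nh <- sum(p == "high"); no <- sum(p == "optimal")
    data.frame(chir_um = cc, n = length(p), n_low = nl, n_optimal = no,
               n_high = nh, score = (nh - nl) / length(p))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("DeviationResult", "data.frame")
  out
}

# rank-statistic AUC of scores for a binary indicator
.binaryAUC <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a dose classifier
#'
#' Accuracy plus macro-averaged (unweighted over classes) precision,
#' recall, F1 and one-vs-rest AUC.  Classes absent from \code{y} are
#' skipped with a warning.
#'
#' @param model a \code{doseClassifier}
#' @param X feature matrix
#' @param y true classes
#' @return Named list: accuracy, precision, recall, f1, auc.
#' @export
evaluateClassifier <- function(model, X, y) {
  pred <- predict(model, X, type = "class")
  prob <- predict(model, X, type = "prob")
  classificationMetrics(y, pred, prob, classes = model$classes)
}

#' Leave-one-batch-out validation of the dose pipeline
#'
#' Each round holds one batch out; ANOVA feature selection and classifier
#' training run on the remaining batches, Deviation Scores are computed on
#' the held-out batch, and every tested concentration contributes a
#' (predicted score, true delta-CHIR) pair.
#'
#' @param tables named list (one per batch) of data.frames containing the
#'   feature columns plus \code{chir_um}, \code{class} (true dose class)
#'   and \code{delta_chir}
#' @param reg regularization preset, default \code{dosePreset("cross-batch")}
#' @param nFeatures features kept per round (default 4)
#' @param featureCols feature column names; defaults to all columns except
#'   the three metadata columns
#' @return List with \code{pairs} (batch, chir_um, score, delta_chir) and
#'   pooled \code{pearson} correlation.
#' @export
crossBatchValidate <- function(tables, reg = dosePreset("cross-batch"),
                               nFeatures = 4L, featureCols = NULL) {
  if (length(tables) < 2) stop("need at least 2 batches")
  if (is.null(names(tables))) names(tables) <- seq_along(tables)
  meta <- c("chir_um", "class", "delta_chir", "batch")
  if (is.null(featureCols))
    featureCols <- setdiff(names(tables[[1]]), meta)
  pairs <- NULL
  for (b in names(tables)) {
    train <- do.call(rbind, tables[names(tables) != b])
    test <- tables[[b]]
    Xtr <- as.matrix(train[, featureCols]); ytr <- train$class
    sel <- selectFeaturesAnova(Xtr, ytr, k = min(nFeatures, length(featureCols)))
    model <- trainDoseClassifier(Xtr[, sel, drop = FALSE], ytr, reg = reg)
    pred <- predict(model, as.matrix(test[, featureCols])[, sel, drop = FALSE])
    ds <- deviationScores(pred, test$chir_um)
    truth <- vapply(ds$chir_um, function(cc)
      test$delta_chir[test$chir_um == cc][1], numeric(1))
    pairs <- rbind(pairs, data.frame(batch = b, chir_um = ds$chir_um,
                                     score = ds$score, delta_chir = truth))
  }
  list(pairs = pairs, pearson = cor(pairs$score, pairs$delta_chir))
}

#' Choose the CHIR duration whose Deviation Score is closest to zero
#'
#' Ties are broken toward the shorter duration.
#'
#' @param scores named numeric vector: names are durations (h), values are
#'   Deviation Scores
#' @return The chosen duration (numeric).
#' @export
#' @examples
#' chooseDuration(c("24" = -0.6, "36" = 0.1, "48" = 0.7))  # 36
chooseDuration <- function(scores) {
  stopifnot(length(scores) >= 1)
  dur <- as.numeric(names(scores))
  dur[order(abs(scores), dur)][1]
}

#' Classification metrics from labels, predictions and probabilities
#'
#' Accuracy plus macro-averaged precision, recall, F1 and one-vs-rest AUC
#' over the given class set; classes absent from \code{y} are skipped with
#' a warning.  This is the metric core behind
#' \code{\link{evaluateClassifier}}.
#'
#' @param y true classes
#' @param pred predicted classes
#' @param prob matrix of class probabilities (columns named by class);
#'   optional, AUC is NA without it
#' @param classes class set (default: columns of \code{prob} or classes in
#'   \code{y})
#' @return Named list: accuracy, precision, recall, f1, auc.
#' @export
classificationMetrics <- function(y, pred, prob = NULL, classes = NULL) {
  y <- as.character(y); pred <- as.character(pred)
  if (is.null(classes))
    classes <- if (!is.null(prob)) colnames(prob) else sort(unique(y))
  present <- classes %in% y
  if (!all(present))
    warning("classes absent from y skipped: ",
            paste(classes[!present], collapse = ", "))
  per <- vapply(classes[present], function(cl) {
    tp <- sum(pred == cl & y == cl)
    fp <- sum(pred == cl & y != cl)
    fn <- sum(pred != cl & y == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    auc <- if (is.null(prob)) NA_real_ else .binaryAUC(prob[, cl], y == cl)
    c(precision = prec, recall = rec, f1 = f1, auc = auc)
  }, numeric(4))
  list(accuracy = mean(pred == y),
       precision = mean(per["precision", ]),
       recall = mean(per["recall", ]),
       f1 = mean(per["f1", ]),
       auc = mean(per["auc", ], na.rm = TRUE))
}
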