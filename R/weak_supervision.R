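# Weakly supervised fate-region localization: patch-level labels are built
# from annotation masks, a small CNN classifies patches as containing
# committed regions or not, and gradient-weighted class-activation maps
# localize the signal inside positive patches; patch results are stitched
# back to whole-well predictions.

#' Build a labeled patch dataset from images and masks
#'
#' Tiles each image (and its aligned mask) and labels every patch:
#' positive when the fraction of \code{positiveCode} pixels reaches
#' \code{positiveFrac}; negative when the patch satisfies the negative
#' rule (\code{"only_black"}: the mask contains only black pixels;
#' \code{"no_positive"}: no positive-code pixel at all, the definitive-
#' endoderm convention); all other patches are discarded.
#'
#' @param images list of \linkS4class{WellImage} or matrices
#' @param masks list of \linkS4class{RegionMask} or matrices, aligned
#' @param patch patch side (pixels)
#' @param overlap tiling overlap fraction
#' @param positiveFrac positive labeling threshold (default 0.30; the
#'   endoderm variant uses 0.20)
#' @param positiveCode mask code counted as positive (default dark gray)
#' @param negativeRule \code{"only_black"} or \code{"no_positive"}
#' @return Object of class \code{PatchDataset}: list with \code{patches},
#'   \code{labels} (factor negative/positive), \code{well}, \code{origins}
#'   and the labeling parameters.
#' @export
buildPatchDataset <- function(images, masks, patch, overlap = 0.5,
                              positiveFrac = 0.30,
                              positiveCode = maskPalette()[["dark_gray"]],
                              negativeRule = c("only_black", "no_positive")) {
  negativeRule <- match.arg(negativeRule)
  stopifnot(length(images) == length(masks))
  black <- maskPalette()[["black"]]
  patches <- list(); labels <- character(0); wells <- character(0)
  origins <- NULL
  for (i in seq_along(images)) {
    im <- .asMatrix(images[[i]])
    mk <- if (is(masks[[i]], "RegionMask")) maskLabels(masks[[i]]) else masks[[i]]
    if (!all(dim(im) == dim(mk))) stop("image/mask shapes differ for item ", i)
    wid <- if (is(images[[i]], "WellImage")) wellId(images[[i]]) else as.character(i)
    tI <- cropPatches(im, patch, overlap)
    tM <- cropPatches(mk, patch, overlap)
    for (pIdx in seq_along(tI$patches)) {
      mp <- tM$patches[[pIdx]]
      posFrac <- mean(mp == positiveCode)
      lab <- if (posFrac >= positiveFrac) "positive"
      else if (negativeRule == "only_black" && all(mp == black)) "negative"
      else if (negativeRule == "no_positive" && posFrac == 0) "negative"
      else NA_character_
      if (is.na(lab)) next
      patches[[length(patches) + 1L]] <- tI$patches[[pIdx]]
      labels <- c(labels, lab)
      wells <- c(wells, wid)
      origins <- rbind(origins, tI$origins[pIdx, ])
    }
  }
  structure(list(patches = patches,
                 labels = factor(labels, levels = c("negative", "positive")),
                 well = wells, origins = origins, patch = patch,
                 positiveFrac = positiveFrac, positiveCode = positiveCode,
                 negativeRule = negativeRule),
            class = "PatchDataset")
}

#' @export
print.PatchDataset <- function(x, ...) {
  cat(sprintf("PatchDataset: %d patches (%d positive, %d negative), %d px, rule %s >= %.0f%%\n",
              length(x$patches), sum(x$labels == "positive"),
              sum(x$labels == "negative"), x$patch, x$negativeRule,
              100 * x$positiveFrac))
  invisible(x)
}

#' Binary region mask from a nuclear fluorescence image
#'
#' Thresholds the fluorescence image and applies morphological closing with
#' a disc, merging nearby nuclear signals into contiguous cell regions (the
#' SOX17 convention for definitive-endoderm labeling).
#'
#' @param fluor \linkS4class{WellImage} or matrix, intensities in [0,1]
#' @param threshold binarization threshold (default 0.5)
#' @param closingRadius disc radius of the closing element (default 5)
#' @return Binary \linkS4class{RegionMask} (codes black/white).
#' @export
maskFromFluorescence <- function(fluor, threshold = 0.5, closingRadius = 5L) {
  p <- .asMatrix(fluor)
  bin <- p > threshold
  if (any(bin) && closingRadius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closingRadius) + 1L, "disc")
    bin <- .m(EBImage::closing(EBImage::Image(bin * 1), brush)) > 0.5
  }
  wid <- if (is(fluor, "WellImage")) wellId(fluor) else "well"
  RegionMask(bin, wellId = wid)
}

#' Small CNN backbone for patch classification
#'
#' Three 3x3 convolution blocks with 2x average pooling, ending in global
#' average pooling and a 2-class linear head; the activations feeding the
#' global pool are the class-activation-map layer.  Satisfies the backbone
#' contract (class probabilities + target-layer activations + their
#' gradients); a large residual network can be substituted by supplying a
#' different builder.
#'
#' @param channels channel widths of the three blocks
#' @return Builder function used by \code{\link{trainPatchClassifier}}.
#' @export
smallPatchBackbone <- function(channels = c(8L, 16L, 16L)) {
  function() {
    net <- .buildSequential(list(
      list("conv", out = channels[1], k = 3L), list("relu"), list("pool"),
      list("conv", out = channels[2], k = 3L), list("relu"), list("pool"),
      list("conv", out = channels[3], k = 3L), list("relu"),
      list("gap"), list("dense", out = 2L)), inC = 1L)
    list(net = net, camLayer = 8L)  # output of the last ReLU before GAP
  }
}

#' Training configuration for the patch classifier
#'
#' The \code{"desk"} preset (the tested path) trains the small CNN on
#' 64-px patches in minutes on one CPU; the \code{"paper"} preset carries
#' the published large-scale settings (300 epochs, mini-batch 6, learning
#' rate 3e-5) for use with an external large backbone.
#'
#' @param preset \code{"desk"} or \code{"paper"}
#' @return List of training parameters.
#' @export
patchTrainConfig <- function(preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (preset == "desk")
    list(preset = "desk", inputSide = 64L, epochs = 12L, batch = 8L,
         lr = 2e-3, valFraction = 0.2, seed = 1L)
  else
    list(preset = "paper", inputSide = 512L, epochs = 300L, batch = 6L,
         lr = 3e-5, valFraction = 0.2, seed = 1L)
}

.resizeTo <- function(p, side) {
  if (nrow(p) == side && ncol(p) == side) return(p)
  .m(EBImage::resize(EBImage::Image(p), w = side, h = side))
}

#' Train the weakly supervised patch classifier
#'
#' Binary (negative/positive) classification of bright-field patches with
#' softmax cross-entropy and Adam, on an 80/20 train/validation split
#' (seeded).  The model exposes class probabilities, the activations of the
#' last convolutional layer before global average pooling, and gradients of
#' the positive-class pre-softmax score with respect to them — everything
#' class-activation mapping needs.
#'
#' @param dataset a \code{PatchDataset} with both labels present
#' @param backbone backbone builder, default \code{\link{smallPatchBackbone}()}
#' @param config from \code{\link{patchTrainConfig}}
#' @return Object of class \code{patchClassifier} with training history.
#' @export
trainPatchClassifier <- function(dataset, backbone = smallPatchBackbone(),
                                 config = patchTrainConfig("desk")) {
  labs <- dataset$labels
  if (nlevels(droplevels(labs)) < 2) stop("dataset must contain both labels")
  side <- config$inputSide
  X <- lapply(dataset$patches, .resizeTo, side = side)
  y <- as.integer(labs)  # 1 = negative, 2 = positive
  withSeed(config$seed, {
    bb <- backbone()
    net <- bb$net
    n <- length(X)
    idx <- sample.int(n)
    nVal <- max(1L, floor(config$valFraction * n))
    valI <- idx[seq_len(nVal)]; trI <- idx[-seq_len(nVal)]
    state <- .adamInit(net)
    t <- 0L
    hist <- NULL
    for (ep in seq_len(config$epochs)) {
      ord <- sample(trI)
      epLoss <- 0
      for (start in seq(1, length(ord), by = config$batch)) {
        bi <- ord[start:min(start + config$batch - 1L, length(ord))]
        gAcc <- NULL
        bLoss <- 0
        for (s in bi) {
          x <- array(X[[s]], c(side, side, 1L))
          fw <- .seqForward(net, x, train = TRUE)
          logit <- fw$out
          pr <- exp(logit - max(logit)); pr <- pr / sum(pr)
          bLoss <- bLoss - log(max(pr[y[s]], 1e-12))
          dlogit <- pr; dlogit[y[s]] <- dlogit[y[s]] - 1
          bw <- .seqBackward(net, fw, dlogit)
          gAcc <- if (is.null(gAcc)) bw$grads else
            mapply(function(a, b) {
              if (is.null(a)) return(NULL)
              mapply(`+`, a, b, SIMPLIFY = FALSE)
            }, gAcc, bw$grads, SIMPLIFY = FALSE)
        }
        gAcc <- lapply(gAcc, function(g)
          if (is.null(g)) NULL else lapply(g, `/`, length(bi)))
        t <- t + 1L
        up <- .adamStep(net, gAcc, state, lr = config$lr, t = t)
        net <- up$net; state <- up$state
        epLoss <- epLoss + bLoss
      }
      # validation accuracy
      valAcc <- mean(vapply(valI, function(s) {
        fw <- .seqForward(net, array(X[[s]], c(side, side, 1L)))
        which.max(fw$out) == y[s]
      }, logical(1)))
      hist <- rbind(hist, data.frame(epoch = ep,
                                     train_loss = epLoss / length(trI),
                                     val_accuracy = valAcc))
    }
    structure(list(net = net, camLayer = bb$camLayer,
                   classes = c("negative", "positive"), inputSide = side,
                   history = hist, config = config),
              class = "patchClassifier")
  })
}

#' @export
print.patchClassifier <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf("patchClassifier: %d-px input, %d epochs, final val accuracy %.3f\n",
              x$inputSide, nrow(x$history), h$val_accuracy))
  invisible(x)
}

#' Class probabilities for one patch
#'
#' @param model a \code{patchClassifier}
#' @param patch matrix (resized to the model input internally)
#' @return Named probabilities (negative, positive).
#' @export
predictPatch <- function(model, patch) {
  x <- array(.resizeTo(.asMatrix(patch), model$inputSide),
             c(model$inputSide, model$inputSide, 1L))
  logit <- .seqForward(model$net, x)$out
  pr <- exp(logit - max(logit)); pr <- pr / sum(pr)
  names(pr) <- model$classes
  pr
}

#' Gradient-weighted class-activation map of one patch
#'
#' For a patch predicted positive, channel weights are the spatial means of
#' the gradient of the positive-class pre-softmax score with respect to the
#' last convolutional activations, and the heatmap is the ReLU of the
#' weighted activation sum, upsampled to patch size; patches predicted
#' negative get an all-zero map.  The map is normalized to 0-255 (an
#' all-zero map stays zero) and binarized at \code{binThreshold}.
#'
#' @param model a \code{patchClassifier}
#' @param patch matrix or \linkS4class{WellImage} patch
#' @param binThreshold binarization threshold on the 0-255 scale (default 10)
#' @return Object of class \code{CamResult}: list with \code{heatmap}
#'   (patch-shaped, non-negative), \code{normalized8}, \code{binary},
#'   \code{score} (positive-class pre-softmax score) and \code{predicted}.
#' @export
gradCAM <- function(model, patch, binThreshold = 10) {
  p0 <- .asMatrix(patch)
  outSide <- nrow(p0)
  x <- array(.resizeTo(p0, model$inputSide),
             c(model$inputSide, model$inputSide, 1L))
  fw <- .seqForward(model$net, x)
  logit <- fw$out
  predicted <- model$classes[which.max(logit)]
  score <- logit[2]
  if (predicted == "negative") {
    z <- matrix(0, outSide, ncol(p0))
    res <- list(heatmap = z, normalized8 = z, binary = z > 0,
                score = score, predicted = predicted)
    class(res) <- "CamResult"
    return(res)
  }
  dlogit <- c(0, 1)  # d(score_positive)/d(logits), pre-softmax
  bw <- .seqBackward(model$net, fw, dlogit)
  A <- fw$acts[[model$camLayer]]
  dA <- bw$dAt[[model$camLayer]]  # gradient wrt the camLayer activations
  alpha <- colMeans(matrix(dA, dim(dA)[1] * dim(dA)[2], dim(dA)[3]))
  heat <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(dim(A)[3])) heat <- heat + alpha[k] * A[, , k]
  heat[heat < 0] <- 0
  heatUp <- .m(EBImage::resize(EBImage::Image(heat),
                                      w = outSide, h = ncol(p0)))
  heatUp[heatUp < 0] <- 0
  norm8 <- if (max(heatUp) > 0) 255 * heatUp / max(heatUp) else heatUp
  res <- list(heatmap = heatUp, normalized8 = norm8,
              binary = norm8 > binThreshold, score = score,
              predicted = predicted)
  class(res) <- "CamResult"
  res
}

#' @export
print.CamResult <- function(x, ...) {
  cat(sprintf("CamResult: predicted %s (score %.3f), positive fraction %.3f\n",
              x$predicted, x$score, mean(x$binary)))
  invisible(x)
}

#' Whole-well region prediction
#'
#' Tiles the well, runs class-activation mapping per patch, and
#' reconstructs whole-well results: heatmaps by mean, binary predictions by
#' logical OR over overlaps.
#'
#' @param model a \code{patchClassifier}
#' @param whole \linkS4class{WellImage} or matrix
#' @param patch patch side (default the model input side)
#' @param overlap tiling overlap (default 0.5)
#' @param binThreshold per-patch binarization threshold (default 10)
#' @return List with \code{heatmap}, \code{binary} and \code{fraction}
#'   (predicted positive-region fraction).
#' @export
predictRegions <- function(model, whole, patch = model$inputSide,
                           overlap = 0.5, binThreshold = 10) {
  p <- .asMatrix(whole)
  tiling <- cropPatches(p, patch, overlap)
  heats <- vector("list", length(tiling$patches))
  bins <- vector("list", length(tiling$patches))
  for (i in seq_along(tiling$patches)) {
    cam <- gradCAM(model, tiling$patches[[i]], binThreshold)
    heats[[i]] <- cam$heatmap
    bins[[i]] <- cam$binary * 1
  }
  heat <- reconstructPatches(heats, tiling$origins, dim(p), "mean")
  bin <- reconstructPatches(bins, tiling$origins, dim(p), "any_positive")
  list(heatmap = heat, binary = bin, fraction = mean(bin))
}

#' Pixel-level segmentation metrics
#'
#' Counts TP/FP/FN/TN of a binary prediction against ground truth and
#' reports accuracy, precision, recall, F1, specificity and IoU by the
#' standard formulas.  In \code{"cpc"} mode the ground-truth positives are
#' the dark-gray and light-gray mask regions; \code{"binary"} mode takes
#' nonzero mask values as positives.  Images fully covered by positives or
#' without positives are flagged \code{discarded}.
#'
#' @param pred logical matrix (predicted positive regions)
#' @param gt \linkS4class{RegionMask} or matrix
#' @param mode \code{"cpc"} or \code{"binary"}
#' @return List with the six metrics, the four counts and \code{discarded}.
#' @export
segmentationMetrics <- function(pred, gt, mode = c("cpc", "binary")) {
  mode <- match.arg(mode)
  g <- if (is(gt, "RegionMask")) maskLabels(gt) else gt
  if (!all(dim(pred) == dim(g))) stop("prediction and ground truth shapes differ")
  pal <- maskPalette()
  gtPos <- if (mode == "cpc")
    g == pal[["dark_gray"]] | g == pal[["light_gray"]]
  else g != 0
  pr <- pred > 0
  TP <- sum(pr & gtPos); FP <- sum(pr & !gtPos)
  FN <- sum(!pr & gtPos); TN <- sum(!pr & !gtPos)
  list(accuracy = (TN + TP) / (TN + FN + TP + FP),
       precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
       recall = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       f1 = TP / (TP + (FN + FP) / 2),
       specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
       iou = if (TP + FP + FN > 0) TP / (TP + FP + FN) else NA_real_,
       TP = TP, FP = FP, FN = FN, TN = TN,
       discarded = all(gtPos) || !any(gtPos))
}

#' Rank screening wells by predicted positive-region fraction
#'
#' Wells are sorted by descending predicted fraction (ties broken by well
#' id); the top-k flag marks initial candidates and the threshold flag
#' marks wells whose predicted committed-region percentage reaches
#' \code{candidateThreshold}.  Control wells are carried through unranked.
#'
#' @param fractions named numeric vector: predicted positive fraction per
#'   well
#' @param controls character vector of control well ids
#' @param k size of the top selection (default 40)
#' @param candidateThreshold fraction threshold (default 0.40)
#' @return data.frame with well, fraction, rank (NA for controls),
#'   \code{top_k} and \code{candidate} flags.
#' @export
rankWells <- function(fractions, controls = character(0), k = 40L,
                      candidateThreshold = 0.40) {
  stopifnot(!is.null(names(fractions)), all(fractions >= 0 & fractions <= 1))
  df <- data.frame(well = names(fractions), fraction = as.numeric(fractions),
                   stringsAsFactors = FALSE)
  isCtl <- df$well %in% controls
  ranked <- df[!isCtl, ]
  ord <- order(-ranked$fraction, ranked$well)
  ranked <- ranked[ord, ]
  ranked$rank <- seq_len(nrow(ranked))
  ctl <- df[isCtl, ]
  if (nrow(ctl) > 0) ctl$rank <- NA_integer_
  out <- rbind(ranked, ctl)
  out$top_k <- !is.na(out$rank) & out$rank <= k
  out$candidate <- !is.na(out$rank) & out$fraction >= candidateThreshold
  rownames(out) <- NULL
  out
}
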