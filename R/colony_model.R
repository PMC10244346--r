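# 0 h PSC colony morphology: per-component shape statistics, the 343-D
# morphological profile, and random-forest feature importance / efficiency
# prediction.

# per-component geometry of a binary mask; components under minComponent
# pixels are dropped as noise specks
.componentShapes <- function(mask, minComponent = 50L) {
  lbl <- .label8(mask)  # components by 8-connectivity
  n <- max(lbl)
  if (n == 0) return(NULL)
  oc <- EBImage::ocontour(EBImage::Image(lbl))
  areas <- tabulate(as.integer(lbl)[as.integer(lbl) > 0], nbins = n)
  rows <- list()
  for (k in seq_len(n)) {
    if (areas[k] < minComponent) next
    xy <- oc[[k]]
    if (is.null(xy) || nrow(xy) < 3) next
    npts <- nrow(xy)
    # polygonal perimeter, resampled (~5 px arc) for smooth-shape stability
    idx <- if (npts >= 25) seq(1L, npts, by = 5L) else seq_len(npts)
    perim <- .polyPerimeter(xy[idx, , drop = FALSE])
    if (perim <= 0) next
    hull <- xy[grDevices::chull(xy), , drop = FALSE]
    hullPerim <- .polyPerimeter(hull)
    # lattice-point count inside the hull (Pick-style correction), so a
    # convex component has solidity exactly 1
    hullArea <- .polyArea(hull) + .polyPerimeter(hull) / 2 + 1
    pix <- which(lbl == k, arr.ind = TRUE)
    centroid <- colMeans(pix)
    # circularity uses the polygon (contour center-line) area so that the
    # area and perimeter estimators are consistent: a digitized disc then
    # scores 1 instead of overshooting by its half-pixel boundary band
    polyA <- .polyArea(xy[idx, , drop = FALSE])
    # ocontour coordinates are (x, y) 0-based
    ccd <- sqrt((xy[, 2] + 1 - centroid[1])^2 + (xy[, 1] + 1 - centroid[2])^2)
    rows[[length(rows) + 1L]] <- data.frame(
      component = k, area = areas[k], perimeter = perim,
      solidity = min(areas[k] / hullArea, 1),
      convexity = min(hullPerim / perim, 1),
      circularity = 4 * pi * polyA / perim^2,
      maxCCD = max(ccd), minCCD = min(ccd),
      minMaxCCD = min(ccd) / max(ccd), meanCCD = mean(ccd),
      stdCCD = sqrt(mean((ccd - mean(ccd))^2)))
  }
  if (length(rows) == 0) NULL else do.call(rbind, rows)
}

#' Shape statistics of a binary cell-region mask
#'
#' Per connected component: solidity (area over convex-hull area),
#' convexity (hull perimeter over perimeter), circularity
#' (4 pi area / perimeter^2) and the centroid-contour distance (CCD)
#' statistics {max, min, min/max, mean, sd}; image-level values are the
#' component values averaged with the component's area as weight.
#'
#' @param mask logical matrix (cell regions)
#' @param minComponent smallest component kept, in pixels (default 50)
#' @return List with \code{perComponent} (data.frame) and
#'   \code{imageLevel} (named numeric); all-zero image level (with a
#'   warning) for an empty mask.
#' @export
shapeStats <- function(mask, minComponent = 50L) {
  empty <- c(Solidity = 0, Convexity = 0, Circularity = 0, MaxCCD = 0,
             MinCCD = 0, MinMaxCCD = 0, MeanCCD = 0, StdCCD = 0)
  comp <- if (any(mask)) .componentShapes(mask, minComponent) else NULL
  if (is.null(comp)) {
    warning("no components of at least ", minComponent, " px; shape stats are 0")
    return(list(perComponent = NULL, imageLevel = empty))
  }
  w <- comp$area / sum(comp$area)
  lvl <- c(Solidity = sum(w * comp$solidity),
           Convexity = sum(w * comp$convexity),
           Circularity = sum(w * comp$circularity),
           MaxCCD = sum(w * comp$maxCCD), MinCCD = sum(w * comp$minCCD),
           MinMaxCCD = sum(w * comp$minMaxCCD),
           MeanCCD = sum(w * comp$meanCCD), StdCCD = sum(w * comp$stdCCD))
  list(perComponent = comp, imageLevel = lvl)
}

#' Spacing between cell-containing regions
#'
#' Skeletonizes the cell-free complement and returns the mean Euclidean
#' distance from skeleton pixels to the nearest cell pixel.
#'
#' @param mask logical matrix (cell regions)
#' @return Spacing in pixels; 0 with a warning for a full or empty mask.
#' @export
colonySpacing <- function(mask) {
  if (!any(mask) || all(mask)) {
    warning("mask is empty or full; spacing is 0")
    return(0)
  }
  free <- !mask
  skel <- cpp_thin(matrix(as.integer(free), nrow(mask), ncol(mask))) > 0
  if (!any(skel)) return(0)
  d <- .m(EBImage::distmap(EBImage::Image(free * 1)))
  mean(d[skel])
}

# Hu's seven moment invariants of a grayscale image (raw values, no
# log-magnitude transform)
.huMoments <- function(p) {
  H <- nrow(p); W <- ncol(p)
  i <- matrix(seq_len(H), H, W); j <- matrix(seq_len(W), H, W, byrow = TRUE)
  m00 <- sum(p)
  if (m00 <= 0) return(numeric(7))
  xb <- sum(j * p) / m00; yb <- sum(i * p) / m00
  mu <- function(pq, qq) sum((j - xb)^pq * (i - yb)^qq * p)
  eta <- function(pq, qq) mu(pq, qq) / m00^(1 + (pq + qq) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  c(n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) * ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2))
}

#' 343-D morphological profile of an initial PSC colony image
#'
#' Texture (local entropy at radius 5, cell brightness/contrast, total
#' variation), the seven Hu moment invariants, 256-D and 64-D
#' bag-of-keypoints histograms, normalized area/circumference statistics of
#' the cell regions, per-component shape statistics (solidity, convexity,
#' circularity, CCD statistics, area-weighted) and the inter-colony
#' spacing.
#'
#' @param img \linkS4class{WellImage} or matrix (bright-field, 0 h)
#' @param siftCodebook \code{Codebook} with k = 256 (128-D family)
#' @param orbCodebook \code{Codebook} with k = 64 (32-D family)
#' @param radius local-entropy radius (default 5)
#' @param entropyThreshold cell-region threshold in bits (default 3)
#' @param minComponent smallest component kept (default 50 px)
#' @return Named numeric vector of length 343.
#' @export
colonyFeatureVector <- function(img, siftCodebook, orbCodebook, radius = 5,
                                entropyThreshold = 3, minComponent = 50L) {
  if (missing(siftCodebook) || missing(orbCodebook) ||
      !inherits(siftCodebook, "Codebook") || !inherits(orbCodebook, "Codebook"))
    stop("both codebooks (k = 256 and k = 64) are required")
  if (siftCodebook$k != 256L || orbCodebook$k != 64L)
    stop("codebooks must have k = 256 and k = 64")
  p <- .asMatrix(img)
  side <- min(dim(p))
  mask <- cellRegionMask(p, radius = radius, entropyThreshold = entropyThreshold)
  ent <- attr(mask, "entropy")
  hasCells <- any(mask)
  tex <- c(LocalEntropy = if (hasCells) mean(ent[mask]) else 0,
           CellBrightness = if (hasCells) mean(p[mask]) else 0,
           CellContrast = if (hasCells) sd(as.numeric(p[mask])) else 0,
           TotalVariation = mean(abs(p[, c(2:ncol(p), ncol(p))] - p)) +
             mean(abs(p[c(2:nrow(p), nrow(p)), ] - p)))
  if (!hasCells) tex["CellContrast"] <- 0
  hu <- .huMoments(p); names(hu) <- paste0("HuMoment", 1:7)
  bok256 <- bagOfKeypoints(p, siftCodebook); names(bok256) <- paste0("SIFT", 1:256)
  bok64 <- bagOfKeypoints(p, orbCodebook); names(bok64) <- paste0("ORB", 1:64)
  area <- mean(mask)
  circ <- .contourLength(mask) / side
  ac <- c(Area = area, Circumference = circ,
          ACRatio = if (circ > 0) area / circ else 0)
  shp <- shapeStats(mask, minComponent)$imageLevel
  sp <- c(Spacing = if (hasCells && !all(mask)) colonySpacing(mask) else 0)
  out <- c(tex, hu, bok256, bok64, ac, shp, sp)
  stopifnot(length(out) == 343L)
  out
}

#' Fit a random forest on colony profiles
#'
#' Importance mode uses 1000 trees of maximum depth 8 with 15 candidate
#' features per split; prediction mode uses 20 trees with default
#' hyperparameters.  Importances are normalized to sum to 1.
#'
#' @param X feature matrix (samples x features)
#' @param y numeric target (normalized efficiency)
#' @param mode \code{"importance"} or \code{"prediction"}
#' @param seed forest seed
#' @return Object of class \code{colonyForest} with \code{fit},
#'   \code{importances} (importance mode) and \code{featureNames}.
#' @export
fitForest <- function(X, y, mode = c("importance", "prediction"), seed = 1L) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (nrow(X) < 10) stop("need at least 10 samples")
  bad <- colnames(X)[colSums(!is.finite(X)) > 0]
  if (length(bad) > 0)
    stop("non-finite features: ", paste(bad, collapse = ", "))
  df <- data.frame(X, .target = y, check.names = FALSE)
  fit <- if (mode == "importance")
    ranger::ranger(dependent.variable.name = ".target", data = df,
                   num.trees = 1000L, max.depth = 8L,
                   mtry = min(15L, ncol(X)), importance = "impurity",
                   seed = seed)
  else
    ranger::ranger(dependent.variable.name = ".target", data = df,
                   num.trees = 20L, seed = seed)
  imp <- if (mode == "importance") {
    v <- fit$variable.importance
    if (sum(v) > 0) v / sum(v) else v
  } else NULL
  structure(list(fit = fit, mode = mode, featureNames = colnames(X),
                 importances = imp, seed = seed),
            class = "colonyForest")
}

#' @export
print.colonyForest <- function(x, ...) {
  cat(sprintf("colonyForest (%s mode): %d trees, %d features\n",
              x$mode, x$fit$num.trees, length(x$featureNames)))
  if (!is.null(x$importances)) {
    top <- sort(x$importances, decreasing = TRUE)[1:5]
    cat("  top importances:",
        paste(names(top), sprintf("%.3f", top), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict normalized efficiency from colony profiles
#'
#' @param model a \code{colonyForest}
#' @param X feature matrix with the training feature names
#' @return Predicted efficiencies clipped to [0, 1].
#' @export
predictEfficiency <- function(model, X) {
  X <- as.matrix(X)
  if (!identical(colnames(X), model$featureNames))
    stop("feature names do not match the fitted model")
  p <- predict(model$fit, data.frame(X, check.names = FALSE))$predictions
  pmin(pmax(p, 0), 1)
}
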