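# Keypoint-descriptor features: a 448-D per-image summary over three
# descriptor families, bag-of-keypoints histograms against k-means
# codebooks, and the LDA/PCA projections used for trajectory visualization.
#
# Keypoints are Harris corners with gradient-orientation normalization; the
# three families follow the field's 128-D gradient-histogram, 64-D
# Haar-sum and 32-byte binary-test descriptor layouts.  The 64-D slot is a
# gradient-sum variant of the same keypoints (the classical 64-D descriptor
# family is patent-encumbered); the substitution is recorded in the result
# metadata.

.DESC_FAMILIES <- c(f128 = 128L, f64 = 64L, f32 = 32L)

.sobel <- function(p) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  list(gx = .m(EBImage::filter2(p, kx)),
       gy = .m(EBImage::filter2(p, t(kx))))
}

#' Detect Harris keypoints with dominant orientations
#'
#' @param img \linkS4class{WellImage} or matrix
#' @param maxKeypoints cap on the number of keypoints (strongest kept)
#' @param qualityLevel response threshold relative to the strongest corner
#' @param margin border margin excluded (descriptor support)
#' @return Matrix with columns \code{row}, \code{col}, \code{response},
#'   \code{angle}; zero rows when no keypoint passes.
#' @export
detectKeypoints <- function(img, maxKeypoints = 500L, qualityLevel = 0.02,
                            margin = 24L) {
  p <- .asMatrix(img)
  g <- .sobel(p)
  w <- EBImage::makeBrush(9, "Gaussian", sigma = 1.5)
  A <- .m(EBImage::filter2(g$gx^2, w))
  B <- .m(EBImage::filter2(g$gy^2, w))
  C <- .m(EBImage::filter2(g$gx * g$gy, w))
  R <- (A * B - C^2) - 0.04 * (A + B)^2
  H <- nrow(p); W <- ncol(p)
  out <- matrix(numeric(0), 0, 4,
                dimnames = list(NULL, c("row", "col", "response", "angle")))
  if (max(R) <= 0) return(out)
  # 3x3 local maxima above the quality threshold, away from the border
  ok <- R >= qualityLevel * max(R)
  ok[c(1, H), ] <- FALSE; ok[, c(1, W)] <- FALSE
  idx <- which(ok)
  if (length(idx) == 0) return(out)
  i <- (idx - 1L) %% H + 1L; j <- (idx - 1L) %/% H + 1L
  keep <- i > margin & i <= H - margin & j > margin & j <= W - margin
  i <- i[keep]; j <- j[keep]; idx <- idx[keep]
  if (length(idx) == 0) return(out)
  isMax <- rep(TRUE, length(idx))
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    isMax <- isMax & R[idx] >= R[cbind(i + di, j + dj)]
  }
  i <- i[isMax]; j <- j[isMax]
  r <- R[cbind(i, j)]
  o <- order(r, decreasing = TRUE)
  if (length(o) > maxKeypoints) o <- o[seq_len(maxKeypoints)]
  i <- i[o]; j <- j[o]; r <- r[o]
  # dominant orientation: peak of the 36-bin gradient-direction histogram
  # over a disc of radius 8
  off <- expand.grid(dy = -8:8, dx = -8:8)
  off <- off[off$dy^2 + off$dx^2 <= 64, ]
  ang <- numeric(length(i))
  for (k in seq_along(i)) {
    yy <- i[k] + off$dy; xx <- j[k] + off$dx
    gx <- g$gx[cbind(yy, xx)]; gy <- g$gy[cbind(yy, xx)]
    mag <- sqrt(gx^2 + gy^2)
    th <- atan2(gy, gx)
    bin <- floor((th + pi) / (2 * pi) * 36) %% 36 + 1
    hist36 <- vapply(1:36, function(b) sum(mag[bin == b]), numeric(1))
    ang[k] <- (which.max(hist36) - 0.5) / 36 * 2 * pi - pi
  }
  cbind(row = i, col = j, response = r, angle = ang)
}

# sample a rotated 16x16 patch (bilinear) around one keypoint
.samplePatch <- function(p, row, col, angle, n = 16L, spacing = 1.5) {
  u <- (seq_len(n) - (n + 1) / 2) * spacing
  gy <- rep(u, times = n); gx <- rep(u, each = n)
  ca <- cos(angle); sa <- sin(angle)
  yy <- row + ca * gy - sa * gx
  xx <- col + sa * gy + ca * gx
  y0 <- floor(yy); x0 <- floor(xx)
  fy <- yy - y0; fx <- xx - x0
  H <- nrow(p); W <- ncol(p)
  cl <- function(a, m) pmin(pmax(a, 1L), m)
  v <- p[cbind(cl(y0, H), cl(x0, W))] * (1 - fy) * (1 - fx) +
    p[cbind(cl(y0 + 1L, H), cl(x0, W))] * fy * (1 - fx) +
    p[cbind(cl(y0, H), cl(x0 + 1L, W))] * (1 - fy) * fx +
    p[cbind(cl(y0 + 1L, H), cl(x0 + 1L, W))] * fy * fx
  matrix(v, n, n)
}

# fixed, seed-stable pattern of 256 pixel-pair comparisons for the 32-byte
# binary-test family
.binaryTestPattern <- local({
  pat <- NULL
  function() {
    if (is.null(pat)) {
      pat <<- withSeed(987654L, {
        n <- 16
        cbind(a = sample.int(n * n, 256, replace = TRUE),
              b = sample.int(n * n, 256, replace = TRUE))
      })
    }
    pat
  }
})

.describeKeypoints <- function(p, kp, family) {
  d <- .DESC_FAMILIES[[family]]
  if (nrow(kp) == 0) return(matrix(numeric(0), 0, d))
  out <- matrix(0, nrow(kp), d)
  pat <- .binaryTestPattern()
  cell <- rep(rep(1:4, each = 4), times = 4) + 4 * (rep(rep(1:4, each = 4), each = 4) - 1)
  for (k in seq_len(nrow(kp))) {
    patch <- .samplePatch(p, kp[k, "row"], kp[k, "col"], kp[k, "angle"])
    if (family == "f32") {
      sm <- (patch + patch[c(1, 1:15), ] + patch[, c(1, 1:15)] +
               patch[c(2:16, 16), ] + patch[, c(2:16, 16)]) / 5
      bits <- as.integer(sm[pat[, "a"]] > sm[pat[, "b"]])
      out[k, ] <- colSums(matrix(bits, 8, 32) * 2^(0:7))
      next
    }
    dx <- (patch[, c(2:16, 16)] - patch[, c(1, 1:15)]) / 2
    dy <- (patch[c(2:16, 16), ] - patch[c(1, 1:15), ]) / 2
    if (family == "f64") {
      v <- c(vapply(1:16, function(cc) {
        s <- cell == cc
        c(sum(dx[s]), sum(abs(dx[s])), sum(dy[s]), sum(abs(dy[s])))
      }, numeric(4)))
      n2 <- sqrt(sum(v^2))
      out[k, ] <- if (n2 > 0) v / n2 else v
    } else {
      mag <- sqrt(dx^2 + dy^2)
      th <- atan2(dy, dx)
      bin <- floor((th + pi) / (2 * pi) * 8) %% 8 + 1
      v <- numeric(128)
      idx <- (cell - 1) * 8 + bin
      for (q in seq_along(idx)) v[idx[q]] <- v[idx[q]] + mag[q]
      n2 <- sqrt(sum(v^2))
      if (n2 > 0) {
        v <- pmin(v / n2, 0.2)
        v <- v / sqrt(sum(v^2))
      }
      out[k, ] <- v
    }
  }
  out
}

#' Keypoint-descriptor summary of an image
#'
#' Detects keypoints once and computes, for each descriptor family (128-D,
#' 64-D, 32-D), the per-dimension mean and population standard deviation
#' over all keypoints, concatenated family-major as [means, sds] per
#' family: (128 + 64 + 32) x 2 = 448 values.  Images without keypoints give
#' an all-zero vector with a warning.
#'
#' @param img \linkS4class{WellImage} or matrix
#' @param families descriptor families (default all three)
#' @param ... passed to \code{\link{detectKeypoints}}
#' @return Named numeric vector (448-D for the default families) with
#'   attributes \code{"nKeypoints"} and \code{"familyImplementations"}.
#' @export
descriptorSummary <- function(img, families = names(.DESC_FAMILIES), ...) {
  p <- .asMatrix(img)
  kp <- detectKeypoints(p, ...)
  if (nrow(kp) == 0) warning("no keypoints detected; zero descriptor summary")
  out <- numeric(0)
  for (fam in families) {
    d <- .DESC_FAMILIES[[fam]]
    D <- .describeKeypoints(p, kp, fam)
    mu <- if (nrow(D) > 0) colMeans(D) else numeric(d)
    sdv <- if (nrow(D) > 1) sqrt(colMeans(sweep(D, 2, mu)^2)) else numeric(d)
    if (nrow(D) == 1) sdv <- numeric(d)
    v <- c(mu, sdv)
    names(v) <- c(paste0(fam, "_mean", seq_len(d)), paste0(fam, "_sd", seq_len(d)))
    out <- c(out, v)
  }
  attr(out, "nKeypoints") <- nrow(kp)
  attr(out, "familyImplementations") <- c(
    f128 = "gradient-orientation histogram (128-D)",
    f64 = "gradient-sum grid (64-D substitute family)",
    f32 = "binary-test bytes (32-D)")[families]
  out
}

#' Fit a bag-of-keypoints codebook
#'
#' Pools the chosen family's descriptors over the fitting images and runs
#' k-means; the fitting image ids are stored so downstream train/test sets
#' can be kept disjoint from them.
#'
#' @param images list of \linkS4class{WellImage} or matrices
#' @param family one of \code{"f128"}, \code{"f64"}, \code{"f32"}
#' @param k number of clusters (256 and 64 are the canonical sizes)
#' @param seed k-means seed
#' @param fitIds optional ids of the fitting images
#' @return Object of class \code{Codebook}.
#' @export
fitCodebook <- function(images, family = "f128", k = 256L, seed = 1L,
                        fitIds = NULL) {
  pool <- do.call(rbind, lapply(images, function(im) {
    p <- .asMatrix(im)
    .describeKeypoints(p, detectKeypoints(p), family)
  }))
  if (is.null(pool) || nrow(pool) < k)
    stop(sprintf("need at least %d pooled keypoints, got %d", k,
                 if (is.null(pool)) 0L else nrow(pool)))
  km <- withSeed(seed, kmeans(pool, centers = k, iter.max = 50L, nstart = 1L))
  structure(list(k = as.integer(k), centers = km$centers, family = family,
                 seed = as.integer(seed), fitIds = fitIds),
            class = "Codebook")
}

#' @export
print.Codebook <- function(x, ...) {
  cat(sprintf("Codebook: %d centers, family %s, seed %d, %d fit image(s)\n",
              x$k, x$family, x$seed, length(x$fitIds)))
  invisible(x)
}

#' Save / load a codebook as JSON
#'
#' @param codebook a \code{Codebook}
#' @param path JSON path
#' @return \code{writeCodebook}: \code{path} invisibly; \code{readCodebook}:
#'   the \code{Codebook}.
#' @export
writeCodebook <- function(codebook, path) {
  jsonlite::write_json(list(k = codebook$k, family = codebook$family,
                            seed = codebook$seed, fitIds = codebook$fitIds,
                            centers = codebook$centers),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCodebook
#' @export
readCodebook <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(k = as.integer(j$k), centers = as.matrix(j$centers),
                 family = j$family, seed = as.integer(j$seed),
                 fitIds = j$fitIds), class = "Codebook")
}

#' Bag-of-keypoints histogram
#'
#' Assigns each detected keypoint's descriptor to its nearest codebook
#' center and counts assignments; the histogram sums to the number of
#' keypoints.
#'
#' @param img \linkS4class{WellImage} or matrix
#' @param codebook a fitted \code{Codebook}
#' @return Integer count vector of length \code{codebook$k}.
#' @export
bagOfKeypoints <- function(img, codebook) {
  stopifnot(inherits(codebook, "Codebook"))
  p <- .asMatrix(img)
  D <- .describeKeypoints(p, detectKeypoints(p), codebook$family)
  counts <- integer(codebook$k)
  if (nrow(D) > 0) {
    cc <- codebook$centers
    d2 <- outer(rowSums(D^2), rowSums(cc^2), "+") - 2 * D %*% t(cc)
    a <- max.col(-d2, ties.method = "first")
    tab <- tabulate(a, nbins = codebook$k)
    counts <- as.integer(tab)
  }
  counts
}

#' Linear discriminant projection to 2-D
#'
#' Shrinkage LDA: the within-class scatter is shrunk toward a scaled
#' identity, \eqn{(1-s)\Sigma_W + s\,\bar\sigma^2 I}, and the top two
#' discriminants of \eqn{\Sigma_W^{-1}\Sigma_B} are returned together with
#' the projection basis for reuse on new samples.
#'
#' @param X numeric matrix (samples x features)
#' @param y class labels (>= 2 classes)
#' @param shrinkage shrinkage intensity in [0, 1]
#' @return List with \code{scores} (n x 2), \code{basis} (p x 2),
#'   \code{center}; class \code{"ldaProjection"}.
#' @export
projectLDA <- function(X, y, shrinkage = 0) {
  X <- as.matrix(X); y <- as.factor(y)
  if (nlevels(y) < 2) stop("LDA needs at least 2 classes")
  n <- nrow(X); pdim <- ncol(X)
  mu <- colMeans(X)
  Sw <- matrix(0, pdim, pdim); Sb <- matrix(0, pdim, pdim)
  for (cl in levels(y)) {
    i <- y == cl
    mc <- colMeans(X[i, , drop = FALSE])
    Xc <- sweep(X[i, , drop = FALSE], 2, mc)
    Sw <- Sw + crossprod(Xc) / n
    Sb <- Sb + sum(i) / n * tcrossprod(mc - mu)
  }
  if (shrinkage > 0)
    Sw <- (1 - shrinkage) * Sw + shrinkage * mean(diag(Sw)) * diag(pdim)
  ch <- try(chol(Sw), silent = TRUE)
  if (inherits(ch, "try-error"))
    stop("within-class scatter is singular; use shrinkage > 0")
  W <- chol2inv(ch) %*% Sb
  eg <- eigen(W)
  V <- Re(eg$vectors[, 1:2, drop = FALSE])
  V <- apply(V, 2, function(v) v / sqrt(sum(v^2)))
  structure(list(scores = sweep(X, 2, mu) %*% V, basis = V, center = mu),
            class = "ldaProjection")
}

#' @rdname projectLDA
#' @param object an \code{ldaProjection} or \code{pcaProjection}
#' @param newX new samples to project
#' @return \code{projectNew}: matrix of 2-D coordinates.
#' @export
projectNew <- function(object, newX) {
  sweep(as.matrix(newX), 2, object$center) %*% object$basis
}

#' Principal-component projection to 2-D
#'
#' @param X numeric matrix (samples x features)
#' @return List with \code{scores}, \code{basis}, \code{center},
#'   \code{varianceRatio}; class \code{"pcaProjection"}.
#' @export
projectPCA <- function(X) {
  X <- as.matrix(X)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  structure(list(scores = pc$x[, 1:2, drop = FALSE],
                 basis = pc$rotation[, 1:2, drop = FALSE],
                 center = pc$center,
                 varianceRatio = pc$sdev^2 / sum(pc$sdev^2)),
            class = "pcaProjection")
}
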