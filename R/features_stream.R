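# Handcrafted 21-D representation of a 0-12 h bright-field image stream:
# fractal dimension, local-entropy colony statistics and dense optical flow,
# pooled over pre/mid/post phases.

.asMatrix <- function(img) if (is(img, "WellImage")) pixels(img) else img

#' Cell-region mask from local entropy
#'
#' Computes, for every pixel, the Shannon entropy (base 2) of the 8-bit
#' intensity histogram over its disc neighborhood (Euclidean radius
#' \code{radius}); pixels with entropy >= \code{entropyThreshold} are
#' regarded as covered by cells.
#'
#' @param img \linkS4class{WellImage} or matrix
#' @param radius disc radius in pixels (default 10)
#' @param entropyThreshold threshold in bits (default 3)
#' @return Logical matrix (cell regions); the entropy map is attached as
#'   attribute \code{"entropy"}.
#' @export
cellRegionMask <- function(img, radius = 10, entropyThreshold = 3) {
  p <- .asMatrix(img)
  ent <- cpp_local_entropy(p, as.integer(radius))
  mask <- ent >= entropyThreshold
  attr(mask, "entropy") <- ent
  mask
}

#' Differential box-counting fractal dimension
#'
#' Treats the grayscale image as an intensity surface and counts, for each
#' box width r in the schedule 2, 2k, 2k^2, ..., 2k^15 with k = 243^(1/15),
#' the boxes N(r) of height r * G / M (G = 256 gray levels, M = image side)
#' needed to cover the surface over an r x r grid; the fractal dimension is
#' minus the slope of the least-squares fit of log N(r) on log r, and lies
#' in [2, 3].
#'
#' @param img \linkS4class{WellImage} or matrix with side >= 486 (the
#'   largest box width in the schedule)
#' @param grayLevels number of gray levels (default 256)
#' @return Fractal dimension, clipped to [2, 3] with a warning if the fit
#'   falls outside by numerical error.
#' @export
fractalDimension <- function(img, grayLevels = 256L) {
  p <- .asMatrix(img)
  k <- 243^(1 / 15)
  widths <- as.integer(round(2 * k^(0:15)))
  if (min(dim(p)) < max(widths))
    stop(sprintf("image side must be >= %d for the box schedule", max(widths)))
  N <- cpp_dbc_counts(p, widths, as.integer(grayLevels))
  fd <- -unname(coef(stats::lm(log(N) ~ log(widths)))[2])
  if (fd < 2 || fd > 3) {
    warning(sprintf("fractal dimension %.4f outside [2,3]; clipped", fd))
    fd <- min(max(fd, 2), 3)
  }
  fd
}

# total polygonal contour length of the components of a binary mask, using
# the outer contours resampled at ~5 px arc spacing (stabilizes perimeter
# estimates of smooth shapes against chain-code overcount)
.contourLength <- function(mask, spacing = 5L) {
  if (!any(mask)) return(0)
  lbl <- .label8(mask)
  oc <- EBImage::ocontour(EBImage::Image(lbl))
  total <- 0
  for (xy in oc) {
    n <- nrow(xy)
    if (n < 3) next
    idx <- unique(c(seq(1L, n, by = spacing)))
    total <- total + .polyPerimeter(xy[idx, , drop = FALSE])
  }
  total
}

#' Colony statistics of a frame
#'
#' Area (cell-pixel fraction), Circumference (total contour length of the
#' cell-region components divided by the image side), their ratio, and the
#' mean intensity of cell regions.
#'
#' @param img \linkS4class{WellImage} or matrix
#' @param mask logical cell-region mask, as from
#'   \code{\link{cellRegionMask}}
#' @return Named numeric: \code{Area}, \code{Circumference},
#'   \code{ACRatio}, \code{CellBrightness}; all zero (with a warning) for an
#'   empty mask.
#' @export
colonyStats <- function(img, mask) {
  p <- .asMatrix(img)
  if (!any(mask)) {
    warning("empty cell-region mask; colony statistics set to 0")
    return(c(Area = 0, Circumference = 0, ACRatio = 0, CellBrightness = 0))
  }
  side <- min(dim(p))
  area <- mean(mask)
  circ <- .contourLength(mask) / side
  c(Area = area, Circumference = circ,
    ACRatio = if (circ > 0) area / circ else 0,
    CellBrightness = mean(p[mask]))
}

# 2x block-mean downsampling (sides cropped to even)
.down2 <- function(m) {
  H <- nrow(m) %/% 2L * 2L; W <- ncol(m) %/% 2L * 2L
  m <- m[seq_len(H), seq_len(W)]
  (m[seq(1, H, 2), seq(1, W, 2)] + m[seq(2, H, 2), seq(1, W, 2)] +
     m[seq(1, H, 2), seq(2, W, 2)] + m[seq(2, H, 2), seq(2, W, 2)]) / 4
}

#' Dense optical-flow magnitude between two frames
#'
#' Estimates a dense displacement field on a grid of \code{window}-sized
#' blocks by coarse-to-fine block matching (sum-of-squared-difference
#' search with parabolic sub-pixel refinement), discards vectors with
#' magnitude <= \code{minMagnitude} and returns the mean magnitude of the
#' survivors (0 when none survive).
#'
#' @param prev,nxt consecutive frames (\linkS4class{WellImage} or matrix),
#'   same shape
#' @param window block size in pixels (default 16)
#' @param minMagnitude discard threshold in pixels (default 4)
#' @param maxShift largest displacement searched (default 20)
#' @param qualityRatio a nonzero displacement is accepted only when its SSD
#'   is below this fraction of the zero-displacement SSD (rejects windows
#'   whose content left the frame)
#' @return Mean surviving flow magnitude in pixels; the per-window field is
#'   attached as attribute \code{"field"} (columns row, col, dy, dx, mag).
#' @export
opticalFlowFeature <- function(prev, nxt, window = 16L, minMagnitude = 4,
                               maxShift = 20L, qualityRatio = 0.25) {
  a <- .asMatrix(prev); b <- .asMatrix(nxt)
  if (!all(dim(a) == dim(b))) stop("frames must share one shape")
  window <- as.integer(window)
  # coarse pass at 1/4 resolution bounds the search cost
  a2 <- .down2(.down2(a)); b2 <- .down2(.down2(b))
  cw <- max(4L, window %/% 2L)
  coarse <- cpp_block_flow(a2, b2, cw, cw, matrix(0, 0, 2),
                           as.integer(ceiling(maxShift / 4) + 1L), qualityRatio)
  fys <- seq.int(0L, nrow(a) - window, by = window)
  fxs <- seq.int(0L, ncol(a) - window, by = window)
  init <- matrix(0, length(fys) * length(fxs), 2)
  if (nrow(coarse) > 0) {
    ccy <- coarse[, 1] + cw / 2; ccx <- coarse[, 2] + cw / 2
    k <- 0L
    for (y0 in fys) for (x0 in fxs) {
      k <- k + 1L
      d2 <- (ccy - (y0 + window / 2) / 4)^2 + (ccx - (x0 + window / 2) / 4)^2
      j <- which.min(d2)
      if (coarse[j, 5] > 0) init[k, ] <- 4 * coarse[j, 3:4]
    }
  }
  fine <- cpp_block_flow(a, b, window, window, init, 3L, qualityRatio)
  ok <- fine[, 5] > 0
  mag <- sqrt(fine[, 3]^2 + fine[, 4]^2)
  field <- cbind(row = fine[, 1], col = fine[, 2], dy = fine[, 3],
                 dx = fine[, 4], mag = mag)[ok, , drop = FALSE]
  keep <- field[, "mag"] > minMagnitude
  out <- if (any(keep)) mean(field[keep, "mag"]) else 0
  attr(out, "field") <- field
  out
}

#' 21-D feature vector of an image stream
#'
#' Type-I features (FractalDimension, LocalEntropy, Area, Circumference,
#' ACRatio, CellBrightness) are computed at each of the 10 frames; the
#' Type-II OpticalFlow feature at the 9 consecutive frame pairs.  The Area,
#' Circumference, ACRatio and OpticalFlow sequences are normalized by their
#' first value (sequences whose first value is below \code{1e-6} are left
#' unnormalized and flagged), frames are pooled into pre/mid/post phases by
#' arithmetic mean, and the 7 x 3 values are returned feature-major.
#'
#' @param stream an \linkS4class{ImageStream}
#' @param radius local-entropy disc radius (default 10)
#' @param entropyThreshold cell-region threshold in bits (default 3)
#' @param phasesI frame indices of the three Type-I phases
#' @param phasesII pair indices of the three Type-II phases
#' @return Named numeric vector of length 21
#'   (\code{<Feature>.pre/.mid/.post}); unnormalized sequences are listed in
#'   attribute \code{"unnormalized"}.
#' @export
streamFeatureVector <- function(stream, radius = 10, entropyThreshold = 3,
                                phasesI = list(pre = 1:3, mid = 4:7, post = 8:10),
                                phasesII = list(pre = 1:3, mid = 4:6, post = 7:9)) {
  fr <- frames(stream)
  if (length(fr) != 10L) stop("a stream has exactly 10 frames")
  typeI <- matrix(NA_real_, 10, 6,
                  dimnames = list(NULL, c("FractalDimension", "LocalEntropy", "Area",
                                          "Circumference", "ACRatio", "CellBrightness")))
  for (t in 1:10) {
    p <- pixels(fr[[t]])
    mask <- cellRegionMask(p, radius, entropyThreshold)
    ent <- attr(mask, "entropy")
    cs <- colonyStats(p, mask)
    typeI[t, ] <- c(fractalDimension(p),
                    if (any(mask)) mean(ent[mask]) else 0,
                    cs["Area"], cs["Circumference"], cs["ACRatio"],
                    cs["CellBrightness"])
  }
  flow <- vapply(1:9, function(t)
    as.numeric(opticalFlowFeature(fr[[t]], fr[[t + 1]])), numeric(1))
  unnorm <- character(0)
  normFirst <- function(x, name) {
    if (abs(x[1]) < 1e-6) {
      unnorm <<- c(unnorm, name)
      x
    } else x / x[1]
  }
  for (nm in c("Area", "Circumference", "ACRatio"))
    typeI[, nm] <- normFirst(typeI[, nm], nm)
  flow <- normFirst(flow, "OpticalFlow")
  pool <- function(x, phases) vapply(phases, function(i) mean(x[i]), numeric(1))
  out <- c(vapply(colnames(typeI), function(nm) pool(typeI[, nm], phasesI),
                  numeric(3)))
  names(out) <- paste(rep(colnames(typeI), each = 3),
                      rep(names(phasesI), 6), sep = ".")
  fl <- pool(flow, phasesII)
  names(fl) <- paste("OpticalFlow", names(phasesII), sep = ".")
  out <- c(out, fl)
  attr(out, "unnormalized") <- unnorm
  out
}
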