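# Image, mask and table I/O plus the patch-tiling conventions shared by all
# downstream modules.  Internal intensity scale is [0,1]; 8-/16-bit integer
# scales exist only at the file boundary.

#' Read a whole-well image
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG into a
#' \linkS4class{WellImage} with intensities scaled to [0,1].  RGB inputs are
#' converted to luminance (0.2126 R + 0.7152 G + 0.0722 B) with a warning.
#'
#' @param path file path (.tif/.tiff/.png)
#' @param channel channel tag for the result
#' @param wellId well identifier; defaults to the file stem
#' @return A \linkS4class{WellImage}.
#' @export
readWellImage <- function(path, channel = "brightfield", wellId = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", path))
  if (length(dim(a)) == 3L) {
    warning("multi-channel image converted to luminance: ", path)
    if (dim(a)[3] >= 3L)
      a <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
    else a <- a[, , 1]
  }
  if (is.null(wellId)) wellId <- tools::file_path_sans_ext(basename(path))
  WellImage(a, wellId = wellId, channel = channel)
}

#' Write a whole-well image
#'
#' Bright-field and fluorescence images are written as 16-bit grayscale TIFF
#' (or 8-bit PNG when the path ends in .png).
#'
#' @param img a \linkS4class{WellImage}
#' @param path output path
#' @return \code{path}, invisibly.
#' @export
writeWellImage <- function(img, path) {
  p <- .clip01(pixels(img))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) tiff::writeTIFF(p, path, bits.per.sample = 16L)
  else if (ext == "png") png::writePNG(p, path)
  else stop("unsupported image format: ", path)
  invisible(path)
}

#' Read / write region masks as 8-bit PNG with the fixed palette
#'
#' @param path PNG path
#' @param wellId well identifier; defaults to the file stem
#' @return \code{readRegionMask}: a \linkS4class{RegionMask}.
#' @export
readRegionMask <- function(path, wellId = NULL) {
  if (!file.exists(path)) stop("cannot read mask: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  codes <- as.integer(round(a * 255))
  pal <- maskPalette()
  snap <- pal[apply(abs(outer(codes, pal, "-")), 1, which.min)]
  if (is.null(wellId)) wellId <- tools::file_path_sans_ext(basename(path))
  RegionMask(matrix(as.integer(snap), nrow(a), ncol(a)), wellId = wellId)
}

#' @rdname readRegionMask
#' @param mask a \linkS4class{RegionMask}
#' @return \code{writeRegionMask}: \code{path}, invisibly.
#' @export
writeRegionMask <- function(mask, path) {
  png::writePNG(maskLabels(mask) / 255, path)
  invisible(path)
}

#' Crop an image into overlapping patches
#'
#' Tiles an image with square patches at stride
#' \code{round(patch * (1 - overlap))}; the last patch on each axis is
#' re-anchored flush to the far edge so coverage is complete without
#' padding.  Origins are 0-based with half-open extents
#' \code{[r, r + patch)}.
#'
#' @param img a \linkS4class{WellImage} or numeric matrix
#' @param patch patch side in pixels
#' @param overlap overlap fraction in [0, 1)
#' @param originsOnly skip extracting pixel patches (origins arithmetic only)
#' @return A list with \code{patches} (list of matrices) and \code{origins}
#'   (two-column 0-based matrix of row/col origins, row-major order).
#' @export
#' @examples
#' tiling <- cropPatches(matrix(0, 64, 64), patch = 32, overlap = 0.5)
#' nrow(tiling$origins)  # 3 x 3 = 9 patches
cropPatches <- function(img, patch, overlap = 0.5, originsOnly = FALSE) {
  p <- if (is(img, "WellImage")) pixels(img) else img
  H <- nrow(p); W <- ncol(p)
  if (patch > H || patch > W) stop("patch exceeds image side")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  stride <- max(1L, as.integer(round(patch * (1 - overlap))))
  ax <- function(side) {
    o <- seq.int(0L, max(side - patch, 0L), by = stride)
    if (o[length(o)] + patch < side) o <- c(o, side - patch)
    o
  }
  rows <- ax(H); cols <- ax(W)
  origins <- cbind(row = rep(rows, each = length(cols)),
                   col = rep(cols, times = length(rows)))
  patches <- if (originsOnly) NULL else
    lapply(seq_len(nrow(origins)), function(i) {
      r <- origins[i, 1]; c0 <- origins[i, 2]
      p[(r + 1):(r + patch), (c0 + 1):(c0 + patch)]
    })
  list(patches = patches, origins = origins, patch = patch)
}

#' Reconstruct a whole-well array from per-patch values
#'
#' Inverse of \code{\link{cropPatches}} for patch-level predictions: values
#' in overlap regions are combined by the chosen aggregator.  Every output
#' pixel must be covered by at least one patch.
#'
#' @param values list of patch matrices (all the same size)
#' @param origins two-column 0-based origin matrix, as from
#'   \code{\link{cropPatches}}
#' @param outSize output (rows, cols)
#' @param aggregator one of \code{"mean"}, \code{"max"},
#'   \code{"any_positive"}
#' @return Numeric (or logical for \code{any_positive}) matrix of
#'   \code{outSize}.
#' @export
reconstructPatches <- function(values, origins, outSize,
                               aggregator = c("mean", "max", "any_positive")) {
  aggregator <- match.arg(aggregator)
  H <- outSize[1]; W <- outSize[2]
  count <- matrix(0L, H, W)
  acc <- switch(aggregator,
    mean = matrix(0, H, W),
    max = matrix(-Inf, H, W),
    any_positive = matrix(FALSE, H, W))
  for (i in seq_along(values)) {
    v <- values[[i]]
    r <- origins[i, 1]; c0 <- origins[i, 2]
    ri <- (r + 1):(r + nrow(v)); ci <- (c0 + 1):(c0 + ncol(v))
    if (max(ri) > H || max(ci) > W) stop("patch extends beyond output size")
    count[ri, ci] <- count[ri, ci] + 1L
    if (aggregator == "mean") acc[ri, ci] <- acc[ri, ci] + v
    else if (aggregator == "max") acc[ri, ci] <- pmax(acc[ri, ci], v)
    else acc[ri, ci] <- acc[ri, ci] | (v > 0)
  }
  if (any(count == 0L)) {
    gap <- which(count == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("uncovered pixel at (row %d, col %d)", gap[1], gap[2]))
  }
  if (aggregator == "mean") acc / count else acc
}

#' Acquisition plan arithmetic
#'
#' Number of microscope tiles needed to image a plate: each well is covered
#' by an n x n tile grid at each of the z focal planes.
#'
#' @param wells number of wells imaged
#' @param grid tiles per side within a well
#' @param zStacks number of z planes
#' @return List with \code{total} tile count and a \code{tiles} coordinate
#'   table (well, tileRow, tileCol, z).
#' @export
#' @examples
#' acquisitionPlan(96, 5, 3)$total  # 7200 tiles per round
acquisitionPlan <- function(wells, grid, zStacks = 1L) {
  stopifnot(wells >= 1, grid >= 1, zStacks >= 1)
  tiles <- expand.grid(tileRow = seq_len(grid), tileCol = seq_len(grid),
                       z = seq_len(zStacks), well = seq_len(wells))
  tiles <- tiles[, c("well", "tileRow", "tileCol", "z")]
  list(total = grid^2 * zStacks * wells, tiles = tiles)
}

#' Resize images and masks
#'
#' Bilinear interpolation for intensity images, nearest neighbor for masks
#' (so palette codes are preserved).
#'
#' @param x a \linkS4class{WellImage} or \linkS4class{RegionMask}
#' @param side target side in pixels
#' @return Object of the same class at the new size.
#' @export
resizeWell <- function(x, side) {
  if (is(x, "WellImage")) {
    p <- EBImage::resize(EBImage::Image(pixels(x)), w = side, h = side)
    WellImage(as.matrix(p), wellId = wellId(x), channel = channel(x))
  } else if (is(x, "RegionMask")) {
    l <- maskLabels(x)
    ri <- pmin(nrow(l), pmax(1L, round(seq(0.5, nrow(l) - 0.5, length.out = side) + 0.5)))
    ci <- pmin(ncol(l), pmax(1L, round(seq(0.5, ncol(l) - 0.5, length.out = side) + 0.5)))
    RegionMask(l[ri, ci], wellId = wellId(x))
  } else stop("unsupported class")
}
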