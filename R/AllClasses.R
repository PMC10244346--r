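#' @import methods
#' @importFrom stats runif rnorm kmeans prcomp sd cor aov predict quantile
#' @importFrom utils read.csv write.csv head
#' @importFrom tools file_ext file_path_sans_ext
#' @importFrom grDevices chull
#' @importFrom stats setNames coef lm
#' @useDynLib pscdiff, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.CHANNELS <- c("brightfield", "cTnT", "SIX2", "SOX17")

#' Fixed 8-bit palette for region masks
#'
#' Region masks use four fixed 8-bit codes: \code{black} (0) for cells that
#' fail to reach the target fate (and background), \code{light_gray} (128)
#' for cells likely to reach it, \code{dark_gray} (192) for cells committed
#' to it, and \code{white} (255) for recolored ground-truth positives in
#' evaluation.
#'
#' @return Named integer vector of the four mask codes.
#' @export
#' @examples
#' maskPalette()
maskPalette <- function() {
  c(black = 0L, light_gray = 128L, dark_gray = 192L, white = 255L)
}

#' WellImage: one grayscale whole-well image
#'
#' A single-channel whole-well microscopy image with intensities on the
#' internal [0,1] scale, together with its well identifier, channel tag and
#' (optionally) the pixel size in micrometers.
#'
#' @slot pixels numeric matrix of intensities in [0,1]
#' @slot wellId character well identifier
#' @slot channel one of \code{"brightfield"}, \code{"cTnT"}, \code{"SIX2"},
#'   \code{"SOX17"}
#' @slot pixelSize numeric, micrometers per pixel (NA when unknown)
#' @export
setClass("WellImage",
  representation(pixels = "matrix", wellId = "character",
                 channel = "character", pixelSize = "numeric"),
  prototype(pixels = matrix(0, 1, 1), wellId = "well", channel = "brightfield",
            pixelSize = NA_real_))

setValidity("WellImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (length(p) == 0L) return("pixels must be non-empty")
  rng <- range(p, finite = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    return("intensities must lie in [0,1]")
  if (!object@channel %in% .CHANNELS)
    return(sprintf("channel must be one of: %s", paste(.CHANNELS, collapse = ", ")))
  TRUE
})

#' Construct a WellImage
#'
#' Intensities are clipped to [0,1].
#'
#' @param pixels numeric matrix of intensities
#' @param wellId well identifier
#' @param channel channel tag
#' @param pixelSize micrometers per pixel
#' @return A \linkS4class{WellImage}.
#' @export
#' @examples
#' img <- WellImage(matrix(runif(64), 8, 8), wellId = "A01")
WellImage <- function(pixels, wellId = "well", channel = "brightfield",
                      pixelSize = NA_real_) {
  pixels <- pmin(pmax(pixels, 0), 1)
  new("WellImage", pixels = pixels, wellId = wellId, channel = channel,
      pixelSize = as.numeric(pixelSize))
}

#' RegionMask: pixel labels for fate regions
#'
#' Pixel-level fate annotation with codes from \code{\link{maskPalette}}.
#' Three-level masks (dark gray / light gray / black) annotate progenitor
#' regions; binary masks (values 0/1 in the \code{labels} slot are also
#' accepted through the palette code 255 convention of predictions).
#'
#' @slot labels integer matrix of palette codes
#' @slot wellId character well identifier
#' @export
setClass("RegionMask",
  representation(labels = "matrix", wellId = "character"),
  prototype(labels = matrix(0L, 1, 1), wellId = "well"))

setValidity("RegionMask", function(object) {
  l <- object@labels
  if (!all(l %in% maskPalette()))
    return("mask codes must come from maskPalette()")
  TRUE
})

#' Construct a RegionMask
#'
#' @param labels integer matrix of palette codes (see \code{\link{maskPalette}});
#'   a logical/0-1 matrix is promoted to black/white codes
#' @param wellId well identifier
#' @return A \linkS4class{RegionMask}.
#' @export
RegionMask <- function(labels, wellId = "well") {
  if (is.logical(labels)) labels <- labels * 1L
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (all(labels %in% c(0L, 1L)) && any(labels == 1L))
    labels[labels == 1L] <- maskPalette()[["white"]]
  new("RegionMask", labels = labels, wellId = wellId)
}

#' ImageStream: T1-T10 frames of one well over 0-12 h
#'
#' Ten bright-field frames taken at uniform intervals over the first 12 h of
#' CHIR treatment, together with the dose metadata of the well.
#'
#' @slot frames list of 10 \linkS4class{WellImage} objects
#' @slot timestamps numeric, hours in [0, 12], uniformly spaced
#' @slot wellId character
#' @slot chirUm CHIR concentration in micromolar
#' @slot chirH CHIR duration in hours
#' @export
setClass("ImageStream",
  representation(frames = "list", timestamps = "numeric", wellId = "character",
                 chirUm = "numeric", chirH = "numeric"))

setValidity("ImageStream", function(object) {
  if (length(object@frames) != 10L) return("an ImageStream has exactly 10 frames")
  if (!all(vapply(object@frames, is, logical(1), class2 = "WellImage")))
    return("frames must be WellImage objects")
  ts <- object@timestamps
  if (length(ts) != 10L) return("10 timestamps required")
  if (any(ts < 0 | ts > 12)) return("timestamps must lie in [0, 12] h")
  d <- diff(ts)
  if (max(abs(d - d[1])) > 1e-6) return("timestamps must be uniformly spaced")
  dims <- vapply(object@frames, function(f) dim(f@pixels), numeric(2))
  if (any(dims != dims[, 1])) return("all frames must share one shape")
  TRUE
})

#' Construct an ImageStream
#'
#' @param frames list of 10 \linkS4class{WellImage}
#' @param timestamps hours, default uniform over [0, 12]
#' @param wellId well identifier
#' @param chirUm CHIR concentration (micromolar)
#' @param chirH CHIR duration (hours)
#' @return An \linkS4class{ImageStream}.
#' @export
ImageStream <- function(frames, timestamps = seq(0, 12, length.out = 10),
                        wellId = "well", chirUm = NA_real_, chirH = NA_real_) {
  new("ImageStream", frames = frames, timestamps = timestamps, wellId = wellId,
      chirUm = as.numeric(chirUm), chirH = as.numeric(chirH))
}

#' SyntheticPlan: study design for the synthetic well generator
#'
#' Describes a synthetic batch: number of wells, cell lines with their
#' line-specific optimal CHIR concentration, the concentration and duration
#' grids, image geometry and noise level.  A fixed seed makes all generated
#' artifacts byte-identical across calls.
#'
#' @slot nWells number of wells in a batch
#' @slot cellLines character vector of line identifiers
#' @slot concentrations CHIR concentrations (micromolar), all positive
#' @slot durations CHIR durations (hours)
#' @slot optimalCenter named numeric, optimal CHIR concentration per line
#' @slot imageSize image side in pixels (>= 256)
#' @slot coloniesPerWell integer range (min, max) of colonies per well
#' @slot noiseSd intensity noise standard deviation
#' @slot maxDarkFraction committed-region area fraction at the optimum dose
#' @slot logWidth width (in log-concentration) of the dose-response bump
#' @slot textureMargin multiplier for the extra texture contrast of committed
#'   regions over plain colony interior
#' @slot seed integer master seed
#' @export
setClass("SyntheticPlan",
  representation(nWells = "integer", cellLines = "character",
                 concentrations = "numeric", durations = "numeric",
                 optimalCenter = "numeric", imageSize = "integer",
                 coloniesPerWell = "integer", noiseSd = "numeric",
                 maxDarkFraction = "numeric", logWidth = "numeric",
                 textureMargin = "numeric", seed = "integer"))

setValidity("SyntheticPlan", function(object) {
  if (any(object@concentrations <= 0)) return("concentrations must be positive")
  if (object@imageSize < 256L) return("imageSize must be >= 256")
  if (length(object@coloniesPerWell) != 2L || any(object@coloniesPerWell < 1L))
    return("coloniesPerWell must be a positive (min, max) pair")
  if (!all(object@cellLines %in% names(object@optimalCenter)))
    return("every cell line needs an optimalCenter entry")
  if (is.na(object@seed)) return("seed must be a finite integer")
  TRUE
})

#' Construct a SyntheticPlan
#'
#' Defaults describe a cardiac-induction batch: concentrations straddling a
#' 6 uM line optimum, 486-px wells (the smallest side accommodating the full
#' box-counting schedule), and a committed-area fraction peaking at 0.35.
#'
#' @param nWells number of wells
#' @param cellLines line identifiers
#' @param concentrations CHIR concentrations in micromolar
#' @param durations CHIR durations in hours
#' @param optimalCenter named numeric, optimum concentration per line
#' @param imageSize image side in pixels
#' @param coloniesPerWell (min, max) colonies per well
#' @param noiseSd additive intensity noise SD
#' @param maxDarkFraction committed-area fraction at the optimum
#' @param logWidth log-concentration width of the dose-response bump
#' @param textureMargin texture-contrast multiplier for committed regions
#' @param seed master seed (integer)
#' @return A \linkS4class{SyntheticPlan}.
#' @export
#' @examples
#' plan <- syntheticPlan(nWells = 6L, seed = 1L)
syntheticPlan <- function(nWells = 12L,
                          cellLines = "iPS-S1",
                          concentrations = c(2, 4, 6, 8, 10),
                          durations = 24,
                          optimalCenter = c("iPS-S1" = 6),
                          imageSize = 486L,
                          coloniesPerWell = c(3L, 6L),
                          noiseSd = 0.02,
                          maxDarkFraction = 0.6,
                          logWidth = 0.25,
                          textureMargin = 2.5,
                          seed = 1L) {
  if (!is.finite(seed)) stop("seed must be a finite integer")
  if (imageSize < 256) stop("imageSize must be >= 256")
  new("SyntheticPlan", nWells = as.integer(nWells), cellLines = cellLines,
      concentrations = concentrations, durations = durations,
      optimalCenter = optimalCenter, imageSize = as.integer(imageSize),
      coloniesPerWell = as.integer(coloniesPerWell), noiseSd = noiseSd,
      maxDarkFraction = maxDarkFraction, logWidth = logWidth,
      textureMargin = textureMargin, seed = as.integer(seed))
}
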