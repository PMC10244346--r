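# Differentiation-efficiency quantification from fluorescence labels.

#' Differentiation Efficiency Index of a fluorescence image
#'
#' For a fluorescence image with intensities in [0,1], the index is the sum
#' of intensities strictly exceeding the threshold \code{alpha}, divided by
#' the number of pixels:
#' \deqn{\mathrm{Index} = \frac{1}{W^2} \sum_{I_{ij} > \alpha} I_{ij}}
#' (with \eqn{W^2} replaced by the pixel count for non-square images).
#' The positive fraction is the fraction of pixels above \code{alpha} and is
#' the image-based proxy used for percentage-of-positive-cells labeling.
#'
#' @param fluor a \linkS4class{WellImage} (fluorescence channel) or matrix
#' @param alpha intensity threshold, default 0.5
#' @return An object of class \code{EfficiencyResult}: list with
#'   \code{index}, \code{positive_fraction} and \code{alpha}.
#' @export
#' @examples
#' img <- matrix(c(rep(0.8, 8), rep(0.2, 8)), 4, 4)
#' efficiencyIndex(img)$index  # 8 * 0.8 / 16 = 0.4
efficiencyIndex <- function(fluor, alpha = 0.5) {
  p <- if (is(fluor, "WellImage")) pixels(fluor) else fluor
  if (length(p) == 0L) stop("empty image")
  if (min(p) < -1e-9 || max(p) > 1 + 1e-9) stop("intensities must lie in [0,1]")
  pos <- p > alpha
  res <- list(index = sum(p[pos]) / length(p),
              positive_fraction = mean(pos),
              alpha = alpha)
  class(res) <- "EfficiencyResult"
  res
}

#' @export
print.EfficiencyResult <- function(x, ...) {
  cat(sprintf("Efficiency Index %.4f (positive fraction %.4f at alpha = %.2f)\n",
              x$index, x$positive_fraction, x$alpha))
  invisible(x)
}

#' Normalize efficiencies within groups
#'
#' Divides each well's efficiency by the maximum within its group (by
#' default its cell line), so every line's best well scores 1; groups whose
#' maximum is zero are set to 0 with a warning.
#'
#' @param records data.frame of well records
#' @param groupBy grouping column, default \code{"line"}
#' @param valueCol column to normalize, default \code{"efficiency_index"}
#' @return \code{records} with an added \code{efficiency_norm} column in
#'   [0,1].
#' @export
normalizeEfficiencies <- function(records, groupBy = "line",
                                  valueCol = "efficiency_index") {
  stopifnot(groupBy %in% names(records), valueCol %in% names(records))
  v <- records[[valueCol]]
  g <- records[[groupBy]]
  out <- numeric(length(v))
  for (grp in unique(g)) {
    i <- g == grp
    m <- max(v[i])
    if (m <= 0) {
      warning("group '", grp, "' has zero maximum efficiency; set to 0")
      out[i] <- 0
    } else out[i] <- v[i] / m
  }
  records$efficiency_norm <- out
  records
}
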