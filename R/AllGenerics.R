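#' @rdname WellImage-class
#' @param object,x a \linkS4class{WellImage}, \linkS4class{RegionMask} or
#'   \linkS4class{ImageStream}
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname WellImage-class
#' @export
setGeneric("wellId", function(x) standardGeneric("wellId"))

#' @rdname WellImage-class
#' @export
setGeneric("channel", function(x) standardGeneric("channel"))

#' @rdname RegionMask-class
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

#' @rdname ImageStream-class
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname ImageStream-class
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' @rdname WellImage-class
#' @export
setMethod("pixels", "WellImage", function(x) x@pixels)

#' @rdname WellImage-class
#' @export
setMethod("wellId", "WellImage", function(x) x@wellId)

#' @rdname RegionMask-class
#' @export
setMethod("wellId", "RegionMask", function(x) x@wellId)

#' @rdname ImageStream-class
#' @export
setMethod("wellId", "ImageStream", function(x) x@wellId)

#' @rdname WellImage-class
#' @export
setMethod("channel", "WellImage", function(x) x@channel)

#' @rdname RegionMask-class
#' @export
setMethod("maskLabels", "RegionMask", function(x) x@labels)

#' @rdname ImageStream-class
#' @export
setMethod("frames", "ImageStream", function(x) x@frames)

#' @rdname ImageStream-class
#' @export
setMethod("timestamps", "ImageStream", function(x) x@timestamps)

#' @rdname WellImage-class
#' @export
setMethod("dim", "WellImage", function(x) dim(x@pixels))

#' @rdname RegionMask-class
#' @export
setMethod("dim", "RegionMask", function(x) dim(x@labels))

setMethod("show", "WellImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("WellImage '%s' [%s] %d x %d px, intensity range [%.3f, %.3f]\n",
              object@wellId, object@channel, d[1], d[2],
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "RegionMask", function(object) {
  pal <- maskPalette()
  tab <- table(factor(object@labels, levels = pal, labels = names(pal)))
  d <- dim(object@labels)
  cat(sprintf("RegionMask '%s' %d x %d px\n", object@wellId, d[1], d[2]))
  frac <- round(tab / length(object@labels), 3)
  cat("  label fractions:", paste(names(frac), frac, sep = "=", collapse = " "), "\n")
})

setMethod("show", "ImageStream", function(object) {
  d <- dim(object@frames[[1]]@pixels)
  cat(sprintf("ImageStream '%s': 10 frames %d x %d px over %.1f-%.1f h, CHIR %.3g uM / %.3g h\n",
              object@wellId, d[1], d[2], min(object@timestamps),
              max(object@timestamps), object@chirUm, object@chirH))
})

setMethod("show", "SyntheticPlan", function(object) {
  cat(sprintf("SyntheticPlan: %d wells, %d line(s), %d concentration(s) x %d duration(s), %d px, seed %d\n",
              object@nWells, length(object@cellLines),
              length(object@concentrations), length(object@durations),
              object@imageSize, object@seed))
})
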