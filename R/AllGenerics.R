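#' Accessors for eosinQuant objects
#'
#' `wavelengths()` returns the band-center grid of a stack, profile, peak
#' map or phantom spec; `pixelSize()` the physical pixel size in
#' micrometres; `nPlanes()` the number of spectral planes; `planeAt()` one
#' plane by wavelength; `fitc()`/`tritc()` the channel images;
#' `tissueMask()`/`bloodMask()` the ground-truth masks;
#' `trueBloodPercent()` the exact ground-truth blood fraction;
#' `bloodPercent()` the estimated blood-to-tissue percentage;
#' `threshold()` the selected grey level.
#'
#' @param x an eosinQuant object.
#' @param wavelength band-center wavelength in nm (must be on the grid).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("nPlanes", function(x) standardGeneric("nPlanes"))
#' @rdname accessors
#' @export
setGeneric("planeAt", function(x, wavelength) standardGeneric("planeAt"))
#' @rdname accessors
#' @export
setGeneric("fitc", function(x) standardGeneric("fitc"))
#' @rdname accessors
#' @export
setGeneric("tritc", function(x) standardGeneric("tritc"))
#' @rdname accessors
#' @export
setGeneric("tissueMask", function(x) standardGeneric("tissueMask"))
#' @rdname accessors
#' @export
setGeneric("bloodMask", function(x) standardGeneric("bloodMask"))
#' @rdname accessors
#' @export
setGeneric("trueBloodPercent", function(x) standardGeneric("trueBloodPercent"))
#' @rdname accessors
#' @export
setGeneric("bloodPercent", function(x) standardGeneric("bloodPercent"))
#' @rdname accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname accessors
#' @export
setMethod("wavelengths", "LambdaStack", function(x) x@wavelengths)
#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectrumProfile", function(x) x@wavelengths)
#' @rdname accessors
#' @export
setMethod("wavelengths", "PeakMap", function(x) x@wavelengths)
#' @rdname accessors
#' @export
setMethod("wavelengths", "PhantomSpec", function(x) x@wavelengths)

#' @rdname accessors
#' @export
setMethod("pixelSize", "LambdaStack", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "ChannelPair", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "PhantomSpec", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("nPlanes", "LambdaStack", function(x) dim(x@data)[3])

#' @rdname accessors
#' @export
setMethod("planeAt", "LambdaStack", function(x, wavelength) {
  i <- match(wavelength, x@wavelengths)
  if (is.na(i))
    stop("wavelength ", wavelength, " nm is not on the stack's band grid")
  x@data[, , i]
})

#' @rdname accessors
#' @export
setMethod("fitc", "ChannelPair", function(x) x@fitc)
#' @rdname accessors
#' @export
setMethod("tritc", "ChannelPair", function(x) x@tritc)

#' @rdname accessors
#' @export
setMethod("tissueMask", "Phantom", function(x) x@tissueMask)
#' @rdname accessors
#' @export
setMethod("bloodMask", "Phantom", function(x) x@bloodMask)
#' @rdname accessors
#' @export
setMethod("trueBloodPercent", "Phantom", function(x) x@trueBloodPercent)

#' @rdname accessors
#' @export
setMethod("tissueMask", "QuantResult", function(x) x@intermediates$tissueMask)
#' @rdname accessors
#' @export
setMethod("bloodMask", "QuantResult", function(x) x@intermediates$bloodMask)
#' @rdname accessors
#' @export
setMethod("bloodPercent", "QuantResult", function(x) x@bloodPercent)

#' @rdname accessors
#' @export
setMethod("threshold", "ThresholdResult", function(x) x@threshold)

#' Extract the stack or channels from a Phantom
#'
#' @param x a [Phantom-class].
#' @return `lambdaStack()` returns the [LambdaStack-class]; `channels()` the
#'   [ChannelPair-class]; `phantomSpec()` the generating
#'   [PhantomSpec-class].
#' @export
setGeneric("lambdaStack", function(x) standardGeneric("lambdaStack"))
#' @rdname lambdaStack
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
#' @rdname lambdaStack
#' @export
setGeneric("phantomSpec", function(x) standardGeneric("phantomSpec"))
#' @rdname lambdaStack
#' @export
setMethod("lambdaStack", "Phantom", function(x) x@stack)
#' @rdname lambdaStack
#' @export
setMethod("channels", "Phantom", function(x) x@channels)
#' @rdname lambdaStack
#' @export
setMethod("phantomSpec", "Phantom", function(x) x@spec)

setMethod("show", "SpectralModel", function(object) {
  cat(sprintf("SpectralModel: peak %g nm, sigma %g nm, amplitude %g\n",
              object@peak, object@sigma, object@amplitude))
})

setMethod("show", "LambdaStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("LambdaStack: %d x %d px, %d bands (%g-%g nm)",
              d[1], d[2], d[3], min(object@wavelengths),
              max(object@wavelengths)))
  if (!is.na(object@pixelSize))
    cat(sprintf(", %g um/px", object@pixelSize))
  cat("\n")
})

setMethod("show", "ChannelPair", function(object) {
  d <- dim(object@fitc)
  cat(sprintf("ChannelPair: %d x %d px (FITC + TRITC)", d[1], d[2]))
  if (!is.na(object@pixelSize))
    cat(sprintf(", %g um/px", object@pixelSize))
  cat("\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: %d x %d px at %g um/px, %d bands, ",
                     "%d RBCs of %g um, seed %d\n"),
              object@width, object@height, object@pixelSize,
              length(object@wavelengths), object@rbcCount,
              object@rbcDiameter, object@seed))
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom: %d x %d px, tissue %d px, blood %d px (%.2f%%)\n",
              nrow(object@tissueMask), ncol(object@tissueMask),
              sum(object@tissueMask), sum(object@bloodMask),
              object@trueBloodPercent))
})

setMethod("show", "SpectrumProfile", function(object) {
  pk <- object@wavelengths[which.max(object@meanIntensity)]
  cat(sprintf("SpectrumProfile: %d bands, %d px averaged, peak at %g nm\n",
              length(object@wavelengths), object@nPixels, pk))
})

setMethod("show", "PeakMap", function(object) {
  cat(sprintf("PeakMap: %d x %d px, %d valid (%.1f%%)\n",
              nrow(object@peak), ncol(object@peak), sum(object@valid),
              100 * mean(object@valid)))
})

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf("ThresholdResult: threshold %d, fuzziness %.5f (%d candidates)\n",
              object@threshold, object@fuzziness,
              length(object@candidates)))
})

setMethod("show", "QuantResult", function(object) {
  cat("QuantResult\n")
  cat(sprintf("  tissue: threshold %d, area %d px", object@tissueThreshold,
              object@tissueAreaPx))
  if (!is.na(object@tissueAreaUm2))
    cat(sprintf(" (%.2f um^2)", object@tissueAreaUm2))
  cat(sprintf("\n  blood:  threshold %d, area %d px", object@bloodThreshold,
              object@bloodAreaPx))
  if (!is.na(object@bloodAreaUm2))
    cat(sprintf(" (%.2f um^2)", object@bloodAreaUm2))
  cat(sprintf("\n  blood-to-tissue: %.2f%%\n", object@bloodPercent))
})
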