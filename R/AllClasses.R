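#' @import methods
NULL

#' Gaussian emission model for a fluorophore population
#'
#' A single-Gaussian model of an emission spectrum, parameterised by peak
#' wavelength, bandwidth (standard deviation) and relative amplitude. Eosin Y
#' bound to bulk tissue peaks near 550 nm; bound to erythrocytes the peak
#' red-shifts to about 570 nm and the signal is brighter.
#'
#' @slot peak peak emission wavelength in nm (within 400--750).
#' @slot sigma Gaussian bandwidth (standard deviation) in nm, > 0.
#' @slot amplitude relative intensity at the peak, dimensionless, > 0.
#'
#' @seealso [emissionSpectrum()], [tissueModel()], [bloodModel()]
#' @export
setClass("SpectralModel",
  representation(peak = "numeric", sigma = "numeric", amplitude = "numeric"))

setValidity("SpectralModel", function(object) {
  msg <- NULL
  if (length(object@peak) != 1L || is.na(object@peak) ||
      object@peak < 400 || object@peak > 750)
    msg <- c(msg, "peak must be a single wavelength within [400, 750] nm")
  if (length(object@sigma) != 1L || is.na(object@sigma) || object@sigma <= 0)
    msg <- c(msg, "sigma must be a single positive bandwidth (nm)")
  if (length(object@amplitude) != 1L || is.na(object@amplitude) ||
      object@amplitude <= 0)
    msg <- c(msg, "amplitude must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SpectralModel
#'
#' @param peak peak emission wavelength, nm.
#' @param sigma Gaussian bandwidth, nm. Default 30.
#' @param amplitude relative peak intensity. Default 1.
#' @return A [SpectralModel-class] object.
#' @examples
#' tissue <- SpectralModel(550)
#' blood  <- SpectralModel(570, amplitude = 2)
#' @export
SpectralModel <- function(peak, sigma = 30, amplitude = 1) {
  new("SpectralModel", peak = as.numeric(peak), sigma = as.numeric(sigma),
      amplitude = as.numeric(amplitude))
}

#' Default eosin emission models for tissue and blood
#'
#' `tissueModel()` returns the default model for eosin bound to bulk tissue
#' (peak 550 nm); `bloodModel()` the red-shifted, brighter model for eosin
#' bound to erythrocytes (peak 570 nm, twice the amplitude).
#'
#' @return A [SpectralModel-class] object.
#' @export
tissueModel <- function() SpectralModel(550, sigma = 30, amplitude = 1)

#' @rdname tissueModel
#' @export
bloodModel <- function() SpectralModel(570, sigma = 30, amplitude = 2)

#' Lambda stack: co-registered emission-band images
#'
#' An ordered set of intensity planes of the same field, one per narrow
#' emission wavelength band (band centers in `wavelengths`). The canonical
#' acquisition steps a 10-nm filter from 480 to 690 nm.
#'
#' @slot data numeric array `[rows, cols, bands]`, intensities >= 0.
#' @slot wavelengths strictly increasing band-center wavelengths, nm.
#' @slot pixelSize physical pixel size in micrometres, or `NA` if unknown.
#'
#' @seealso [LambdaStack()], [peakWavelengthMap()], [integrateBand()]
#' @export
setClass("LambdaStack",
  representation(data = "array", wavelengths = "numeric",
                 pixelSize = "numeric"))

setValidity("LambdaStack", function(object) {
  msg <- NULL
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a 3-D array [rows, cols, bands]")
  else if (d[3] != length(object@wavelengths))
    msg <- c(msg, "number of planes must equal number of wavelengths")
  if (length(object@wavelengths) > 1L &&
      any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (anyNA(object@data) || any(object@data < 0))
    msg <- c(msg, "intensities must be finite and >= 0")
  if (length(object@pixelSize) != 1L)
    msg <- c(msg, "pixelSize must be a single value (may be NA)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a LambdaStack
#'
#' @param data numeric array `[rows, cols, bands]` of non-negative
#'   intensities, or a list of equally sized matrices (one per band).
#' @param wavelengths band-center wavelengths in nm, strictly increasing,
#'   one per plane.
#' @param pixelSize physical pixel size in micrometres (optional).
#' @return A [LambdaStack-class] object.
#' @export
LambdaStack <- function(data, wavelengths, pixelSize = NA_real_) {
  if (is.list(data)) {
    d <- dim(data[[1]])
    data <- array(unlist(data, use.names = FALSE),
                  dim = c(d[1], d[2], length(data)))
  }
  new("LambdaStack", data = data, wavelengths = as.numeric(wavelengths),
      pixelSize = as.numeric(pixelSize))
}

#' Co-registered FITC and TRITC channel images
#'
#' Holds the green (FITC, emission 520--540 nm) and red (TRITC, emission
#' 570--610 nm) channel images of one field, with optional physical pixel
#' size. This is the input to the blood-quantification pipeline.
#'
#' @slot fitc numeric matrix, FITC intensities >= 0.
#' @slot tritc numeric matrix of identical dimensions, TRITC intensities >= 0.
#' @slot pixelSize physical pixel size in micrometres, or `NA`.
#'
#' @seealso [ChannelPair()], [quantifyBlood()]
#' @export
setClass("ChannelPair",
  representation(fitc = "matrix", tritc = "matrix", pixelSize = "numeric"))

setValidity("ChannelPair", function(object) {
  msg <- NULL
  if (!identical(dim(object@fitc), dim(object@tritc)))
    msg <- c(msg, "fitc and tritc must have identical dimensions")
  if (anyNA(object@fitc) || anyNA(object@tritc) ||
      any(object@fitc < 0) || any(object@tritc < 0))
    msg <- c(msg, "intensities must be finite and >= 0")
  if (length(object@pixelSize) != 1L)
    msg <- c(msg, "pixelSize must be a single value (may be NA)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a ChannelPair
#'
#' @param fitc,tritc numeric matrices of identical dimensions.
#' @param pixelSize physical pixel size in micrometres (optional).
#' @return A [ChannelPair-class] object.
#' @export
ChannelPair <- function(fitc, tritc, pixelSize = NA_real_) {
  new("ChannelPair", fitc = fitc, tritc = tritc,
      pixelSize = as.numeric(pixelSize))
}

#' Specification of a synthetic phantom
#'
#' All parameters of one synthetic H&E-like field: geometry, spectral models,
#' erythrocyte geometry and count, vessel regions, noise, and the mandatory
#' random seed. Defaults mirror the reported imaging conditions: emission
#' sampled 480--690 nm in 10-nm steps, tissue peak 550 nm, blood peak 570 nm
#' and brighter, ~5-micron donut-shaped erythrocytes.
#'
#' @slot width,height image size in pixels.
#' @slot pixelSize micrometres per pixel (default 0.32).
#' @slot wavelengths emission band centers, nm, strictly increasing.
#' @slot tissueModel,bloodModel [SpectralModel-class] objects; blood must be
#'   brighter than tissue unless deliberately overridden.
#' @slot rbcDiameter erythrocyte outer diameter in micrometres (default 5).
#' @slot rbcCount number of erythrocytes to place (>= 0).
#' @slot vesselRegions list of ellipses, each
#'   `list(center = c(x, y), axes = c(a, b), angle = degrees)` in pixel
#'   coordinates (x = column, y = row, origin top-left).
#' @slot tissueFillFraction fraction of the field covered by tissue, [0, 1].
#' @slot noise `list(poissonScale, gaussianSigma)`; `poissonScale = 0`
#'   disables shot noise, `gaussianSigma = 0` disables read noise.
#' @slot seed integer random seed; generation is always seeded.
#'
#' @seealso [PhantomSpec()], [renderPhantom()]
#' @export
setClass("PhantomSpec",
  representation(width = "integer", height = "integer",
                 pixelSize = "numeric", wavelengths = "numeric",
                 tissueModel = "SpectralModel", bloodModel = "SpectralModel",
                 rbcDiameter = "numeric", rbcCount = "integer",
                 vesselRegions = "list", tissueFillFraction = "numeric",
                 noise = "list", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- NULL
  if (object@width < 8L || object@height < 8L)
    msg <- c(msg, "width and height must be at least 8 pixels")
  if (length(object@wavelengths) < 2L ||
      any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing with >= 2 entries")
  if (object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be positive")
  if (object@rbcDiameter / object@pixelSize < 3)
    msg <- c(msg, "rbcDiameter must span >= 3 pixels to be resolvable")
  if (object@rbcCount < 0L)
    msg <- c(msg, "rbcCount must be >= 0")
  if (object@tissueFillFraction < 0 || object@tissueFillFraction > 1)
    msg <- c(msg, "tissueFillFraction must be within [0, 1]")
  if (!all(c("poissonScale", "gaussianSigma") %in% names(object@noise)) ||
      object@noise$poissonScale < 0 || object@noise$gaussianSigma < 0)
    msg <- c(msg, "noise must be list(poissonScale >= 0, gaussianSigma >= 0)")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "a single integer seed is required; unseeded generation is not supported")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PhantomSpec
#'
#' The seed is a required argument: phantom generation is always
#' deterministic and unseeded generation is an error by design.
#'
#' @param seed integer random seed (required).
#' @param width,height image size in pixels. Default 256 x 256.
#' @param pixelSize micrometres per pixel. Default 0.32.
#' @param wavelengths emission band centers in nm. Default
#'   `seq(480, 690, by = 10)`.
#' @param tissueModel,bloodModel emission models; defaults [tissueModel()]
#'   (peak 550 nm) and [bloodModel()] (peak 570 nm, 2x amplitude). A blood
#'   model dimmer than tissue is accepted but warned about.
#' @param rbcDiameter erythrocyte outer diameter, micrometres. Default 5.
#' @param rbcCount number of erythrocytes. Default 30.
#' @param vesselRegions list of ellipse descriptors (see
#'   [PhantomSpec-class]). Default: one centred ellipse with semi-axes 35%
#'   of the field size.
#' @param tissueFillFraction tissue coverage fraction. Default 0.65,
#'   lung-like: alveolar tissue leaves a substantial airspace background.
#' @param noise `list(poissonScale, gaussianSigma)`. Default
#'   `list(poissonScale = 100, gaussianSigma = 0.01)`. Use [noNoise()] for a
#'   noise-free phantom.
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- PhantomSpec(seed = 1, noise = noNoise())
#' @export
PhantomSpec <- function(seed, width = 256L, height = 256L, pixelSize = 0.32,
                        wavelengths = seq(480, 690, by = 10),
                        tissueModel = eosinQuant::tissueModel(),
                        bloodModel = eosinQuant::bloodModel(),
                        rbcDiameter = 5, rbcCount = 30L,
                        vesselRegions = NULL, tissueFillFraction = 0.65,
                        noise = list(poissonScale = 100, gaussianSigma = 0.01)) {
  if (missing(seed))
    stop("a seed is required; unseeded phantom generation is an error")
  if (is.null(vesselRegions))
    vesselRegions <- list(list(center = c(width / 2, height / 2),
                               axes = c(width * 0.35, height * 0.35),
                               angle = 0))
  if (bloodModel@amplitude <= tissueModel@amplitude)
    warning("bloodModel amplitude <= tissueModel amplitude: ",
            "blood will not appear brighter than tissue")
  new("PhantomSpec", width = as.integer(width), height = as.integer(height),
      pixelSize = pixelSize, wavelengths = as.numeric(wavelengths),
      tissueModel = tissueModel, bloodModel = bloodModel,
      rbcDiameter = rbcDiameter, rbcCount = as.integer(rbcCount),
      vesselRegions = vesselRegions,
      tissueFillFraction = tissueFillFraction,
      noise = noise, seed = as.integer(seed))
}

#' Noise-free noise settings
#'
#' Convenience for `list(poissonScale = 0, gaussianSigma = 0)`.
#' @return A list suitable for the `noise` argument of [PhantomSpec()].
#' @export
noNoise <- function() list(poissonScale = 0, gaussianSigma = 0)

#' Synthetic phantom with ground truth
#'
#' A rendered synthetic scene: the lambda stack, the derived FITC/TRITC
#' channel pair, binary ground-truth masks and the exact blood-to-tissue
#' percentage. Erythrocytes always lie inside tissue, so
#' `bloodMask <= tissueMask` everywhere.
#'
#' @slot spec the [PhantomSpec-class] that produced the phantom.
#' @slot stack the rendered [LambdaStack-class] (noise applied).
#' @slot channels the [ChannelPair-class] integrated from the stack.
#' @slot tissueMask,bloodMask logical matrices; `bloodMask` is a subset of
#'   `tissueMask`.
#' @slot trueBloodPercent exactly
#'   `100 * sum(bloodMask) / sum(tissueMask)`.
#'
#' @seealso [renderPhantom()]
#' @export
setClass("Phantom",
  representation(spec = "PhantomSpec", stack = "LambdaStack",
                 channels = "ChannelPair", tissueMask = "matrix",
                 bloodMask = "matrix", trueBloodPercent = "numeric"))

setValidity("Phantom", function(object) {
  msg <- NULL
  dm <- dim(object@tissueMask)
  if (!identical(dim(object@bloodMask), dm) ||
      !identical(dim(object@stack@data)[1:2], dm))
    msg <- c(msg, "stack planes and masks must share identical dimensions")
  if (any(object@bloodMask & !object@tissueMask))
    msg <- c(msg, "bloodMask must be a subset of tissueMask")
  expected <- if (sum(object@tissueMask) == 0) 0 else
    100 * sum(object@bloodMask) / sum(object@tissueMask)
  if (!isTRUE(all.equal(object@trueBloodPercent, expected)))
    msg <- c(msg, "trueBloodPercent must equal 100 * |bloodMask| / |tissueMask|")
  if (is.null(msg)) TRUE else msg
})

#' Mean emission spectrum over a region of interest
#'
#' @slot wavelengths band centers, nm.
#' @slot meanIntensity mean intensity per band over the ROI.
#' @slot nPixels number of ROI pixels averaged (>= 1).
#'
#' @seealso [extractSpectrum()], [normalizeSpectrum()]
#' @export
setClass("SpectrumProfile",
  representation(wavelengths = "numeric", meanIntensity = "numeric",
                 nPixels = "integer"))

setValidity("SpectrumProfile", function(object) {
  msg <- NULL
  if (length(object@wavelengths) != length(object@meanIntensity))
    msg <- c(msg, "wavelengths and meanIntensity must have equal length")
  if (object@nPixels < 1L)
    msg <- c(msg, "nPixels must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Per-pixel peak emission wavelength map
#'
#' For every sufficiently bright pixel, the wavelength (in nm, on the
#' stack's band grid) at which its emission spectrum peaks; dim pixels are
#' invalid and carry `NA`.
#'
#' @slot peak numeric matrix of peak wavelengths in nm; `NA` where invalid.
#' @slot valid logical matrix marking pixels bright enough to call a peak.
#' @slot wavelengths the band grid the peaks were taken from.
#'
#' @seealso [peakWavelengthMap()], [classifyRedshift()]
#' @export
setClass("PeakMap",
  representation(peak = "matrix", valid = "matrix",
                 wavelengths = "numeric"))

setValidity("PeakMap", function(object) {
  msg <- NULL
  if (!identical(dim(object@peak), dim(object@valid)))
    msg <- c(msg, "peak and valid must have identical dimensions")
  pv <- object@peak[object@valid]
  if (length(pv) && (anyNA(pv) || !all(pv %in% object@wavelengths)))
    msg <- c(msg, "every valid pixel's peak must be a member of the wavelength grid")
  if (any(!is.na(object@peak[!object@valid])))
    msg <- c(msg, "invalid pixels must carry the NA sentinel")
  if (is.null(msg)) TRUE else msg
})

#' Result of Huang fuzzy-entropy automatic thresholding
#'
#' @slot threshold selected grey level t in [0, 255]; foreground is the set
#'   of pixels with binned grey level strictly greater than t.
#' @slot fuzziness the minimal fuzzy entropy E(t).
#' @slot candidates candidate grey levels examined.
#' @slot entropy E(t) for each candidate.
#'
#' @seealso [huangThreshold()], [applyThreshold()]
#' @export
setClass("ThresholdResult",
  representation(threshold = "integer", fuzziness = "numeric",
                 candidates = "integer", entropy = "numeric"))

setValidity("ThresholdResult", function(object) {
  msg <- NULL
  if (length(object@candidates) != length(object@entropy))
    msg <- c(msg, "candidates and entropy must have equal length")
  if (object@fuzziness < -1e-12)
    msg <- c(msg, "fuzziness must be >= 0")
  i <- match(object@threshold, object@candidates)
  if (is.na(i) || object@entropy[i] > min(object@entropy) + 1e-12)
    msg <- c(msg, "threshold must attain the minimum of the entropy curve")
  if (is.null(msg)) TRUE else msg
})

#' Blood-quantification result
#'
#' Output of the two-channel quantification pipeline: the automatic
#' thresholds, tissue and blood areas in pixels (and square micrometres when
#' the pixel size is known), the blood-to-tissue percentage, and all
#' intermediate images for audit.
#'
#' @slot tissueThreshold,bloodThreshold Huang grey-level thresholds (0--255)
#'   of the mean and the background-corrected subtracted image.
#' @slot tissueAreaPx,bloodAreaPx mask areas in pixels.
#' @slot tissueAreaUm2,bloodAreaUm2 areas in square micrometres
#'   (`NA` when the pixel size is unknown).
#' @slot bloodPercent `100 * bloodAreaPx / tissueAreaPx`.
#' @slot intermediates named list: `fitcNorm`, `tritcNorm`, `meanImage`,
#'   `subtracted`, `corrected`, `tissueMask`, `bloodMask`.
#'
#' @seealso [quantifyBlood()]
#' @export
setClass("QuantResult",
  representation(tissueThreshold = "integer", bloodThreshold = "integer",
                 tissueAreaPx = "integer", bloodAreaPx = "integer",
                 tissueAreaUm2 = "numeric", bloodAreaUm2 = "numeric",
                 bloodPercent = "numeric", intermediates = "list"))

setValidity("QuantResult", function(object) {
  msg <- NULL
  if (object@tissueAreaPx <= 0L)
    msg <- c(msg, "tissueAreaPx must be positive")
  expected <- 100 * object@bloodAreaPx / object@tissueAreaPx
  if (!isTRUE(all.equal(object@bloodPercent, expected)))
    msg <- c(msg, "bloodPercent must equal 100 * bloodAreaPx / tissueAreaPx")
  if (is.null(msg)) TRUE else msg
})
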