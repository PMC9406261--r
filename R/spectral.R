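#' Mean emission spectrum over a region of interest
#'
#' Averages each spectral plane over the ROI pixels. No normalisation is
#' applied; see [normalizeSpectrum()].
#'
#' @param stack a [LambdaStack-class].
#' @param roi logical matrix of the planes' dimensions; must select at
#'   least one pixel.
#' @return A [SpectrumProfile-class].
#' @examples
#' ph <- renderPhantom(PhantomSpec(seed = 1, noise = noNoise()))
#' sp <- extractSpectrum(lambdaStack(ph), tissueMask(ph) & !bloodMask(ph))
#' wavelengths(sp)[which.max(sp@meanIntensity)]   # 550 nm
#' @export
extractSpectrum <- function(stack, roi) {
  stopifnot(is(stack, "LambdaStack"))
  roi <- roi > 0
  if (!identical(dim(roi), dim(stack@data)[1:2]))
    stop("ROI dimensions must match the stack planes")
  n <- sum(roi)
  if (n == 0L)
    stop("empty ROI")
  k <- nPlanes(stack)
  mi <- vapply(seq_len(k), function(i) mean(stack@data[, , i][roi]),
               numeric(1))
  new("SpectrumProfile", wavelengths = stack@wavelengths,
      meanIntensity = mi, nPixels = as.integer(n))
}

#' Normalise a spectrum to unit peak
#'
#' Divides the mean intensities by their maximum, so the peak is 1 and the
#' peak location is unchanged. Idempotent.
#'
#' @param profile a [SpectrumProfile-class] with a positive maximum.
#' @return A [SpectrumProfile-class].
#' @export
normalizeSpectrum <- function(profile) {
  stopifnot(is(profile, "SpectrumProfile"))
  m <- max(profile@meanIntensity)
  if (m <= 0)
    stop("zero spectrum")
  new("SpectrumProfile", wavelengths = profile@wavelengths,
      meanIntensity = profile@meanIntensity / m,
      nPixels = profile@nPixels)
}

## Gaussian smoothing along the wavelength axis only (never spatial).
## X is [pixels x bands]; sigma in nm on the (possibly non-uniform) grid.
## The kernel is renormalised at the edges so flat spectra stay flat.
smoothAlongLambda <- function(X, wavelengths, sigma) {
  if (sigma <= 0)
    return(X)
  W <- outer(wavelengths, wavelengths,
             function(a, b) exp(-(a - b)^2 / (2 * sigma^2)))
  W <- W / rowSums(W)
  X %*% t(W)
}

#' Per-pixel peak emission wavelength map
#'
#' For every pixel, the wavelength (on the stack's band grid) of the
#' maximum of its spectrum, after optional Gaussian smoothing along the
#' wavelength axis. Smoothing is spectral only, never spatial, so small
#' objects are not blurred. Ties break toward the lowest wavelength.
#' Pixels whose maximum (smoothed) intensity falls below `minIntensity`
#' are invalid and carry `NA`; when `minIntensity` is `NULL` the validity
#' mask defaults to the Huang threshold of the stack's
#' maximum-intensity projection.
#'
#' @param stack a [LambdaStack-class] with at least 2 planes.
#' @param minIntensity intensity cutoff for calling a peak, or `NULL` for
#'   the automatic (Huang) default.
#' @param smoothSigma Gaussian bandwidth (nm) of the spectral smoothing;
#'   0 disables smoothing.
#' @return A [PeakMap-class].
#' @export
peakWavelengthMap <- function(stack, minIntensity = NULL, smoothSigma = 0) {
  stopifnot(is(stack, "LambdaStack"))
  if (nPlanes(stack) < 2L)
    stop("need >=2 spectral planes")
  if (smoothSigma < 0)
    stop("smoothSigma must be >= 0")
  d <- dim(stack@data)
  X <- matrix(stack@data, d[1] * d[2], d[3])
  Xs <- smoothAlongLambda(X, stack@wavelengths, smoothSigma)
  peakIdx <- max.col(Xs, ties.method = "first")
  peakInt <- Xs[cbind(seq_len(nrow(Xs)), peakIdx)]
  if (is.null(minIntensity)) {
    maxProj <- apply(stack@data, c(1, 2), max)
    valid <- applyThreshold(maxProj, huangThreshold(maxProj))
  } else {
    if (minIntensity < 0)
      stop("minIntensity must be >= 0")
    valid <- matrix(peakInt >= minIntensity, d[1], d[2])
  }
  peak <- matrix(stack@wavelengths[peakIdx], d[1], d[2])
  peak[!valid] <- NA_real_
  new("PeakMap", peak = peak, valid = valid,
      wavelengths = stack@wavelengths)
}

#' Classify red-shifted (blood-like) pixels
#'
#' Valid pixels whose peak emission wavelength is at or beyond the cutoff.
#' The default cutoff of 560 nm is the midpoint between the tissue peak
#' (550 nm) and the erythrocyte peak (570 nm). Monotone in the cutoff:
#' raising it never adds pixels.
#'
#' @param peakmap a [PeakMap-class].
#' @param cutoff wavelength in nm; must lie within the map's band range.
#' @return Logical matrix: `TRUE` where the peak is red-shifted.
#' @export
classifyRedshift <- function(peakmap, cutoff = 560) {
  stopifnot(is(peakmap, "PeakMap"))
  rng <- range(peakmap@wavelengths)
  if (cutoff < rng[1] || cutoff > rng[2])
    stop("cutoff must lie within the stack's wavelength range [",
         rng[1], ", ", rng[2], "] nm")
  mask <- peakmap@valid & !is.na(peakmap@peak) & peakmap@peak >= cutoff
  mask[is.na(mask)] <- FALSE
  mask
}
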