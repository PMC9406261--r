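#' Evaluate a Gaussian emission spectrum on a wavelength grid
#'
#' Intensity at wavelength lambda is
#' `amplitude * exp(-(lambda - peak)^2 / (2 * sigma^2))`: non-negative
#' everywhere, maximal at the grid point nearest the peak.
#'
#' @param model a [SpectralModel-class].
#' @param grid strictly increasing wavelengths, nm.
#' @return Numeric vector of intensities, one per grid point.
#' @examples
#' emissionSpectrum(tissueModel(), seq(480, 690, by = 10))
#' @export
emissionSpectrum <- function(model, grid) {
  stopifnot(is(model, "SpectralModel"))
  if (length(grid) == 0L)
    stop("empty wavelength grid")
  if (any(diff(grid) <= 0))
    stop("wavelength grid must be strictly increasing")
  model@amplitude * exp(-(grid - model@peak)^2 / (2 * model@sigma^2))
}

## Rasterise one ellipse onto a logical matrix. Pixel-center sampling:
## pixel (row r, col c) has center (x = c, y = r), origin top-left.
rasterizeEllipse <- function(nrow, ncol, center, axes, angle = 0) {
  th <- angle * pi / 180
  x <- matrix(rep(seq_len(ncol), each = nrow), nrow)
  y <- matrix(rep(seq_len(nrow), ncol), nrow)
  dx <- x - center[1]
  dy <- y - center[2]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

## Distance-squared field from pixel centers to a point.
distSq <- function(nrow, ncol, center) {
  dx <- matrix(rep(seq_len(ncol), each = nrow), nrow) - center[1]
  dy <- matrix(rep(seq_len(nrow), ncol), nrow) - center[2]
  dx^2 + dy^2
}

## Rejection-sample rbc centers inside vessel regions, pairwise separation
## >= minDist (no overlap). Deterministic under the caller's seed scope.
placeRbcCenters <- function(count, vesselMask, nr, nc, minDist) {
  inVessel <- which(vesselMask)
  if (length(inVessel) == 0L)
    stop("no vessel region to place erythrocytes")
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  maxTries <- 1000L * count
  while (nrow(centers) < count) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop("cannot place ", count, " non-overlapping erythrocytes in the ",
           "vessel regions; enlarge them or reduce rbcCount")
    idx <- inVessel[sample.int(length(inVessel), 1L)]
    cy <- (idx - 1L) %% nr + 1L
    cx <- (idx - 1L) %/% nr + 1L
    jit <- stats::runif(2, -0.5, 0.5)
    cand <- c(cx + jit[1], cy + jit[2])
    if (nrow(centers) == 0L ||
        all((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 >=
            minDist^2))
      centers <- rbind(centers, cand)
  }
  centers
}

#' Render a synthetic phantom with known ground truth
#'
#' Builds a synthetic eosin-stained field: a textured tissue region (a
#' smoothed seeded random field thresholded to the requested fill fraction,
#' unioned with the vessel ellipses), donut-shaped erythrocytes (bright
#' annulus, dimmer core at 40% of the outer diameter and 30% intensity)
#' placed without overlap inside the vessel regions, a lambda stack in which
#' tissue pixels emit the tissue spectrum and erythrocyte pixels the
#' red-shifted blood spectrum, and FITC/TRITC channels integrated from the
#' stack. Shot (Poisson) and read (Gaussian) noise are applied to the stack
#' after rendering; masks and the true blood percentage are
#' noise-independent. Identical spec (including seed) gives bit-identical
#' output.
#'
#' @param spec a [PhantomSpec-class].
#' @param fitcBand,tritcBand emission bands (nm) used to derive the channel
#'   pair from the stack. Defaults 520--540 and 570--610, the standard
#'   filter-set passbands.
#' @return A [Phantom-class].
#' @examples
#' ph <- renderPhantom(PhantomSpec(seed = 1, rbcCount = 5, noise = noNoise()))
#' trueBloodPercent(ph)
#' @export
renderPhantom <- function(spec, fitcBand = c(520, 540),
                          tritcBand = c(570, 610)) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  h <- spec@height
  w <- spec@width
  withr::with_seed(spec@seed, {
    ## textured tissue field: smoothed white noise, thresholded by quantile
    field <- matrix(stats::rnorm(h * w), h, w)
    field <- as.matrix(EBImage::gblur(field, sigma = 8))
    tissue <- field >= stats::quantile(field, 1 - spec@tissueFillFraction)
    vessel <- matrix(FALSE, h, w)
    for (v in spec@vesselRegions)
      vessel <- vessel | rasterizeEllipse(h, w, v$center, v$axes,
                                          if (is.null(v$angle)) 0 else v$angle)
    tissue <- tissue | vessel

    ## erythrocytes: full disc is blood; annulus bright, core dim
    blood <- matrix(FALSE, h, w)
    bloodIntensity <- matrix(0, h, w)
    if (spec@rbcCount > 0L) {
      if (length(spec@vesselRegions) == 0L)
        stop("no vessel region to place erythrocytes")
      rOuter <- spec@rbcDiameter / 2 / spec@pixelSize
      rCore <- 0.4 * rOuter
      centers <- placeRbcCenters(spec@rbcCount, vessel, h, w,
                                 minDist = 2 * rOuter)
      for (i in seq_len(nrow(centers))) {
        d2 <- distSq(h, w, centers[i, ])
        disc <- d2 <= rOuter^2
        core <- d2 <= rCore^2
        blood <- blood | disc
        ## staining varies from cell to cell: per-cell brightness factor
        cellFactor <- stats::runif(1, 0.85, 1.15)
        bloodIntensity[disc & !core] <- cellFactor
        bloodIntensity[core] <- 0.3 * cellFactor
      }
      blood <- blood & tissue        # clip to tissue
      bloodIntensity[!blood] <- 0
    }

    ## contributions: blood displaces tissue under the cell footprint.
    ## Staining intensity varies smoothly across a section, so both the
    ## tissue and the erythrocytes are modulated by the same large-scale
    ## texture field (rescaled to [0.6, 1.4]); a flat field would be
    ## unrealistic and would make per-channel normalisation degenerate.
    texture <- field
    tmin <- min(texture[tissue])
    tmax <- max(texture[tissue])
    texture <- 0.6 + 0.8 * (texture - tmin) / (tmax - tmin)
    tissueContribution <- ifelse(tissue & !blood, texture, 0)

    tSpec <- emissionSpectrum(spec@tissueModel, spec@wavelengths)
    bSpec <- emissionSpectrum(spec@bloodModel, spec@wavelengths)
    k <- length(spec@wavelengths)
    stackData <- array(0, dim = c(h, w, k))
    for (i in seq_len(k))
      stackData[, , i] <- tissueContribution * tSpec[i] +
        bloodIntensity * bSpec[i]

    ## noise: scaled Poisson (shot) then additive Gaussian (read), clip at 0
    ps <- spec@noise$poissonScale
    gs <- spec@noise$gaussianSigma
    if (ps > 0)
      stackData[] <- stats::rpois(length(stackData), stackData * ps) / ps
    if (gs > 0)
      stackData[] <- stackData + stats::rnorm(length(stackData), sd = gs)
    stackData[stackData < 0] <- 0
  })

  stack <- LambdaStack(stackData, spec@wavelengths,
                       pixelSize = spec@pixelSize)
  pair <- ChannelPair(integrateBand(stack, fitcBand),
                      integrateBand(stack, tritcBand),
                      pixelSize = spec@pixelSize)
  pct <- if (sum(tissue) == 0) 0 else 100 * sum(blood) / sum(tissue)
  new("Phantom", spec = spec, stack = stack, channels = pair,
      tissueMask = tissue, bloodMask = blood, trueBloodPercent = pct)
}

#' Integrate lambda-stack planes over an emission band
#'
#' Sums, per pixel, all planes whose band centers lie within
#' `[band[1], band[2]]` inclusive. This emulates a band-pass filter set:
#' the FITC passband is 520--540 nm and the TRITC passband 570--610 nm.
#'
#' @param stack a [LambdaStack-class].
#' @param band numeric length-2, `c(low, high)` in nm.
#' @return Numeric matrix of integrated intensities.
#' @examples
#' ph <- renderPhantom(PhantomSpec(seed = 1, rbcCount = 0, noise = noNoise()))
#' green <- integrateBand(lambdaStack(ph), c(520, 540))
#' @export
integrateBand <- function(stack, band) {
  stopifnot(is(stack, "LambdaStack"), length(band) == 2L)
  if (band[1] > band[2])
    stop("band must be c(low, high) with low <= high")
  sel <- which(stack@wavelengths >= band[1] & stack@wavelengths <= band[2])
  if (length(sel) == 0L)
    stop("band outside stack range")
  out <- stack@data[, , sel[1]]
  for (i in sel[-1])
    out <- out + stack@data[, , i]
  out
}
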