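test_that("ROI spectra are per-band means over the ROI", {
  # constant planes: profile equals the constants
  k <- 5
  consts <- c(0.5, 1, 2, 4, 3)
  planes <- lapply(consts, function(c) matrix(c, 6, 6))
  st <- LambdaStack(planes, seq(500, 540, by = 10))
  roi <- matrix(TRUE, 6, 6)
  sp <- extractSpectrum(st, roi)
  expect_equal(sp@meanIntensity, consts)
  expect_equal(sp@nPixels, 36L)

  # singleton ROI: the pixel's own values
  roi1 <- matrix(FALSE, 6, 6); roi1[2, 3] <- TRUE
  sp1 <- extractSpectrum(st, roi1)
  expect_equal(sp1@meanIntensity,
               vapply(1:k, function(i) st@data[2, 3, i], numeric(1)))

  expect_error(extractSpectrum(st, matrix(FALSE, 6, 6)), "empty ROI")
})

test_that("ROI spectrum extraction is linear in the stack", {
  wl <- seq(480, 550, by = 10)
  set.seed(31)
  a <- LambdaStack(array(runif(5 * 5 * 8), c(5, 5, 8)), wl)
  b <- LambdaStack(array(runif(5 * 5 * 8), c(5, 5, 8)), wl)
  ab <- LambdaStack(a@data + b@data, wl)
  roi <- matrix(rep(c(TRUE, FALSE), length.out = 25), 5, 5)
  expect_equal(extractSpectrum(ab, roi)@meanIntensity,
               extractSpectrum(a, roi)@meanIntensity +
                 extractSpectrum(b, roi)@meanIntensity)
})

test_that("tissue spectrum of a noise-free phantom peaks at 550 nm", {
  ph <- renderPhantom(smallSpec(seed = 4))
  sp <- extractSpectrum(lambdaStack(ph), tissueMask(ph) & !bloodMask(ph))
  expect_equal(wavelengths(sp)[which.max(sp@meanIntensity)], 550)
})

test_that("peak map equals a brute-force per-pixel argmax oracle", {
  set.seed(77)
  st <- LambdaStack(array(runif(5 * 5 * 8), c(5, 5, 8)),
                    seq(480, 550, by = 10))
  pm <- peakWavelengthMap(st, minIntensity = 0, smoothSigma = 0)
  for (r in 1:5) for (c in 1:5) {
    spec <- st@data[r, c, ]
    expect_identical(pm@peak[r, c],
                     st@wavelengths[which.max(spec)])  # first max = lowest
  }
})

test_that("peak map handles single maxima, ties and dim pixels", {
  wl <- seq(480, 690, by = 10)
  dat <- array(0, c(2, 2, length(wl)))
  dat[1, 1, wl == 680] <- 9                  # lone spike at 680
  dat[1, 2, wl %in% c(500, 600)] <- c(3, 3)  # tie -> lowest wavelength
  dat[2, 1, ] <- 0.01                        # dim everywhere
  dat[2, 2, wl == 550] <- 5
  st <- LambdaStack(dat, wl)
  pm <- peakWavelengthMap(st, minIntensity = 1, smoothSigma = 0)
  expect_equal(pm@peak[1, 1], 680)
  expect_equal(pm@peak[1, 2], 500)
  expect_true(is.na(pm@peak[2, 1]) && !pm@valid[2, 1])
  expect_equal(pm@peak[2, 2], 550)

  expect_error(
    peakWavelengthMap(LambdaStack(array(1, c(2, 2, 1)), 550)),
    "need >=2 spectral planes")
})

test_that("spectral smoothing acts along wavelength only", {
  wl <- seq(480, 690, by = 10)
  dat <- array(0, c(2, 2, length(wl)))
  # noisy double-bump spectrum at one pixel: smoothing merges to one peak
  dat[1, 1, ] <- exp(-(wl - 560)^2 / 800)
  dat[1, 1, wl == 490] <- dat[1, 1, wl == 490] + 0.9  # spurious spike
  dat[2, 2, wl == 550] <- 1
  st <- LambdaStack(dat, wl)
  raw <- peakWavelengthMap(st, minIntensity = 0, smoothSigma = 0)
  sm <- peakWavelengthMap(st, minIntensity = 0, smoothSigma = 15)
  expect_equal(raw@peak[1, 1], 560)   # spike 0.9 < bump 1.0
  expect_equal(sm@peak[1, 1], 560)
  # a narrow spike taller than the bump wins raw but loses smoothed
  dat[1, 1, wl == 490] <- 1.1
  st2 <- LambdaStack(dat, wl)
  expect_equal(peakWavelengthMap(st2, 0, 0)@peak[1, 1], 490)
  expect_equal(peakWavelengthMap(st2, 0, 15)@peak[1, 1], 560)
  # smoothing never touches neighbouring pixels
  expect_equal(peakWavelengthMap(st2, 0, 15)@peak[2, 2], 550)
})

test_that("red-shift classification recovers phantom blood", {
  ph <- defaultPhantom(seed = 1)
  pm <- peakWavelengthMap(lambdaStack(ph))
  mask <- classifyRedshift(pm, cutoff = 560)
  agreement <- mean(mask == bloodMask(ph))
  expect_gte(agreement, 0.95)
})

test_that("red-shift classification is monotone in the cutoff", {
  ph <- renderPhantom(smallSpec(seed = 19,
                                noise = list(poissonScale = 100,
                                             gaussianSigma = 0.01)))
  pm <- peakWavelengthMap(lambdaStack(ph))
  cutoffs <- c(500, 540, 560, 580, 620)
  sizes <- vapply(cutoffs, function(co) sum(classifyRedshift(pm, co)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))

  # trivial extremes
  pmAll550 <- new("PeakMap", peak = matrix(550, 3, 3),
                  valid = matrix(TRUE, 3, 3),
                  wavelengths = seq(480, 690, 10))
  expect_equal(sum(classifyRedshift(pmAll550, 560)), 0)
  pmAll570 <- new("PeakMap", peak = matrix(570, 3, 3),
                  valid = matrix(TRUE, 3, 3),
                  wavelengths = seq(480, 690, 10))
  expect_equal(sum(classifyRedshift(pmAll570, 560)), 9)
  expect_error(classifyRedshift(pmAll570, 700), "wavelength range")
})

test_that("spectrum normalisation rescales to unit peak and preserves argmax", {
  sp <- new("SpectrumProfile", wavelengths = c(500, 510, 520),
            meanIntensity = c(2, 4, 8), nPixels = 10L)
  n <- normalizeSpectrum(sp)
  expect_equal(n@meanIntensity, c(0.25, 0.5, 1.0))
  expect_equal(normalizeSpectrum(n)@meanIntensity, n@meanIntensity)

  set.seed(8)
  for (i in 1:10) {
    sp2 <- new("SpectrumProfile", wavelengths = seq(480, 550, 10),
               meanIntensity = runif(8, 0.01, 5), nPixels = 1L)
    expect_equal(which.max(normalizeSpectrum(sp2)@meanIntensity),
                 which.max(sp2@meanIntensity))
  }

  zero <- new("SpectrumProfile", wavelengths = c(500, 510),
              meanIntensity = c(0, 0), nPixels = 1L)
  expect_error(normalizeSpectrum(zero), "zero spectrum")
})
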