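test_that("emission spectrum follows the Gaussian closed form", {
  grid <- seq(480, 690, by = 10)

  # default tissue model peaks at the 550 nm grid point
  tis <- emissionSpectrum(tissueModel(), grid)
  expect_equal(grid[which.max(tis)], 550)

  # the value exactly at the peak is the amplitude
  expect_equal(emissionSpectrum(SpectralModel(570, 30, 1), 570), 1.0)

  # independent per-point evaluation via the normal density
  m <- SpectralModel(565, 20, 3)
  got <- emissionSpectrum(m, grid)
  oracle <- 3 * stats::dnorm(grid, 565, 20) / stats::dnorm(565, 565, 20)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_true(all(got >= 0))
})

test_that("emission spectrum rejects bad grids and models", {
  expect_error(emissionSpectrum(tissueModel(), numeric(0)),
               "empty wavelength grid")
  expect_error(emissionSpectrum(tissueModel(), c(500, 500, 510)),
               "strictly increasing")
  expect_error(SpectralModel(300), "400")
  expect_error(SpectralModel(550, sigma = -1), "sigma")
  expect_error(SpectralModel(550, amplitude = 0), "amplitude")
})

test_that("a phantom without erythrocytes has zero blood", {
  ph <- renderPhantom(smallSpec(seed = 7, rbcCount = 0L))
  expect_equal(sum(bloodMask(ph)), 0)
  expect_equal(trueBloodPercent(ph), 0)
})

test_that("phantom rendering is deterministic and seed-scoped", {
  sp <- smallSpec(seed = 11,
                  noise = list(poissonScale = 100, gaussianSigma = 0.01))
  a <- renderPhantom(sp)
  b <- renderPhantom(sp)
  expect_identical(a@stack@data, b@stack@data)
  expect_identical(tissueMask(a), tissueMask(b))
  expect_identical(bloodMask(a), bloodMask(b))

  # the generator must not disturb the caller's RNG stream
  set.seed(42); before <- stats::runif(3)
  set.seed(42); invisible(renderPhantom(sp)); after <- stats::runif(3)
  expect_identical(before, after)
})

test_that("erythrocytes require a vessel region", {
  expect_error(
    renderPhantom(PhantomSpec(seed = 1, width = 128L, height = 128L,
                              rbcCount = 3L, vesselRegions = list(),
                              noise = noNoise())),
    "no vessel region")
})

test_that("ground-truth blood percentage matches an independent area count", {
  ph <- renderPhantom(smallSpec(seed = 3, rbcCount = 6L))
  # independent route: flood-fill labelling of the mask, summed areas
  lab <- EBImage::bwlabel(bloodMask(ph))
  areas <- EBImage::computeFeatures.shape(lab)[, "s.area"]
  expect_equal(sum(areas), sum(bloodMask(ph)))
  expect_equal(trueBloodPercent(ph),
               100 * sum(areas) / sum(tissueMask(ph)))
  # erythrocytes lie inside tissue
  expect_false(any(bloodMask(ph) & !tissueMask(ph)))
})

test_that("masks and ground truth are invariant to noise settings", {
  nf <- renderPhantom(smallSpec(seed = 5))
  ns <- renderPhantom(smallSpec(seed = 5,
                                noise = list(poissonScale = 50,
                                             gaussianSigma = 0.05)))
  expect_identical(tissueMask(nf), tissueMask(ns))
  expect_identical(bloodMask(nf), bloodMask(ns))
  expect_identical(trueBloodPercent(nf), trueBloodPercent(ns))
  expect_false(identical(nf@stack@data, ns@stack@data))
})

test_that("blood is brighter than tissue in the TRITC band", {
  for (seed in c(2, 9, 21)) {
    ph <- renderPhantom(smallSpec(seed = seed))
    tr <- tritc(channels(ph))
    inBlood <- mean(tr[bloodMask(ph)])
    inTissue <- mean(tr[tissueMask(ph) & !bloodMask(ph)])
    expect_gt(inBlood, inTissue)
  }
})

test_that("band integration sums exactly the in-band planes", {
  ph <- renderPhantom(smallSpec(seed = 13))
  st <- lambdaStack(ph)

  fitc <- integrateBand(st, c(520, 540))
  expect_equal(fitc, planeAt(st, 520) + planeAt(st, 530) + planeAt(st, 540))

  # full-band integration equals the plane-wise total
  total <- integrateBand(st, c(480, 690))
  expect_equal(total, apply(st@data, c(1, 2), sum))

  # single-plane band is the identity
  expect_equal(integrateBand(st, c(570, 570)), planeAt(st, 570))

  expect_error(integrateBand(st, c(700, 720)), "band outside stack range")
})

test_that("band integration is additive over disjoint bands", {
  ph <- renderPhantom(smallSpec(seed = 17,
                                noise = list(poissonScale = 80,
                                             gaussianSigma = 0.02)))
  st <- lambdaStack(ph)
  ab <- integrateBand(st, c(480, 560)) + integrateBand(st, c(570, 690))
  expect_equal(ab, integrateBand(st, c(480, 690)))
})

test_that("phantom spec invariants are enforced", {
  expect_error(PhantomSpec(), "seed")
  expect_error(PhantomSpec(seed = 1, wavelengths = c(500, 490)),
               "strictly increasing")
  expect_error(PhantomSpec(seed = 1, pixelSize = 2.0), "resolvable")
  expect_warning(PhantomSpec(seed = 1, bloodModel = SpectralModel(570)),
                 "brighter")
})
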