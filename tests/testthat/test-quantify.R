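test_that("channel normalisation maps to [0,1] and preserves order", {
  expect_equal(normalizeChannel(matrix(c(0, 128, 255), 1)),
               matrix(c(0, 128 / 255, 1), 1))
  # already [0,1]-spanning image is unchanged
  img <- matrix(c(0, 0.3, 0.7, 1), 2)
  expect_equal(normalizeChannel(img), img)
  # rank order preserved
  set.seed(2)
  r <- matrix(runif(100, 5, 90), 10)
  expect_equal(order(normalizeChannel(r)), order(r))
  expect_equal(range(normalizeChannel(r)), c(0, 1))
  expect_error(normalizeChannel(matrix(4, 3, 3)), "constant")
})

test_that("mean and subtraction satisfy their analytic identities", {
  set.seed(3)
  f <- matrix(runif(64), 8)
  t <- matrix(runif(64), 8)
  m <- meanImage(f, t)
  expect_equal(meanImage(f, f), f)
  expect_equal(meanImage(matrix(0, 8, 8), matrix(1, 8, 8)),
               matrix(0.5, 8, 8))
  # mean - fitc == (tritc - fitc)/2, pixelwise, before clipping
  expect_equal(m - f, (t - f) / 2)
  # and the pipeline's clipped version
  expect_equal(subtractFitc(m, f), pmax((t - f) / 2, 0))
  expect_equal(subtractFitc(f, f), matrix(0, 8, 8))
  expect_error(meanImage(f, matrix(0, 4, 4)), "dimensions")
})

test_that("subtracted image amplifies blood over tissue on a phantom", {
  ph <- renderPhantom(smallSpec(seed = 23))
  f <- normalizeChannel(fitc(channels(ph)))
  t <- normalizeChannel(tritc(channels(ph)))
  sub <- subtractFitc(meanImage(f, t), f)
  expect_gt(mean(sub[bloodMask(ph)]),
            mean(sub[tissueMask(ph) & !bloodMask(ph)]))
})

test_that("background subtraction removes flat background, keeps spots", {
  expect_equal(backgroundSubtract(matrix(5, 40, 40), 10),
               matrix(0, 40, 40))

  # a narrow bright spot on a pedestal survives within 1% of its height
  img <- matrix(1, 120, 120)
  img[60:62, 60:62] <- 4
  out <- backgroundSubtract(img, 50)
  expect_equal(out[61, 61], 3, tolerance = 0.01)

  # output never exceeds the input
  set.seed(4)
  r <- matrix(runif(900), 30)
  o <- backgroundSubtract(r, 5)
  expect_true(all(o <= r + 1e-12) && all(o >= 0))

  expect_error(backgroundSubtract(r, 0), "radiusPx")
  expect_error(backgroundSubtract(r, 40), "larger than the image")
})

test_that("quantification recovers phantom ground truth", {
  # no blood present: blood mask covers at most 0.5% of tissue
  empty <- renderPhantom(smallSpec(seed = 31, rbcCount = 0L))
  res0 <- quantifyBlood(channels(empty))
  expect_lte(bloodPercent(res0), 0.5)

  # ~10% true blood, noise off: recovered within 2 percentage points
  ph <- defaultPhantom(seed = 41)
  res <- quantifyBlood(channels(ph))
  expect_lte(abs(bloodPercent(res) - trueBloodPercent(ph)), 2)

  # areas are consistent
  expect_equal(res@bloodPercent,
               100 * res@bloodAreaPx / res@tissueAreaPx)
  expect_equal(res@bloodAreaUm2, res@bloodAreaPx * 0.32^2)
})

test_that("blood percentage increases with erythrocyte count", {
  a <- renderPhantom(smallSpec(seed = 51, rbcCount = 6L))
  b <- renderPhantom(smallSpec(seed = 51, rbcCount = 12L))
  expect_gt(trueBloodPercent(b), trueBloodPercent(a))
  expect_gt(bloodPercent(quantifyBlood(channels(b))),
            bloodPercent(quantifyBlood(channels(a))))
})

test_that("blood percentage is invariant to a common intensity scale", {
  ph <- renderPhantom(smallSpec(seed = 61))
  pair <- channels(ph)
  scaled <- ChannelPair(fitc(pair) * 37.5, tritc(pair) * 37.5,
                        pixelSize = pixelSize(pair))
  expect_equal(bloodPercent(quantifyBlood(scaled)),
               bloodPercent(quantifyBlood(pair)))
})

test_that("pipeline output is deterministic", {
  ph <- renderPhantom(smallSpec(seed = 71))
  r1 <- quantifyBlood(channels(ph))
  r2 <- quantifyBlood(channels(ph))
  expect_identical(bloodPercent(r1), bloodPercent(r2))
  expect_identical(r1@intermediates$corrected, r2@intermediates$corrected)
})

test_that("swapping the channels collapses the blood signal", {
  ph <- renderPhantom(smallSpec(seed = 81))
  pair <- channels(ph)
  fS <- normalizeChannel(tritc(pair))   # swapped roles
  tS <- normalizeChannel(fitc(pair))
  subSwap <- subtractFitc(meanImage(fS, tS), fS)
  # the subtracted image vanishes over the former blood pixels
  expect_lt(max(subSwap[bloodMask(ph)]), 1e-10)
})

test_that("unknown threshold methods are rejected", {
  ph <- renderPhantom(smallSpec(seed = 91, rbcCount = 2L))
  expect_error(quantifyBlood(channels(ph), thresholdMethod = "otsu"),
               "unknown threshold method")
})
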