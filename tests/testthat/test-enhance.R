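test_that("display normalization is a recorded, monotone affine clip", {
  ## already-scaled data with no clipping stays put
  p <- matrix(seq(0, 255, length.out = 64), 8, 8)
  out <- normalizeToDisplay(p, clipPercentiles = c(0, 100))
  expect_equal(out, p, tolerance = 1e-12, ignore_attr = TRUE)

  ## two-level image maps to the display endpoints
  p2 <- matrix(c(-1, 1), 4, 4)
  out2 <- normalizeToDisplay(p2, clipPercentiles = c(0, 100))
  expect_equal(sort(unique(as.vector(out2))), c(0, 255), ignore_attr = TRUE)

  ## percentile clipping saturates both tails of a ramp
  r <- matrix(seq(0, 1, length.out = 100), 10, 10)
  out3 <- normalizeToDisplay(r, clipPercentiles = c(10, 90))
  qs <- quantile(r, c(0.10, 0.90), names = FALSE)
  expect_true(all(out3[r <= qs[1L]] == 0))
  expect_true(all(out3[r >= qs[2L]] == 255))

  ## recorded transform inverts the map on the unclipped range
  expect_equal(attr(out3, "scale") * qs[1L] + attr(out3, "offset"), 0)
  ## constant images map to mid-scale
  expect_true(all(normalizeToDisplay(matrix(5, 4, 4)) == 127.5))
})

test_that("intensity reduction is plain repeated multiplication", {
  p <- matrix(200, 4, 4)
  expect_identical(reduceIntensity(p, factor = 1, times = 5), p)
  expect_equal(reduceIntensity(p, 0.5, 3), matrix(25, 4, 4))
  expect_equal(reduceIntensity(matrix(255, 3, 3), 2/3, 3),
               matrix(255 * (2/3)^3, 3, 3), tolerance = 1e-12)
})

test_that("decomposition layers satisfy their exact identities", {
  prm <- enhanceParams()
  ## constant input at the background constant: smooth layers are fixed
  ## points and the coarse layers vanish
  d <- decomposeImage(matrix(56, 10, 10), prm)
  expect_true(all(abs(d@L0 - 56) < 1e-8) && all(abs(d@L1 - 56) < 1e-8))
  expect_true(all(abs(d@diff1) < 1e-8))
  expect_true(all(abs(d@base) < 1e-8))

  ## identical sharp/common filters collapse diff1 exactly
  same <- enhanceParams(wlsSharp = wlsParams(lambda = 2),
                        wlsCommon = wlsParams(lambda = 2))
  set.seed(2)
  p <- matrix(runif(144, 0, 255), 12, 12)
  d2 <- decomposeImage(p, same)
  expect_equal(d2@diff1, matrix(0, 12, 12), tolerance = 1e-12)

  ## identities hold exactly on arbitrary input (validity enforces them)
  d3 <- decomposeImage(p, prm)
  expect_identical(d3@diff0, d3@L - d3@L0)
  expect_identical(d3@diff1, d3@L0 - d3@L1)
  expect_identical(d3@base, d3@L1 - d3@constantImg)
  expect_true(all(d3@constantImg == 56))

  ## the finest layer of a noisy image carries the high-variance content
  noisy <- matrix(128, 24, 24) + matrix(rnorm(576, 0, 40), 24, 24)
  d4 <- decomposeImage(noisy, prm)
  expect_gt(sd(d4@diff0), 0)
  expect_gt(sd(d4@diff0), sd(d4@base))
})

test_that("sigmoid boosting matches its closed form", {
  ## zero maps to zero exactly
  expect_identical(boostLayer(matrix(0, 3, 3))[1, 1], 0)

  ## odd function to 1e-12
  set.seed(4)
  x <- matrix(rnorm(100, 0, 80), 10, 10)
  expect_lt(max(abs(boostLayer(x) + boostLayer(-x))), 1e-12)

  ## direct evaluation at a normalized argument of 0.1 with a = 8
  hr <- 127.5
  out <- boostLayer(matrix(0.1 * hr, 2, 2), a = 8, halfRange = hr)
  expect_equal(out[1, 1], (1 / (1 + exp(-0.8)) - 0.5) * hr,
               tolerance = 1e-12)
  expect_equal(out[1, 1] / hr, 0.18997, tolerance = 1e-4)

  ## saturation bound, including extreme arguments
  big <- matrix(c(-1e6, -300, 0, 300, 1e6, 42), 2, 3)
  b <- boostLayer(big, a = 8, halfRange = hr, layerGain = 1.5)
  expect_true(all(abs(b) <= 1.5 * hr / 2 + 1e-12))
  expect_true(all(is.finite(b)))
})

test_that("enhancement is deterministic and raises the masked SNR", {
  ph <- testPhantom()
  cl <- projectVolume(ph, 0)
  msk <- maskFromReference(cl, 0.1, 2)

  ## constant in, constant out
  out <- enhanceImage(matrix(40, 8, 8))
  expect_equal(max(out) - min(out), 0)

  ns <- addNoiseForSnr(cl, msk, 0.30, seed = 21)
  e1 <- enhanceImage(ns)
  e2 <- enhanceImage(ns)
  expect_identical(pixels(e1), pixels(e2))

  expect_gt(snr(e1, msk), snr(ns, msk))
})

test_that("enhancement leaves the FRC against the clean reference intact", {
  ph <- testPhantom()
  cl <- projectVolume(ph, 0)
  msk <- maskFromReference(cl, 0.1, 2)
  ns <- addNoiseForSnr(cl, msk, 0.30, seed = 8)
  e <- enhanceImage(ns)
  cRaw <- frc(ns, cl)
  cEnh <- frc(e, cl)
  keep <- !is.na(corrValues(cRaw)) & !is.na(corrValues(cEnh))
  expect_lt(mean(abs(corrValues(cEnh)[keep] - corrValues(cRaw)[keep])), 0.1)
  rRaw <- resolutionAt(cRaw, 0.5, 1)
  rEnh <- resolutionAt(cEnh, 0.5, 1)
  expect_lt(abs(rEnh - rRaw) / rRaw, 0.10)
})

test_that("low-pass combination preprocessing keeps the stated order", {
  ph <- testPhantom()
  cl <- projectVolume(ph, 0)
  msk <- maskFromReference(cl, 0.1, 2)
  ns <- addNoiseForSnr(cl, msk, 0.25, seed = 3)

  ## no cutoff: identical to plain enhancement
  expect_identical(pixels(preprocessImage(ns)), pixels(enhanceImage(ns)))

  ## missing pixel size with a cutoff is an error
  bare <- grayImage(pixels(ns))
  expect_error(preprocessImage(bare, lowpassA = 8), "pixel size")

  ## near-Nyquist cutoff is a near-identity preprocessing (only the Fourier
  ## corners beyond the radial Nyquist are touched)
  atNy <- preprocessImage(ns, lowpassA = 2 * pixelSize(ns))
  plain <- enhanceImage(ns)
  expect_gt(cor(as.vector(pixels(atNy)), as.vector(pixels(plain))), 0.9)

  ## SNR ordering of the combination, as on super-noisy data
  sRaw <- snr(ns, msk)
  sLp <- snr(lowpass(ns, 8), msk)
  sBoth <- snr(preprocessImage(ns, lowpassA = 8), msk)
  expect_gt(sLp, sRaw)
  expect_gt(sBoth, sLp)
})
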