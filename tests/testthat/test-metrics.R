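test_that("masked SNR reproduces the defining arithmetic", {
  ## inside all 3; outside alternating 0/2: mean 1, population sd 1
  m <- matrix(FALSE, 4, 4); m[2:3, 2:3] <- TRUE
  a <- matrix(c(0, 2), 4, 4); a[m] <- 3
  expect_identical(snr(a, regionMask(m)), 2)

  ## equal means give zero
  b <- a; b[m] <- 1
  expect_identical(snr(b, regionMask(m)), 0)

  ## sign is preserved for reversed contrast
  d <- a; d[m] <- -1
  expect_lt(snr(d, regionMask(m)), 0)

  ## zero background variance is an error, as is a shape mismatch
  cst <- matrix(1, 4, 4); cst[m] <- 9
  expect_error(snr(cst, regionMask(m)), "background variance")
  expect_error(snr(matrix(1:9, 3, 3), regionMask(m)), "shape")
})

test_that("masked SNR is invariant under positive affine intensity maps", {
  set.seed(9)
  ph <- testPhantom()
  cl <- projectVolume(ph, 0)
  msk <- maskFromReference(cl, 0.1, 2)
  ns <- addNoiseForSnr(cl, msk, 0.5, seed = 2)
  s0 <- snr(ns, msk)
  for (i in 1:5) {
    a <- runif(1, 0.1, 10); b <- runif(1, -100, 100)
    expect_equal(snr(grayImage(pixels(ns) * a + b), msk), s0,
                 tolerance = 1e-10)
  }
})

test_that("reference masks match a brute-force voxel scan", {
  ## single centered blob: one region containing the maximum
  g <- outer(1:33, 1:33, function(i, j) exp(-((i - 17)^2 + (j - 17)^2) / 18))
  mk <- maskFromReference(g, 0.1, 0L)
  expect_true(maskArray(mk)[17, 17])
  expect_identical(maskArray(mk), bruteMask(g, 0.1, 0))

  ## dilation agrees with the explicit chebyshev-distance definition on a
  ## two-blob volume
  ref <- array(0, dim = c(14, 14, 14))
  g1 <- as.matrix(expand.grid(1:14, 1:14, 1:14))
  ref[] <- exp(-colSums((t(g1) - c(5, 5, 7))^2) / 6) +
    0.8 * exp(-colSums((t(g1) - c(10, 9, 8))^2) / 8)
  for (dil in c(1L, 2L)) {
    mk2 <- maskFromReference(ref, 0.05, dil)
    expect_identical(maskArray(mk2), bruteMask(ref, 0.05, dil))
  }

  ## threshold 1 keeps only the argmax set when not dilated
  mk3 <- maskFromReference(g, 1 - 1e-12, 0L)
  expect_identical(which(maskArray(mk3)), which(g == max(g)))
})

test_that("FRC matches trivial cases and the brute-force enumeration", {
  set.seed(6)
  x <- matrix(rnorm(64), 8, 8)
  cSelf <- frc(x, x)
  expect_true(all(abs(corrValues(cSelf) - 1) < 1e-12))
  cNeg <- frc(x, -x)
  expect_true(all(abs(corrValues(cNeg) + 1) < 1e-12))

  y <- matrix(rnorm(64), 8, 8)
  ours <- frc(x, y)
  oracle <- bruteCorrCurve(x, y)
  expect_equal(corrValues(ours), oracle$values, tolerance = 1e-10)
  expect_identical(binCounts(ours), as.integer(oracle$counts))
  expect_equal(binCenters(ours), oracle$binCenters, tolerance = 1e-12)

  ## symmetry in the two arguments
  expect_equal(corrValues(frc(y, x)), corrValues(ours), tolerance = 1e-12)
})

test_that("FSC matches the brute-force shell enumeration and noise bounds", {
  set.seed(13)
  v1 <- array(rnorm(216), dim = c(6, 6, 6))
  v2 <- array(rnorm(216), dim = c(6, 6, 6))
  expect_true(all(abs(corrValues(fsc(v1, v1)) - 1) < 1e-12))
  ours <- fsc(v1, v2)
  oracle <- bruteCorrCurve(v1, v2)
  expect_equal(corrValues(ours), oracle$values, tolerance = 1e-10)

  ## independent white-noise volumes decorrelate per shell
  set.seed(14)
  w1 <- array(rnorm(40^3), dim = c(40, 40, 40))
  w2 <- array(rnorm(40^3), dim = c(40, 40, 40))
  cc <- fsc(w1, w2)
  frac <- mean(abs(corrValues(cc)) <= 3 / sqrt(binCounts(cc)))
  expect_gte(frac, 0.99)
})

test_that("threshold-crossing resolution interpolates and flags Nyquist", {
  flat <- new("CorrelationCurve", binCenters = c(0.1, 0.2, 0.3, 0.4),
              values = rep(1, 4), counts = rep(10L, 4), pixelSize = 1)
  r <- resolutionAt(flat, 0.5)
  expect_equal(as.numeric(r), 2)
  expect_true(attr(r, "nyquistLimited"))

  two <- new("CorrelationCurve", binCenters = c(0.10, 0.20),
             values = c(0.8, 0.2), counts = c(4L, 8L), pixelSize = 1)
  r2 <- resolutionAt(two, 0.5)
  expect_equal(as.numeric(r2), 1 / 0.15, tolerance = 1e-12)
  expect_false(attr(r2, "nyquistLimited"))

  ## self-correlation never crosses: Nyquist-limited
  x <- matrix(rnorm(256), 16, 16)
  r3 <- resolutionAt(frc(x, x), 0.5, pixelSizeA = 1.5)
  expect_equal(as.numeric(r3), 3)
  expect_true(attr(r3, "nyquistLimited"))
})

test_that("the low-pass filter preserves DC and kills the stop band", {
  cst <- grayImage(matrix(3.7, 16, 16), pixelSize = 1)
  expect_equal(pixels(lowpass(cst, 8)), pixels(cst), tolerance = 1e-12)

  set.seed(15)
  p <- grayImage(matrix(rnorm(64^2), 64, 64), pixelSize = 1)
  expect_lt(abs(mean(pixels(lowpass(p, 8))) - mean(pixels(p))), 1e-10)

  ## sinusoid above the stop band (exact grid frequency 20/64 = 0.3125
  ## cycles/px, stop band ends at 1/8 + 5/64 ~ 0.203) is attenuated below 1%
  s <- grayImage(outer(1:64, 1:64,
                       function(i, j) sin(2 * pi * (20 / 64) * j)),
                 pixelSize = 1)
  expect_lt(max(abs(pixels(lowpass(s, 8)))), 0.01 * max(abs(pixels(s))))

  ## near-idempotence: repeated filtering only nibbles at the soft edge
  lp1 <- lowpass(p, 6); lp2 <- lowpass(lp1, 6)
  n2 <- function(m) sqrt(sum(m^2))
  expect_lt(n2(pixels(lp2) - pixels(lp1)), 0.25 * n2(pixels(p)))

  expect_error(lowpass(p, 1.5), "Nyquist")

  ## 3D volumes go through the same filter
  v <- testPhantom(boxPx = 32, nBlobs = 4)
  expect_lt(abs(mean(voxels(lowpass(v, 8))) - mean(voxels(v))), 1e-10)
})

test_that("noise injection hits its target SNR reproducibly", {
  ph <- makePhantom(20, boxPx = 160, seed = 1)
  cl <- projectVolume(ph, 0)
  msk <- maskFromReference(cl, 0.1, 2)
  m <- maskArray(msk)
  contrast <- mean(pixels(cl)[m]) - mean(pixels(cl)[!m])

  ## sigma -> 0 limit returns the clean image
  near <- addNoiseForSnr(cl, msk, 1e9, seed = 1)
  expect_lt(max(abs(pixels(near) - pixels(cl))), 1e-6 * contrast)

  ## determinism: same seed, bit-identical; different seed, different draw
  n1 <- addNoiseForSnr(cl, msk, 0.5, seed = 33)
  n2 <- addNoiseForSnr(cl, msk, 0.5, seed = 33)
  n3 <- addNoiseForSnr(cl, msk, 0.5, seed = 34)
  expect_identical(pixels(n1), pixels(n2))
  expect_false(identical(pixels(n1), pixels(n3)))

  ## sigma is contrast / target; background sd within 3%
  sdMeas <- sd(pixels(n1)[!m] - pixels(cl)[!m])
  expect_equal(sdMeas, contrast / 0.5, tolerance = 0.03)

  ## calibration: mean measured SNR over 20 seeds within 3% of target
  meas <- sapply(1:20, function(s)
    snr(addNoiseForSnr(cl, msk, 0.5, seed = s), msk))
  expect_equal(mean(meas), 0.5, tolerance = 0.03)

  ## nonpositive contrast is rejected
  expect_error(addNoiseForSnr(grayImage(-pixels(cl)), msk, 0.5, seed = 1),
               "contrast")
})
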