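test_that("atom gridding matches direct Gaussian summation", {
  ## single carbon at the box center: symmetric, max at center
  at <- data.frame(element = "C", x = 0, y = 0, z = 0, occupancy = 1,
                   bFactor = 0)
  v <- atomsToMap(at, boxPx = 21, voxelSizeA = 1, resolutionA = 4)
  vx <- voxels(v)
  expect_identical(which(vx == max(vx)), which(array(seq_along(vx),
                   dim(vx)) == ((11 - 1) * 21 + 11 - 1) * 21 + 11))
  expect_equal(vx[11, 11, 5], vx[11, 11, 17], tolerance = 1e-12)
  expect_equal(vx[3, 11, 11], vx[11, 3, 11], tolerance = 1e-12)

  ## additivity of two well-separated atoms
  at2 <- data.frame(element = c("C", "C"), x = c(-6, 6), y = 0, z = 0,
                    occupancy = 1, bFactor = 0)
  v2 <- atomsToMap(at2, boxPx = 33, voxelSizeA = 1, resolutionA = 3)
  expect_equal(sum(voxels(v2)), 2 * sum(voxels(
    atomsToMap(at, boxPx = 33, voxelSizeA = 1, resolutionA = 3))),
    tolerance = 1e-6)

  ## brute-force oracle on random atoms in a 32^3 box
  set.seed(31)
  n <- 5
  atoms <- data.frame(element = sample(c("C", "N", "O", "S"), n, TRUE),
                      x = runif(n, -6, 6), y = runif(n, -6, 6),
                      z = runif(n, -6, 6), occupancy = 1, bFactor = 0)
  res <- 4; vsz <- 1; box <- 32
  v3 <- atomsToMap(atoms, box, vsz, res)
  sigma <- res / (2 * sqrt(2 * log(2)))
  zs <- c(C = 6, N = 7, O = 8, S = 16)[atoms$element]
  ctr <- colMeans(atoms[, c("x", "y", "z")])
  pos <- sweep(as.matrix(atoms[, c("x", "y", "z")]), 2, ctr) + (box - 1) / 2
  brute <- array(0, dim = c(box, box, box))
  grid <- which(array(TRUE, dim(brute)), arr.ind = TRUE) - 1
  for (i in seq_len(n)) {
    dd <- sweep(grid, 2, pos[i, ])
    contrib <- zs[i] * exp(-rowSums(dd^2) / (2 * sigma^2))
    contrib[apply(abs(dd), 1, max) > 4 * sigma] <- 0
    brute <- brute + array(contrib, dim(brute))
  }
  expect_lt(max(abs(voxels(v3) - brute)), 1e-10)
})

test_that("the atom reader understands the PDB fixture", {
  pdb <- system.file("extdata", "synthetic-helix.pdb", package = "tomoBoost")
  at <- readPDBAtoms(pdb)
  expect_identical(nrow(at), 20L)
  expect_setequal(unique(at$element), c("N", "C", "O", "S"))
  atA <- readPDBAtoms(pdb, chains = "A")
  expect_identical(nrow(atA), 12L)
  v <- atomsToMap(at, boxPx = 24, voxelSizeA = 1, resolutionA = 4)
  expect_true(all(dim(voxels(v)) == 24) && max(voxels(v)) > 0)
})

test_that("blob phantoms are seeded, compact and integrable in closed form", {
  v1 <- makePhantom(6, boxPx = 48, seed = 5)
  v2 <- makePhantom(6, boxPx = 48, seed = 5)
  expect_identical(voxels(v1), voxels(v2))
  expect_false(identical(voxels(v1),
                         voxels(makePhantom(6, boxPx = 48, seed = 6))))
  expect_true(all(voxels(v1) >= 0))

  ## single blob, degenerate envelope: closed-form Gaussian integral
  s <- 3
  v3 <- makePhantom(1, boxPx = 64, blobSigmaRangeA = c(s, s),
                    envelopeRadiusFrac = 0, seed = 1)
  expect_equal(sum(voxels(v3)), (2 * pi)^(3/2) * s^3,
               tolerance = 1e-6)

  ## support bound: nothing beyond envelope + truncation reach
  v4 <- makePhantom(5, boxPx = 160, blobSigmaRangeA = c(2, 3),
                    envelopeRadiusFrac = 0.2, seed = 7)
  d <- dim(voxels(v4))
  ctr <- (d + 1) / 2
  g <- which(array(TRUE, d), arr.ind = TRUE)
  r <- sqrt(rowSums(sweep(g, 2, ctr)^2))
  reach <- 0.2 * 160 + 6 * 3 * sqrt(3) + 1
  expect_true(all(voxels(v4)[r > reach] == 0))
})

test_that("projection is exact at zero tilt and conserves mass", {
  v <- testPhantom(boxPx = 64, nBlobs = 8)
  pr0 <- projectVolume(v, 0)
  ref <- t(apply(voxels(v), c(1, 2), sum))
  expect_equal(pixels(pr0), ref, tolerance = 1e-12)
  expect_identical(pixelSize(pr0), voxelSize(v))

  for (ang in c(17, 30, -45, 90)) {
    pm <- sum(pixels(projectVolume(v, ang)))
    expect_equal(pm, sum(pixels(pr0)), tolerance = 0.01)
  }

  ## point mass at the exact center survives any rotation
  pt <- array(0, dim = c(33, 33, 33)); pt[17, 17, 17] <- 5
  for (ang in c(0, 28, 60))
    expect_equal(sum(pixels(projectVolume(densityVolume(pt), ang))), 5,
                 tolerance = 0.01)
})

test_that("Fourier shifting is exact, invertible and matches index rolls", {
  v <- testPhantom(boxPx = 32, nBlobs = 4)
  p <- pixels(projectVolume(v, 12))

  expect_equal(applyShift(p, 0, 0), p, tolerance = 1e-12)

  sh <- applyShift(applyShift(p, 3, -2), -3, 2)
  expect_lt(max(abs(sh - p)), 1e-6)

  ## integer shift of a delta equals the rolled delta
  dlt <- matrix(0, 16, 16); dlt[5, 7] <- 1
  out <- applyShift(dlt, 3, -2)
  rolled <- matrix(0, 16, 16); rolled[3, 10] <- 1
  expect_equal(out, rolled, tolerance = 1e-9)

  expect_error(applyShift(p, 20, 0), "quarter")
})

test_that("tilt-series simulation is reproducible and calibrated", {
  v <- testPhantom(boxPx = 48, nBlobs = 6)

  ## noiseless, centered: image k equals the plain projection exactly
  s0 <- simulateTiltSeries(v, -60, 60, 30, seed = 1)
  expect_identical(angles(s0), seq(-60, 60, 30))
  for (k in seq_len(nImages(s0)))
    expect_identical(pixels(getImage(s0, k)),
                     pixels(projectVolume(v, angles(s0)[k])))
  expect_true(all(appliedShifts(s0) == 0))

  ## seeded end to end
  sA <- simulateTiltSeries(v, -60, 60, 15, shiftRangePx = 5,
                           targetSnr = 0.5, seed = 9)
  sB <- simulateTiltSeries(v, -60, 60, 15, shiftRangePx = 5,
                           targetSnr = 0.5, seed = 9)
  expect_identical(sA@images, sB@images)
  expect_identical(appliedShifts(sA), appliedShifts(sB))
  expect_true(all(abs(appliedShifts(sA)) <= 5))

  ## per-image SNR calibration on full-size projections
  big <- makePhantom(20, boxPx = 160, seed = 1)
  s3 <- simulateTiltSeries(big, -60, 60, 40, targetSnr = 0.3, seed = 2)
  for (k in seq_len(nImages(s3))) {
    cl <- projectVolume(big, angles(s3)[k])
    msk <- maskFromReference(cl, 0.1, 2)
    expect_true(snr(getImage(s3, k), msk) > 0.25 &&
                snr(getImage(s3, k), msk) < 0.35)
  }
})
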