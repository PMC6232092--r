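## Synthetic ground truth: atom-to-density gridding, seeded blob phantoms,
## parallel-beam tilt projection, subpixel shifts, full tilt-series
## simulation.
##
## Tilt geometry convention (used by the whole package): rotation about the
## +y axis, right-handed, projection along +z, angles in degrees; volumes
## indexed (x, y, z), images (row = y, col = x).

elementZ <- c(H = 1, C = 6, N = 7, O = 8, `NA` = 11, MG = 12, P = 15, S = 16,
              CL = 17, K = 19, CA = 20, MN = 25, FE = 26, CU = 29, ZN = 30,
              SE = 34, MO = 42, I = 53)

#' Read atoms from a PDB file
#'
#' Parses ATOM/HETATM records with `bio3d` and returns the coordinate table
#' used by [atomsToMap()].
#'
#' @param path PDB file.
#' @param chains optional character vector of chain identifiers to keep
#'   (e.g. `c("A","B","C","D")`).
#' @return data.frame with columns element, x, y, z (Angstrom), occupancy,
#'   bFactor.
#' @export
readPDBAtoms <- function(path, chains = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at) < 1L) stop("readPDBAtoms: no atoms selected")
  el <- toupper(trimws(at$elesy))
  el[el == "" | is.na(el)] <- toupper(substr(trimws(at$elety[el == "" |
                                                               is.na(el)]),
                                             1L, 1L))
  data.frame(element = el, x = at$x, y = at$y, z = at$z,
             occupancy = ifelse(is.na(at$o), 1, at$o),
             bFactor = ifelse(is.na(at$b), 0, at$b))
}

## Add one isotropic Gaussian (separable, truncated per axis at truncSigma
## standard deviations) to a voxel array. Center in voxel units (1-based).
addGaussianBlob <- function(vox, center, sigmaPx, amp, truncSigma = 6) {
  d <- dim(vox)
  t <- truncSigma * sigmaPx
  lo <- pmax(1L, ceiling(center - t)); hi <- pmin(d, floor(center + t))
  if (any(lo > hi)) return(vox)
  w <- lapply(1:3, function(k) {
    i <- lo[k]:hi[k]
    exp(-((i - center[k])^2) / (2 * sigmaPx^2))
  })
  wxy <- amp * outer(w[[1L]], w[[2L]])
  for (j in seq_along(w[[3L]]))
    vox[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L] + j - 1L] <-
      vox[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L] + j - 1L] + wxy * w[[3L]][j]
  vox
}

#' Grid an atom list onto a density map
#'
#' Each atom contributes weight(element) times an isotropic 3D Gaussian
#' whose FWHM equals the requested resolution (sigma = resolution /
#' (2 sqrt(2 ln 2))), truncated per axis at 4 sigma. Atom weights are
#' atomic numbers; occupancy multiplies the weight. Atoms are re-centered
#' so their centroid sits at the box center; atoms still outside the box
#' are clipped with a warning.
#'
#' @param atoms data.frame as returned by [readPDBAtoms()].
#' @param boxPx box side in voxels.
#' @param voxelSizeA voxel size in Angstrom.
#' @param resolutionA target resolution in Angstrom
#'   (>= 2 * voxelSizeA).
#' @return A [DensityVolume-class], boxPx^3.
#' @export
atomsToMap <- function(atoms, boxPx, voxelSizeA = 1, resolutionA = 4) {
  stopifnot(nrow(atoms) >= 1L, resolutionA >= 2 * voxelSizeA)
  sigmaA <- resolutionA / (2 * sqrt(2 * log(2)))
  sigmaPx <- sigmaA / voxelSizeA
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  boxCtr <- (boxPx - 1) / 2                  # voxel units, 0-based center
  pos <- sweep(xyz, 2L, ctr) / voxelSizeA    # centered, voxel units
  pos <- sweep(pos, 2L, -boxCtr)             # 0-based voxel coords
  outside <- rowSums(pos < 0 | pos > boxPx - 1) > 0
  if (any(outside))
    warning(sprintf("atomsToMap: %d atoms outside the box were clipped",
                    sum(outside)))
  z <- elementZ[atoms$element]
  z[is.na(z)] <- 6                           # unknown elements gridded as C
  w <- z * atoms$occupancy
  vox <- array(0, dim = c(boxPx, boxPx, boxPx))
  for (i in seq_len(nrow(atoms)))
    vox <- addGaussianBlob(vox, pos[i, ] + 1, sigmaPx, w[i], truncSigma = 4)
  densityVolume(vox, voxelSize = voxelSizeA)
}

#' Seeded Gaussian-blob phantom
#'
#' A globular, protein-like test density: `nBlobs` unit-amplitude Gaussian
#' blobs with per-blob widths drawn from `blobSigmaRangeA`, centers uniform
#' in a sphere of radius `envelopeRadiusFrac * boxPx` voxels about the box
#' center. Blobs are truncated per axis at 6 sigma, so each blob's integral
#' matches the closed form (2 pi)^{3/2} sigma^3 to better than 1e-6 and the
#' density vanishes outside the envelope plus 6 sigma sqrt(3). Fully
#' reproducible from `seed`; nonnegative.
#'
#' @param nBlobs number of blobs (>= 1).
#' @param boxPx box side in voxels.
#' @param voxelSizeA voxel size in Angstrom.
#' @param blobSigmaRangeA range of blob sigma in Angstrom.
#' @param envelopeRadiusFrac envelope radius as a fraction of the box side.
#' @param seed integer seed.
#' @return A [DensityVolume-class], boxPx^3.
#' @export
makePhantom <- function(nBlobs = 20, boxPx = 160, voxelSizeA = 1,
                        blobSigmaRangeA = c(2.5, 6),
                        envelopeRadiusFrac = 0.3, seed = 1) {
  stopifnot(nBlobs >= 1)
  R <- envelopeRadiusFrac * boxPx            # voxel units
  boxCtr <- (boxPx - 1) / 2
  withr::with_seed(as.integer(seed), {
    centers <- matrix(0, nBlobs, 3)
    for (i in seq_len(nBlobs)) {
      if (R <= 0) { centers[i, ] <- c(0, 0, 0); next }
      repeat {
        p <- stats::runif(3, -R, R)
        if (sum(p^2) <= R^2) { centers[i, ] <- p; break }
      }
    }
    sigmas <- stats::runif(nBlobs, blobSigmaRangeA[1L], blobSigmaRangeA[2L]) /
      voxelSizeA
    ## recenter the mass-weighted blob centroid on the box center so the
    ## phantom's center of mass defines an unambiguous alignment origin
    w <- sigmas^3
    centers <- sweep(centers, 2L, colSums(centers * w) / sum(w))
    vox <- array(0, dim = c(boxPx, boxPx, boxPx))
    for (i in seq_len(nBlobs))
      vox <- addGaussianBlob(vox, centers[i, ] + boxCtr + 1, sigmas[i],
                             amp = 1, truncSigma = 6)
    densityVolume(vox, voxelSize = voxelSizeA)
  })
}

#' Parallel-beam projection of a volume
#'
#' Rotates the volume about the y (tilt) axis by `angleDeg` with bilinear
#' interpolation in the x-z plane and sums along z. At 0 degrees the result
#' equals the direct axis sum exactly.
#'
#' @param vol a [DensityVolume-class] with nx == nz.
#' @param angleDeg tilt angle in degrees.
#' @return A [GrayImage-class] (rows = y, cols = x); pixel size inherited
#'   from the voxel size.
#' @export
projectVolume <- function(vol, angleDeg) {
  d <- dim(vol@voxels)
  if (d[1L] != d[3L])
    stop("projectVolume: volume must have nx == nz for rotation about y")
  p <- cpp_project_y(as.vector(vol@voxels), d[1L], d[2L], d[3L],
                     as.numeric(angleDeg))
  grayImage(p, pixelSize = vol@voxelSize)
}

## n-dimensional Fourier phase-shift; shift[k] moves content by +shift[k]
## along dimension k (circular, subpixel exact for band-limited content).
fourierShiftArray <- function(a, shift) {
  d <- dim(a)
  F <- stats::fft(a)
  for (i in seq_along(d)) {
    k <- freqIndex(d[i])
    f1 <- exp(-2i * pi * k * shift[i] / d[i])
    ## even-length Nyquist bin: real cosine factor keeps the output real
    ## and makes integer shifts exact
    if (d[i] %% 2L == 0L) f1[d[i] / 2L + 1L] <- cos(pi * shift[i])
    F <- F * array(rep(f1, each = prod(d[seq_len(i - 1L)])), dim = d)
  }
  Re(stats::fft(F, inverse = TRUE)) / length(a)
}

#' Subpixel image translation
#'
#' Fourier phase-shift translation: moves the image content by (+dx, +dy)
#' pixels (x = columns, y = rows), circularly. Exact for band-limited
#' content; the inverse shift recovers the original to high precision.
#'
#' @param img a [GrayImage-class] or matrix.
#' @param dx,dy shift in pixels; must satisfy |dx|,|dy| < min(H, W)/4.
#' @return Same type as `img`.
#' @export
applyShift <- function(img, dx, dy) {
  p <- asPixelMatrix(img)
  if (max(abs(c(dx, dy))) >= min(dim(p)) / 4)
    stop("applyShift: shift must be below a quarter of the image size")
  out <- fourierShiftArray(p, c(dy, dx))
  if (is(img, "GrayImage")) grayImage(out, pixelSize = img@pixelSize) else out
}

#' Simulate a tilt series
#'
#' Projects the volume at every angle in `seq(angleMin, angleMax, step)`,
#' optionally translates each projection by a random subpixel shift drawn
#' uniformly from [-shiftRangePx, +shiftRangePx] per axis (recorded in the
#' returned series), and optionally adds white Gaussian noise calibrated
#' per image so the masked SNR of each projection equals `targetSnr`
#' (mask thresholded from the clean projection). Fully reproducible from
#' `seed`.
#'
#' @param vol ground-truth [DensityVolume-class].
#' @param angleMin,angleMax,step tilt range and increment in degrees.
#' @param shiftRangePx maximum shift per axis in pixels (0 = centered).
#' @param targetSnr target masked SNR per image, or `NULL` for noiseless.
#' @param seed integer seed.
#' @param maskThresholdFrac,maskDilatePx mask construction for the noise
#'   calibration (see [maskFromReference()]).
#' @return A [TiltSeries-class] with `appliedShifts` filled in.
#' @export
simulateTiltSeries <- function(vol, angleMin = -90, angleMax = 90, step = 1,
                               shiftRangePx = 0, targetSnr = NULL, seed = 1,
                               maskThresholdFrac = 0.1, maskDilatePx = 2L) {
  stopifnot(step > 0)
  angs <- seq(angleMin, angleMax, by = step)
  d <- dim(vol@voxels)
  clean <- array(0, dim = c(d[2L], d[1L], length(angs)))
  for (k in seq_along(angs))
    clean[, , k] <- cpp_project_y(as.vector(vol@voxels), d[1L], d[2L], d[3L],
                                  angs[k])
  withr::with_seed(as.integer(seed), {
    shifts <- matrix(stats::runif(2L * length(angs), -shiftRangePx,
                                  shiftRangePx),
                     ncol = 2L)
    if (shiftRangePx == 0) shifts[] <- 0
    imgs <- clean
    for (k in seq_along(angs)) {
      im <- clean[, , k]
      if (shiftRangePx > 0)
        im <- fourierShiftArray(im, c(shifts[k, 2L], shifts[k, 1L]))
      if (!is.null(targetSnr)) {
        m <- maskFromArray(clean[, , k], maskThresholdFrac, maskDilatePx)
        contrast <- mean(clean[, , k][m@mask]) - mean(clean[, , k][!m@mask])
        if (contrast <= 0)
          stop("simulateTiltSeries: nonpositive clean contrast")
        im <- im + matrix(stats::rnorm(length(im), 0, contrast / targetSnr),
                          nrow(im), ncol(im))
      }
      imgs[, , k] <- im
    }
    tiltSeries(imgs, angs, appliedShifts = shifts,
               pixelSize = vol@voxelSize, seed = as.integer(seed))
  })
}
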