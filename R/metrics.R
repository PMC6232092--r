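## Measurement harness: masked SNR, mask construction, FRC/FSC,
## threshold-crossing resolution, Fourier low-pass, calibrated noise.

popSd <- function(x) sqrt(mean((x - mean(x))^2))

snrFromArrays <- function(a, m) {
  if (!identical(dim(a), dim(m)))
    stop("snr: mask shape does not match data shape")
  inside <- a[m]; outside <- a[!m]
  nb <- popSd(outside)
  if (nb == 0) stop("snr: zero background variance, SNR undefined")
  (mean(inside) - mean(outside)) / nb
}

#' @describeIn snr masked SNR of a 2D image.
#' @export
setMethod("snr", signature("GrayImage", "RegionMask"), function(x, mask)
  snrFromArrays(x@pixels, mask@mask))

#' @describeIn snr masked SNR of a 3D volume.
#' @export
setMethod("snr", signature("DensityVolume", "RegionMask"), function(x, mask)
  snrFromArrays(x@voxels, mask@mask))

#' @describeIn snr masked SNR of a bare matrix or 3D array.
#' @export
setMethod("snr", signature("array", "RegionMask"), function(x, mask)
  snrFromArrays(x, mask@mask))

#' @describeIn snr matrix input.
#' @export
setMethod("snr", signature("matrix", "RegionMask"), function(x, mask)
  snrFromArrays(x, mask@mask))

## one binary dilation step over the full (8- or 26-connected) neighborhood
dilateOnce <- function(m) {
  d <- dim(m); nd <- length(d)
  out <- m
  offsets <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    if (all(off == 0)) next
    src <- dst <- vector("list", nd)
    ok <- TRUE
    for (k in seq_len(nd)) {
      i <- seq_len(d[k])
      srcIdx <- i - off[k]
      keep <- srcIdx >= 1L & srcIdx <= d[k]
      if (!any(keep)) { ok <- FALSE; break }
      src[[k]] <- srcIdx[keep]; dst[[k]] <- i[keep]
    }
    if (!ok) next
    shifted <- do.call(`[`, c(list(m), src, list(drop = FALSE)))
    idx <- do.call(`[`, c(list(array(seq_along(m), d)), dst,
                          list(drop = FALSE)))
    out[idx] <- out[idx] | shifted
  }
  out
}

maskFromArray <- function(a, thresholdFrac, dilatePx) {
  m <- a > thresholdFrac * max(a)
  if (!any(m)) stop("maskFromReference: empty mask")
  if (dilatePx > 0)
    for (i in seq_len(dilatePx)) m <- dilateOnce(m)
  if (sum(!m) < 2L)
    stop("maskFromReference: fewer than 2 background elements left")
  regionMask(m)
}

#' @describeIn maskFromReference mask from a clean 2D projection.
#' @export
setMethod("maskFromReference", "GrayImage",
  function(ref, thresholdFrac = 0.1, dilatePx = 2L)
    maskFromArray(ref@pixels, thresholdFrac, dilatePx))

#' @describeIn maskFromReference mask from a ground-truth volume.
#' @export
setMethod("maskFromReference", "DensityVolume",
  function(ref, thresholdFrac = 0.1, dilatePx = 2L)
    maskFromArray(ref@voxels, thresholdFrac, dilatePx))

#' @describeIn maskFromReference mask from a bare array.
#' @export
setMethod("maskFromReference", "array",
  function(ref, thresholdFrac = 0.1, dilatePx = 2L)
    maskFromArray(ref, thresholdFrac, dilatePx))

## Shared ring/shell correlation. a, b: equal-dimension arrays.
corrCurveFromArrays <- function(a, b, widthPx, pixelSize) {
  d <- dim(a)
  if (!identical(d, dim(b))) stop("correlation inputs must share one shape")
  F1 <- stats::fft(a); F2 <- stats::fft(b)
  ks <- lapply(d, freqIndex)
  r2 <- 0
  for (i in seq_along(d))
    r2 <- r2 + array(rep(ks[[i]]^2, each = prod(d[seq_len(i - 1L)])), dim = d)
  r <- sqrt(r2)
  bin <- as.integer(round(r / widthPx))
  n <- min(d)
  maxBin <- as.integer(floor((n / 2) / widthPx))
  keep <- bin >= 1L & bin <= maxBin
  binK <- bin[keep]
  num <- tapply(Re(F1[keep] * Conj(F2[keep])), binK, sum)
  p1 <- tapply(abs(F1[keep])^2, binK, sum)
  p2 <- tapply(abs(F2[keep])^2, binK, sum)
  cnt <- tapply(rep(1L, sum(keep)), binK, sum)
  bins <- as.integer(names(num))
  den <- sqrt(p1 * p2)
  vals <- ifelse(den > 0, num / den, NA_real_)
  new("CorrelationCurve",
      binCenters = bins * widthPx / n,
      values = as.numeric(vals), counts = as.integer(cnt),
      pixelSize = as.numeric(pixelSize))
}

padSquare <- function(p) {
  n <- max(dim(p))
  if (all(dim(p) == n)) return(p)
  out <- matrix(0, n, n)
  out[seq_len(nrow(p)), seq_len(ncol(p))] <- p
  out
}

#' Fourier ring correlation
#'
#' Per ring of spatial frequency, the normalized cross-correlation
#' Re(sum F1 conj(F2)) / sqrt(sum |F1|^2 sum |F2|^2) between the Fourier
#' transforms of two images. Rings are `ringWidthPx` Fourier pixels wide;
#' the DC term is excluded. Rings with zero power give `NA`.
#'
#' @param img1,img2 [GrayImage-class] objects or matrices of equal shape
#'   (padded to square with zeros if rectangular).
#' @param ringWidthPx ring width in Fourier pixels (default 1).
#' @return A [CorrelationCurve-class] with frequencies in cycles/pixel.
#' @export
frc <- function(img1, img2, ringWidthPx = 1) {
  p1 <- padSquare(asPixelMatrix(img1)); p2 <- padSquare(asPixelMatrix(img2))
  ps <- if (is(img1, "GrayImage")) img1@pixelSize else NA_real_
  corrCurveFromArrays(p1, p2, ringWidthPx, ps)
}

#' Fourier shell correlation
#'
#' 3D analogue of [frc()]: the normalized cross-correlation per spherical
#' shell of spatial frequency between two volumes.
#'
#' @param vol1,vol2 [DensityVolume-class] objects or 3D arrays, equal shape.
#' @param shellWidthPx shell width in Fourier pixels (default 1).
#' @return A [CorrelationCurve-class] with frequencies in cycles/pixel.
#' @export
fsc <- function(vol1, vol2, shellWidthPx = 1) {
  a <- if (is(vol1, "DensityVolume")) vol1@voxels else vol1
  b <- if (is(vol2, "DensityVolume")) vol2@voxels else vol2
  ps <- if (is(vol1, "DensityVolume")) vol1@voxelSize else NA_real_
  corrCurveFromArrays(a, b, shellWidthPx, ps)
}

#' Threshold-crossing resolution
#'
#' Returns the resolution in Angstrom at which the correlation curve first
#' decreases to `threshold`, linearly interpolated between adjacent bins.
#' If the curve never drops below the threshold the Nyquist resolution
#' (2 * pixel size) is returned with attribute `nyquistLimited = TRUE`.
#' `NA` bins (zero-power rings) are skipped.
#'
#' @param curve a [CorrelationCurve-class] with at least 2 bins.
#' @param threshold correlation threshold (default 0.5).
#' @param pixelSizeA Angstrom per pixel; defaults to the curve's own.
#' @return Resolution in Angstrom (attribute `nyquistLimited`).
#' @export
resolutionAt <- function(curve, threshold = 0.5, pixelSizeA = NULL) {
  if (is.null(pixelSizeA)) pixelSizeA <- curve@pixelSize
  if (is.na(pixelSizeA)) stop("resolutionAt: pixel size unknown")
  keep <- !is.na(curve@values)
  f <- curve@binCenters[keep]; v <- curve@values[keep]
  if (length(f) < 2L) stop("resolutionAt: need at least 2 usable bins")
  below <- which(v < threshold)
  if (!length(below)) {
    res <- 2 * pixelSizeA
    attr(res, "nyquistLimited") <- TRUE
    return(res)
  }
  i <- below[1L]
  if (i == 1L) {          # already below at the first bin: come down from DC
    f0 <- 0; v0 <- 1
  } else {
    f0 <- f[i - 1L]; v0 <- v[i - 1L]
  }
  fc <- f0 + (v0 - threshold) / (v0 - v[i]) * (f[i] - f0)
  res <- pixelSizeA / fc
  attr(res, "nyquistLimited") <- FALSE
  res
}

## Raised-cosine radial low-pass of an n-D array.
lowpassArray <- function(a, pixelSize, cutoffA, edgePx = 5) {
  if (is.na(pixelSize)) stop("lowpass: pixel size unknown")
  if (cutoffA < 2 * pixelSize)
    stop("lowpass: cutoff beyond Nyquist (needs cutoffA >= 2 * pixel size)")
  d <- dim(a)
  ks <- lapply(d, freqIndex)
  r2 <- 0
  for (i in seq_along(d))
    r2 <- r2 + array(rep((ks[[i]] / d[i])^2,
                         each = prod(d[seq_len(i - 1L)])), dim = d)
  rCyc <- sqrt(r2)                       # cycles/pixel
  fc <- pixelSize / cutoffA              # cutoff in cycles/pixel
  wEdge <- edgePx / max(d)               # soft edge width in cycles/pixel
  H <- ifelse(rCyc <= fc, 1,
              ifelse(rCyc >= fc + wEdge, 0,
                     0.5 * (1 + cos(pi * (rCyc - fc) / wEdge))))
  Re(stats::fft(stats::fft(a) * H, inverse = TRUE)) / length(a)
}

#' @describeIn lowpass low-pass filter a 2D image.
#' @export
setMethod("lowpass", "GrayImage", function(x, cutoffA)
  grayImage(lowpassArray(x@pixels, x@pixelSize, cutoffA),
            pixelSize = x@pixelSize))

#' @describeIn lowpass low-pass filter a 3D volume.
#' @export
setMethod("lowpass", "DensityVolume", function(x, cutoffA)
  densityVolume(lowpassArray(x@voxels, x@voxelSize, cutoffA),
                voxelSize = x@voxelSize, origin = x@origin))

#' Add Gaussian noise calibrated to a target masked SNR
#'
#' Adds i.i.d. zero-mean white Gaussian noise with standard deviation
#' sigma = (Is - Ib) / targetSnr, where Is and Ib are the clean image's
#' masked inside/outside means, so the expected measured SNR of the output
#' equals `targetSnr`. Seeded and reproducible; the caller's RNG state is
#' untouched.
#'
#' @param clean a noise-free [GrayImage-class] or matrix.
#' @param mask a [RegionMask-class] built from the clean image.
#' @param targetSnr desired masked SNR (> 0).
#' @param seed integer seed.
#' @return Same type as `clean`.
#' @export
addNoiseForSnr <- function(clean, mask, targetSnr, seed) {
  stopifnot(targetSnr > 0)
  p <- asPixelMatrix(clean)
  m <- mask@mask
  contrast <- mean(p[m]) - mean(p[!m])
  if (contrast <= 0)
    stop("addNoiseForSnr: clean contrast (Is - Ib) must be positive")
  sigma <- contrast / targetSnr
  noise <- withr::with_seed(as.integer(seed),
                            matrix(stats::rnorm(length(p), 0, sigma),
                                   nrow(p), ncol(p)))
  out <- p + noise
  if (is(clean, "GrayImage")) grayImage(out, pixelSize = clean@pixelSize)
  else out
}
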