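## Accessors and show methods. Slots are never reached into by user code.

#' @describeIn grayImage pixel matrix of an image.
#' @param x object.
#' @export
pixels <- function(x) x@pixels

#' @describeIn grayImage pixel size (Angstrom/px) of an image or series.
#' @export
pixelSize <- function(x) x@pixelSize

#' @describeIn densityVolume voxel array of a volume.
#' @param x object.
#' @export
voxels <- function(x) x@voxels

#' @describeIn densityVolume voxel size in Angstrom.
#' @export
voxelSize <- function(x) x@voxelSize

#' @describeIn tiltSeries tilt angles in degrees.
#' @param x a TiltSeries.
#' @export
angles <- function(x) x@angles

#' @describeIn tiltSeries number of images in the stack.
#' @export
nImages <- function(x) dim(x@images)[3L]

#' @describeIn tiltSeries matrix of known applied shifts (px), 0 rows if
#'   unknown.
#' @export
appliedShifts <- function(x) x@appliedShifts

#' @describeIn tiltSeries extract image `k` as a [GrayImage-class].
#' @param k image index.
#' @export
getImage <- function(x, k) grayImage(x@images[, , k], pixelSize = x@pixelSize)

#' @describeIn tiltSeries replace the image stack (same shape), returning a
#'   new series.
#' @param images new (height, width, n) array or list of matrices.
#' @export
setImages <- function(x, images) {
  if (is.list(images))
    images <- array(unlist(images), dim = dim(x@images))
  storage.mode(images) <- "double"
  initialize(x, images = images)
}

#' @describeIn regionMask logical mask array.
#' @param x a RegionMask.
#' @export
maskArray <- function(x) x@mask

#' @describeIn frc frequency bin centers (cycles/pixel).
#' @param x a CorrelationCurve.
#' @export
binCenters <- function(x) x@binCenters

#' @describeIn frc correlation values per bin.
#' @export
corrValues <- function(x) x@values

#' @describeIn frc Fourier term count per bin.
#' @export
binCounts <- function(x) x@counts

#' @describeIn iterativeAlign per-image alignment corrections (px).
#' @param x an AlignmentResult.
#' @export
alignmentShifts <- function(x) x@shifts

#' @describeIn iterativeAlign mean shift-update magnitude per iteration.
#' @export
alignmentResiduals <- function(x) x@residuals

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("GrayImage %d x %d (h x w), pixel %s A, range [%.4g, %.4g]\n",
              d[1L], d[2L],
              if (is.na(object@pixelSize)) "?" else format(object@pixelSize),
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "DensityVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("DensityVolume %d x %d x %d, voxel %g A, range [%.4g, %.4g]\n",
              d[1L], d[2L], d[3L], object@voxelSize,
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "TiltSeries", function(object) {
  d <- dim(object@images)
  cat(sprintf(
    "TiltSeries of %d images (%d x %d), angles %g..%g deg, pixel %s A%s\n",
    d[3L], d[1L], d[2L], min(object@angles), max(object@angles),
    if (is.na(object@pixelSize)) "?" else format(object@pixelSize),
    if (nrow(object@appliedShifts)) ", known shifts recorded" else ""))
})

setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf("CorrelationCurve: %d bins, %g..%g cycles/px\n",
              length(object@binCenters), min(object@binCenters),
              max(object@binCenters)))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf(
    "AlignmentResult: %d images, %d iterations, final residual %.3g px\n",
    nrow(object@shifts), object@nIter,
    if (length(object@residuals)) object@residuals[length(object@residuals)]
    else NA_real_))
})

setMethod("show", "WLSParams", function(object) {
  cat(sprintf("WLSParams: lambda=%g alpha=%g eps=%g logDomain=%s\n",
              object@lambda, object@alpha, object@eps, object@logDomain))
})

setMethod("show", "EnhanceParams", function(object) {
  cat(sprintf(
    "EnhanceParams: a=%g constant=%g reduction=%g^%d sharp lambda=%g common lambda=%g target=%s\n",
    object@a, object@constantValue, object@reductionFactor,
    object@reductionTimes, object@wlsSharp@lambda, object@wlsCommon@lambda,
    object@filterTarget))
})

## Internal helpers shared across modules.

asPixelMatrix <- function(img) {
  if (is(img, "GrayImage")) img@pixels else img
}

## signed wrapped frequency index k for dimension n: 0, 1, ..., -1 (in
## Fourier pixels, i.e. cycles * n)
freqIndex <- function(n) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k
}
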