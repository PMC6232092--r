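#' @import methods
#' @importFrom stats fft mvfft quantile rnorm sd convolve
NULL

## Central S4 containers. Images are float64 matrices indexed (row = y,
## col = x); volumes are float64 arrays indexed (x, y, z). Pixel/voxel
## sizes are in Angstrom per pixel and may be NA for dimensionless work.

#' GrayImage: a 2D grayscale image
#'
#' A 2D grid of float intensities (arbitrary units) with an optional pixel
#' size in Angstrom per pixel. The matrix is indexed (row = y, col = x).
#' All filters and metrics in the package operate on this unit.
#'
#' @slot pixels numeric matrix of finite intensities, at least 2 x 2.
#' @slot pixelSize Angstrom per pixel (positive) or `NA` when unknown.
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", pixelSize = "numeric"),
  prototype(pixelSize = NA_real_))

setValidity("GrayImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 2L || ncol(p) < 2L) return("image must be at least 2 x 2")
  if (!all(is.finite(p))) return("pixels must all be finite (no NA/NaN/Inf)")
  ps <- object@pixelSize
  if (length(ps) != 1L) return("pixelSize must be a single value")
  if (!is.na(ps) && !(is.finite(ps) && ps > 0))
    return("pixelSize must be positive or NA")
  TRUE
})

#' Construct a GrayImage
#'
#' @param pixels numeric matrix (row = y, col = x).
#' @param pixelSize Angstrom per pixel, or `NA`.
#' @return A [GrayImage-class] object (pixels stored as double).
#' @examples
#' img <- grayImage(matrix(runif(64), 8, 8), pixelSize = 1)
#' @export
grayImage <- function(pixels, pixelSize = NA_real_) {
  storage.mode(pixels) <- "double"
  new("GrayImage", pixels = pixels, pixelSize = as.numeric(pixelSize))
}

#' DensityVolume: a 3D density map
#'
#' A 3D grid of float densities with a voxel size in Angstrom. Ground truth
#' for simulation and the output of reconstruction. The array is indexed
#' (x, y, z); the tilt axis is y and projection is along z.
#'
#' @slot voxels numeric 3D array of finite densities.
#' @slot voxelSize Angstrom per voxel (positive).
#' @slot origin physical origin in Angstrom, length 3.
#' @export
setClass("DensityVolume",
  representation(voxels = "array", voxelSize = "numeric", origin = "numeric"),
  prototype(voxelSize = 1, origin = c(0, 0, 0)))

setValidity("DensityVolume", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("voxels must be a 3D array")
  if (!all(is.finite(v))) return("voxels must all be finite")
  if (!(length(object@voxelSize) == 1L && is.finite(object@voxelSize) &&
        object@voxelSize > 0))
    return("voxelSize must be a single positive number")
  if (length(object@origin) != 3L) return("origin must have length 3")
  TRUE
})

#' Construct a DensityVolume
#'
#' @param voxels numeric 3D array, indexed (x, y, z).
#' @param voxelSize Angstrom per voxel.
#' @param origin physical origin in Angstrom (length 3).
#' @return A [DensityVolume-class] object.
#' @export
densityVolume <- function(voxels, voxelSize = 1, origin = c(0, 0, 0)) {
  storage.mode(voxels) <- "double"
  new("DensityVolume", voxels = voxels, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' TiltSeries: an ordered stack of tilt images
#'
#' Projection images of one specimen over a strictly increasing list of tilt
#' angles (degrees, rotation about the y axis), with the per-image
#' translational shifts that were applied during simulation (if known).
#'
#' @slot images numeric 3D array (height, width, n) holding the stack.
#' @slot angles tilt angles in degrees, strictly increasing, one per image.
#' @slot appliedShifts n x 2 matrix of known applied (dx, dy) shifts in
#'   pixels, or a 0-row matrix when unknown.
#' @slot pixelSize Angstrom per pixel (positive) or `NA`.
#' @slot seed integer seed used to simulate the series, or `NA`.
#' @export
setClass("TiltSeries",
  representation(images = "array", angles = "numeric",
                 appliedShifts = "matrix", pixelSize = "numeric",
                 seed = "integer"),
  prototype(appliedShifts = matrix(numeric(0), 0, 2), pixelSize = NA_real_,
            seed = NA_integer_))

setValidity("TiltSeries", function(object) {
  d <- dim(object@images)
  if (length(d) != 3L) return("images must be a (height, width, n) array")
  n <- d[3L]
  if (length(object@angles) != n)
    return("length(angles) must equal the number of images")
  if (n > 1L && any(diff(object@angles) <= 0))
    return("angles must be strictly increasing")
  if (!all(is.finite(object@images))) return("images must be finite")
  s <- object@appliedShifts
  if (ncol(s) != 2L) return("appliedShifts must have 2 columns")
  if (nrow(s) != 0L && nrow(s) != n)
    return("appliedShifts must have one row per image (or none)")
  TRUE
})

#' Construct a TiltSeries
#'
#' @param images numeric 3D array (height, width, n), or a list of equally
#'   sized matrices / [GrayImage-class] objects.
#' @param angles tilt angles in degrees, strictly increasing.
#' @param appliedShifts optional n x 2 matrix of known (dx, dy) shifts (px).
#' @param pixelSize Angstrom per pixel, or `NA`.
#' @param seed integer simulation seed, or `NA`.
#' @return A [TiltSeries-class] object.
#' @export
tiltSeries <- function(images, angles, appliedShifts = NULL,
                       pixelSize = NA_real_, seed = NA_integer_) {
  if (is.list(images)) {
    mats <- lapply(images, function(x)
      if (is(x, "GrayImage")) x@pixels else x)
    images <- array(unlist(mats), dim = c(dim(mats[[1L]]), length(mats)))
  }
  storage.mode(images) <- "double"
  if (is.null(appliedShifts)) appliedShifts <- matrix(numeric(0), 0, 2)
  appliedShifts <- as.matrix(appliedShifts)
  new("TiltSeries", images = images, angles = as.numeric(angles),
      appliedShifts = appliedShifts, pixelSize = as.numeric(pixelSize),
      seed = as.integer(seed))
}

#' RegionMask: particle/background segmentation
#'
#' Logical 2D or 3D grid, `TRUE` inside the particle. The masked SNR
#' statistic needs at least one inside element and two outside elements
#' (a background standard deviation must exist).
#'
#' @slot mask logical array (2D or 3D).
#' @export
setClass("RegionMask", representation(mask = "array"))

setValidity("RegionMask", function(object) {
  m <- object@mask
  if (!is.logical(m)) return("mask must be logical")
  nd <- length(dim(m))
  if (!(nd %in% c(2L, 3L))) return("mask must be 2D or 3D")
  if (sum(m) < 1L) return("mask needs at least 1 inside element")
  if (sum(!m) < 2L) return("mask needs at least 2 outside elements")
  TRUE
})

#' Construct a RegionMask
#' @param mask logical matrix or 3D array, `TRUE` = inside the particle.
#' @return A [RegionMask-class] object.
#' @export
regionMask <- function(mask) {
  if (is.null(dim(mask))) stop("mask must have dimensions")
  new("RegionMask", mask = mask)
}

#' WLSParams: parameters of the WLS edge-preserving filter
#'
#' @slot lambda smoothness weight (>= 0); 0 returns the input unchanged.
#' @slot alpha gradient-sensitivity exponent, in (0, 4].
#' @slot eps regularizer added to the gradient magnitude (> 0).
#' @slot logDomain compute gradient weights on log intensity.
#' @slot logOffset value added before taking the log (> 0).
#' @export
setClass("WLSParams",
  representation(lambda = "numeric", alpha = "numeric", eps = "numeric",
                 logDomain = "logical", logOffset = "numeric"),
  prototype(lambda = 0.8, alpha = 1.2, eps = 1e-4, logDomain = TRUE,
            logOffset = 1))

setValidity("WLSParams", function(object) {
  if (!(object@lambda >= 0)) return("lambda must be >= 0")
  if (!(object@eps > 0)) return("eps must be > 0")
  if (!(object@alpha > 0 && object@alpha <= 4)) return("alpha must be in (0, 4]")
  if (!(object@logOffset > 0)) return("logOffset must be > 0")
  TRUE
})

#' Construct WLSParams
#'
#' @param lambda smoothness weight (>= 0).
#' @param alpha gradient-sensitivity exponent in (0, 4].
#' @param eps gradient-weight regularizer (> 0).
#' @param logDomain logical; compute gradient weights on log intensity.
#' @param logOffset offset added before the log (> 0).
#' @return A [WLSParams-class] object.
#' @export
wlsParams <- function(lambda = 0.8, alpha = 1.2, eps = 1e-4,
                      logDomain = TRUE, logOffset = 1) {
  new("WLSParams", lambda = as.numeric(lambda), alpha = as.numeric(alpha),
      eps = as.numeric(eps), logDomain = isTRUE(logDomain),
      logOffset = as.numeric(logOffset))
}

#' EnhanceParams: parameters of the multi-scale boosting pipeline
#'
#' @slot a sigmoid steepness of the boosting function (default 8).
#' @slot constantValue background constant on the display scale (default 56).
#' @slot reductionFactor per-step intensity reduction factor in (0, 1].
#' @slot reductionTimes number of reduction applications (default 3).
#' @slot wlsSharp [WLSParams-class] of the sharp-scale filter (small lambda).
#' @slot wlsCommon [WLSParams-class] of the common-scale filter (larger lambda).
#' @slot layerGain post-boost rescale applied to every boosted layer.
#' @slot displayLo,displayHi display scale bounds (default 0 and 255).
#' @slot clipPercentiles length-2 percentiles used to clip the input before
#'   mapping to the display scale.
#' @slot rescaleOutput affinely rescale the recombined output back to the
#'   display range.
#' @slot filterTarget which image the WLS filters decompose: "normalized"
#'   (the display-normalized input, the default) or "reduced" (the
#'   intensity-reduced image L).
#' @export
setClass("EnhanceParams",
  representation(a = "numeric", constantValue = "numeric",
                 reductionFactor = "numeric", reductionTimes = "integer",
                 wlsSharp = "WLSParams", wlsCommon = "WLSParams",
                 layerGain = "numeric", displayLo = "numeric",
                 displayHi = "numeric", clipPercentiles = "numeric",
                 rescaleOutput = "logical", filterTarget = "character"))

setValidity("EnhanceParams", function(object) {
  if (!(object@a > 0)) return("a must be > 0")
  if (!(object@reductionFactor > 0 && object@reductionFactor <= 1))
    return("reductionFactor must be in (0, 1]")
  if (object@reductionTimes < 0L) return("reductionTimes must be >= 0")
  if (!(object@displayHi > object@displayLo))
    return("displayHi must exceed displayLo")
  if (length(object@clipPercentiles) != 2L ||
      object@clipPercentiles[2L] <= object@clipPercentiles[1L])
    return("clipPercentiles must be (lo, hi) with hi > lo")
  if (!(object@layerGain > 0)) return("layerGain must be > 0")
  if (!(object@filterTarget %in% c("reduced", "normalized")))
    return('filterTarget must be "reduced" or "normalized"')
  TRUE
})

#' Construct EnhanceParams
#'
#' Defaults give the standard enhancement: sigmoid steepness a = 8, constant
#' background 56 on a 0--255 display scale, three intensity reductions by
#' 2/3, and sharp/common WLS scales.
#'
#' @param a sigmoid steepness.
#' @param constantValue background constant on the display scale.
#' @param reductionFactor per-step intensity reduction factor in (0, 1].
#' @param reductionTimes number of reduction applications.
#' @param wlsSharp,wlsCommon [WLSParams-class] for the two decomposition
#'   scales; sharp must smooth less than common.
#' @param layerGain post-boost rescale of every boosted layer.
#' @param displayLo,displayHi display range.
#' @param clipPercentiles input clipping percentiles (lo, hi).
#' @param rescaleOutput rescale the recombined image to the display range.
#' @param filterTarget "reduced" or "normalized"; see
#'   [EnhanceParams-class].
#' @return An [EnhanceParams-class] object.
#' @export
enhanceParams <- function(a = 8, constantValue = 56, reductionFactor = 2/3,
                          reductionTimes = 3L,
                          wlsSharp = wlsParams(lambda = 0.5),
                          wlsCommon = wlsParams(lambda = 128),
                          layerGain = 1, displayLo = 0, displayHi = 255,
                          clipPercentiles = c(0.1, 99.9),
                          rescaleOutput = TRUE, filterTarget = "normalized") {
  new("EnhanceParams", a = as.numeric(a),
      constantValue = as.numeric(constantValue),
      reductionFactor = as.numeric(reductionFactor),
      reductionTimes = as.integer(reductionTimes), wlsSharp = wlsSharp,
      wlsCommon = wlsCommon, layerGain = as.numeric(layerGain),
      displayLo = as.numeric(displayLo), displayHi = as.numeric(displayHi),
      clipPercentiles = as.numeric(clipPercentiles),
      rescaleOutput = isTRUE(rescaleOutput),
      filterTarget = as.character(filterTarget))
}

#' DecompositionLayers: the intermediate images of the decomposition
#'
#' Holds the seven intermediate images of the enhancement pipeline: the
#' intensity-reduced image L, the sharp-scale and common-scale WLS filtrates
#' L0 and L1, the constant background image, the two detail layers and the
#' base layer. The layer identities diff0 = L - L0, diff1 = L0 - L1 and
#' base = L1 - constant hold exactly.
#'
#' @slot L,L0,L1,constantImg,diff0,diff1,base numeric matrices, same shape.
#' @export
setClass("DecompositionLayers",
  representation(L = "matrix", L0 = "matrix", L1 = "matrix",
                 constantImg = "matrix", diff0 = "matrix", diff1 = "matrix",
                 base = "matrix"))

setValidity("DecompositionLayers", function(object) {
  d <- dim(object@L)
  for (nm in c("L0", "L1", "constantImg", "diff0", "diff1", "base"))
    if (!identical(dim(slot(object, nm)), d))
      return("all layers must share one shape")
  if (!identical(object@diff0, object@L - object@L0))
    return("diff0 must equal L - L0 exactly")
  if (!identical(object@diff1, object@L0 - object@L1))
    return("diff1 must equal L0 - L1 exactly")
  if (!identical(object@base, object@L1 - object@constantImg))
    return("base must equal L1 - constantImg exactly")
  cv <- object@constantImg
  if (max(cv) != min(cv)) return("constantImg must be spatially constant")
  TRUE
})

#' CorrelationCurve: an FRC or FSC curve
#'
#' Per-frequency-bin normalized cross-correlation between two images (rings)
#' or volumes (shells). Frequencies are stored in cycles/pixel; when the
#' pixel size is known, [resolutionAt()] converts the threshold crossing to
#' Angstrom. Bins whose rings carry zero power hold `NA`, never a silent 0.
#'
#' @slot binCenters spatial frequencies in cycles/pixel, strictly increasing.
#' @slot values correlation per bin, in [-1, 1] (or `NA`).
#' @slot counts number of Fourier terms per bin.
#' @slot pixelSize Angstrom per pixel or `NA`.
#' @export
setClass("CorrelationCurve",
  representation(binCenters = "numeric", values = "numeric",
                 counts = "integer", pixelSize = "numeric"),
  prototype(pixelSize = NA_real_))

setValidity("CorrelationCurve", function(object) {
  n <- length(object@binCenters)
  if (length(object@values) != n || length(object@counts) != n)
    return("binCenters, values and counts must have equal length")
  if (n > 1L && any(diff(object@binCenters) <= 0))
    return("binCenters must be strictly increasing")
  v <- object@values[!is.na(object@values)]
  if (length(v) && any(abs(v) > 1 + 1e-9))
    return("correlation values must lie in [-1, 1]")
  if (any(object@counts < 1L)) return("counts must be >= 1")
  TRUE
})

#' AlignmentResult: trajectory of the iterative alignment
#'
#' @slot shifts n x 2 matrix of the per-image (dx, dy) corrections (px) that
#'   were applied to align the series; for a simulated series these approach
#'   the negated applied shifts.
#' @slot residuals mean shift-update magnitude (px) per iteration.
#' @slot nIter number of iterations performed.
#' @slot lowpassSchedule low-pass cutoff (Angstrom) used at each iteration.
#' @export
setClass("AlignmentResult",
  representation(shifts = "matrix", residuals = "numeric", nIter = "integer",
                 lowpassSchedule = "numeric"))

setValidity("AlignmentResult", function(object) {
  if (ncol(object@shifts) != 2L) return("shifts must have 2 columns")
  if (object@nIter < 1L) return("nIter must be >= 1")
  TRUE
})
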