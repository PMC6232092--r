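## The enhancement pipeline: display normalization, intensity reduction,
## three-way WLS decomposition against a constant background, sigmoid
## boosting of each layer, recombination.

#' Map an image onto the display scale
#'
#' Percentile-clips the intensities and affinely maps them to
#' [displayLo, displayHi]. The map is monotone, and the affine coefficients
#' are recorded in attributes `scale` and `offset` of the returned pixel
#' matrix so it can be inverted (out = scale * clipped + offset). A constant
#' image maps to mid-scale.
#'
#' @param img a [GrayImage-class] or numeric matrix.
#' @param clipPercentiles length-2 percentiles (lo, hi) in [0, 100].
#' @param displayLo,displayHi target range (default 0--255).
#' @return Same type as `img`, values in [displayLo, displayHi].
#' @export
normalizeToDisplay <- function(img, clipPercentiles = c(0.1, 99.9),
                               displayLo = 0, displayHi = 255) {
  p <- asPixelMatrix(img)
  q <- stats::quantile(p, probs = clipPercentiles / 100, names = FALSE)
  if (q[2L] <= q[1L]) {              # constant (or clipped-to-constant) image
    out <- matrix((displayLo + displayHi) / 2, nrow(p), ncol(p))
    sc <- 0; off <- (displayLo + displayHi) / 2
  } else {
    sc <- (displayHi - displayLo) / (q[2L] - q[1L])
    off <- displayLo - sc * q[1L]
    out <- pmin(pmax(p, q[1L]), q[2L]) * sc + off
  }
  attr(out, "scale") <- sc
  attr(out, "offset") <- off
  if (is(img, "GrayImage")) grayImage(out, pixelSize = img@pixelSize) else out
}

#' Reduce image intensity
#'
#' Multiplies the image by `factor`, `times` times (out = img * factor^times),
#' the "reduce the intensity" step that produces the standard image L.
#'
#' @param img a [GrayImage-class] or numeric matrix on the display scale.
#' @param factor per-step reduction factor in (0, 1].
#' @param times number of applications (>= 0).
#' @return Same type as `img`.
#' @export
reduceIntensity <- function(img, factor = 2/3, times = 3L) {
  stopifnot(factor > 0, factor <= 1, times >= 0)
  p <- asPixelMatrix(img) * factor^times
  if (is(img, "GrayImage")) grayImage(p, pixelSize = img@pixelSize) else p
}

#' Three-way multi-scale decomposition
#'
#' Decomposes a display-scale image into the reduced image L, a sharp-scale
#' WLS filtrate L0, a common-scale WLS filtrate L1 and a constant background
#' image, then forms the detail layers diff0 = L - L0, diff1 = L0 - L1 and
#' the base layer base = L1 - constant. L0 retains more detail than L1
#' (sharp lambda << common lambda, so L1 is close to the smooth background
#' and the particle contrast lives in diff1). With `filterTarget =
#' "normalized"` (default) the WLS filters act on the display-normalized
#' input, so diff0 = L - L0 carries the intensity-reduction offset that
#' drives the finest-scale noise into the saturated part of the boosting
#' sigmoid; with `"reduced"` they act on L itself.
#'
#' @param img a [GrayImage-class] or matrix already on the display scale.
#' @param params an [EnhanceParams-class].
#' @return A [DecompositionLayers-class].
#' @export
decomposeImage <- function(img, params = enhanceParams()) {
  p <- asPixelMatrix(img)
  L <- asPixelMatrix(reduceIntensity(p, params@reductionFactor,
                                     params@reductionTimes))
  tgt <- if (params@filterTarget == "reduced") L else p
  L0 <- wlsSmooth(tgt, params@wlsSharp)
  L1 <- wlsSmooth(tgt, params@wlsCommon)
  cst <- matrix(params@constantValue, nrow(p), ncol(p))
  new("DecompositionLayers", L = L, L0 = L0, L1 = L1, constantImg = cst,
      diff0 = L - L0, diff1 = L0 - L1, base = L1 - cst)
}

#' Sigmoid layer boosting
#'
#' Applies the boosting function y = 1/(1 + exp(-a x)) - 0.5 to a layer
#' normalized by `halfRange`, then rescales back:
#' out = layerGain * halfRange * (1/(1 + exp(-a layer/halfRange)) - 0.5).
#' The function is odd and saturates at +/- layerGain * halfRange / 2, so
#' small-amplitude detail is amplified (slope a/4 at zero) while large
#' excursions are compressed.
#'
#' @param layer a [GrayImage-class] or numeric matrix.
#' @param a sigmoid steepness (default 8).
#' @param halfRange normalization scale; default half the 0--255 display
#'   range.
#' @param layerGain post-boost rescale (> 0).
#' @return Same type as `layer`.
#' @export
boostLayer <- function(layer, a = 8, halfRange = 127.5, layerGain = 1) {
  stopifnot(halfRange > 0, a > 0, layerGain > 0)
  p <- asPixelMatrix(layer)
  out <- layerGain * halfRange * (stats::plogis(a * p / halfRange) - 0.5)
  if (is(layer, "GrayImage")) grayImage(out, pixelSize = layer@pixelSize)
  else out
}

#' Enhance an image
#'
#' The full pipeline: normalize the raw image to the display scale,
#' decompose it ([decomposeImage()]), boost the two detail layers and the
#' base layer ([boostLayer()]), recombine with the constant background
#' (out = boost(diff0) + boost(diff1) + boost(base) + constant), and
#' optionally rescale the result back to the display range. Deterministic:
#' identical inputs give bit-identical outputs.
#'
#' @param img a [GrayImage-class] or numeric matrix (any intensity scale).
#' @param params an [EnhanceParams-class].
#' @return Same type as `img`, same shape.
#' @export
enhanceImage <- function(img, params = enhanceParams()) {
  p <- asPixelMatrix(img)
  norm <- normalizeToDisplay(p, params@clipPercentiles, params@displayLo,
                             params@displayHi)
  d <- decomposeImage(norm, params)
  hr <- (params@displayHi - params@displayLo) / 2
  out <- boostLayer(d@diff0, params@a, hr, params@layerGain) +
         boostLayer(d@diff1, params@a, hr, params@layerGain) +
         boostLayer(d@base, params@a, hr, params@layerGain) +
         params@constantValue
  if (params@rescaleOutput) {
    rg <- range(out)
    ## guard against blowing up solver-level ripple on (near-)constant output
    if (rg[2L] - rg[1L] > 1e-6 * (abs(rg[1L]) + abs(rg[2L]) + 1))
      out <- (out - rg[1L]) / (rg[2L] - rg[1L]) *
             (params@displayHi - params@displayLo) + params@displayLo
  }
  if (is(img, "GrayImage")) grayImage(out, pixelSize = img@pixelSize) else out
}

#' Low-pass then enhance
#'
#' Combination preprocessing for very noisy data: a Fourier low-pass filter
#' (typically at 8 Angstrom) is applied first, then the enhancement. The
#' order is fixed.
#'
#' @param img a [GrayImage-class]; must carry a pixel size when `lowpassA`
#'   is given.
#' @param lowpassA low-pass cutoff in Angstrom, or `NULL` for no filtering.
#' @param params an [EnhanceParams-class].
#' @return A [GrayImage-class].
#' @export
preprocessImage <- function(img, lowpassA = NULL, params = enhanceParams()) {
  if (!is.null(lowpassA)) {
    if (!is(img, "GrayImage") || is.na(img@pixelSize))
      stop("preprocessImage: pixel size must be known for low-pass filtering")
    img <- lowpass(img, lowpassA)
  }
  enhanceImage(img, params)
}
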