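#' Masked signal-to-noise ratio
#'
#' SNR = (Is - Ib) / Nb, where Is is the mean intensity inside the particle,
#' Ib the mean intensity outside, and Nb the population standard deviation
#' of the background (outside) intensities. The sign is preserved, so a
#' contrast-reversed particle gives a negative SNR.
#'
#' @param x a [GrayImage-class] or [DensityVolume-class].
#' @param mask a [RegionMask-class] matching the shape of `x`.
#' @return A single numeric SNR value.
#' @export
setGeneric("snr", function(x, mask) standardGeneric("snr"))

#' Fourier low-pass filter
#'
#' Radial Fourier mask at 1/cutoffA with a raised-cosine soft edge of width
#' 5 Fourier pixels. The mean (DC term) is preserved exactly.
#'
#' @param x a [GrayImage-class] or [DensityVolume-class] with a known
#'   pixel/voxel size.
#' @param cutoffA cutoff in Angstrom; must be at least twice the pixel size
#'   (Nyquist).
#' @return An object of the same class as `x`.
#' @export
setGeneric("lowpass", function(x, cutoffA) standardGeneric("lowpass"))

#' Particle mask from a noise-free reference
#'
#' Thresholds a clean reference at a fraction of its maximum and dilates the
#' result, producing the inside/outside segmentation used by the masked SNR.
#'
#' @param ref a noise-free [GrayImage-class] or [DensityVolume-class].
#' @param thresholdFrac fraction of the reference maximum (inside =
#'   ref > thresholdFrac * max).
#' @param dilatePx number of one-pixel binary dilations (full 8/26-connected
#'   neighborhood).
#' @return A [RegionMask-class].
#' @export
setGeneric("maskFromReference",
           function(ref, thresholdFrac = 0.1, dilatePx = 2L)
             standardGeneric("maskFromReference"))
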