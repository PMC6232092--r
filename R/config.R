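## Run configuration: every tunable of the pipeline in one JSON-serializable
## list that round-trips losslessly through its on-disk form. All seeds are
## explicit.

wlsParamsToList <- function(p) list(
  lambda = p@lambda, alpha = p@alpha, eps = p@eps,
  logDomain = p@logDomain, logOffset = p@logOffset)

wlsParamsFromList <- function(l) wlsParams(
  lambda = l$lambda, alpha = l$alpha, eps = l$eps,
  logDomain = l$logDomain, logOffset = l$logOffset)

#' Convert EnhanceParams to/from a plain list
#'
#' @param p an [EnhanceParams-class].
#' @return `enhanceParamsToList`: a named list; `enhanceParamsFromList`:
#'   an [EnhanceParams-class].
#' @export
enhanceParamsToList <- function(p) list(
  a = p@a, constantValue = p@constantValue,
  reductionFactor = p@reductionFactor,
  reductionTimes = p@reductionTimes,
  wlsSharp = wlsParamsToList(p@wlsSharp),
  wlsCommon = wlsParamsToList(p@wlsCommon),
  layerGain = p@layerGain, displayLo = p@displayLo, displayHi = p@displayHi,
  clipPercentiles = p@clipPercentiles, rescaleOutput = p@rescaleOutput,
  filterTarget = p@filterTarget)

#' @rdname enhanceParamsToList
#' @param l a named list as produced by `enhanceParamsToList`.
#' @export
enhanceParamsFromList <- function(l) enhanceParams(
  a = l$a, constantValue = l$constantValue,
  reductionFactor = l$reductionFactor, reductionTimes = l$reductionTimes,
  wlsSharp = wlsParamsFromList(l$wlsSharp),
  wlsCommon = wlsParamsFromList(l$wlsCommon),
  layerGain = l$layerGain, displayLo = l$displayLo, displayHi = l$displayHi,
  clipPercentiles = unlist(l$clipPercentiles),
  rescaleOutput = l$rescaleOutput, filterTarget = l$filterTarget)

#' Default run configuration
#'
#' The full configuration of a simulation + enhancement + reconstruction
#' run: enhancement parameters, simulation block (box, voxel size, tilt
#' range, shift range, target SNRs, seed), metrics block (mask threshold
#' and dilation, ring width, FSC criterion) and reconstruction block
#' (iterations, low-pass schedule).
#'
#' @param outputDir directory where a run writes its products.
#' @return A nested named list.
#' @export
runConfig <- function(outputDir = ".") {
  list(
    enhance = enhanceParamsToList(enhanceParams()),
    simulation = list(
      boxPx = 160L, voxelSizeA = 1, nBlobs = 20L,
      blobSigmaRangeA = c(2.5, 6), envelopeRadiusFrac = 0.3,
      angleMin = -90, angleMax = 90, angleStep = 1,
      shiftRangePx = 30, targetSnrs = c(0.8, 0.5, 0.3), seed = 1L),
    metrics = list(
      maskThresholdFrac2D = 0.1, maskThresholdFrac3D = 0.05,
      maskDilatePx = 2L, ringWidthPx = 1, fscCriterion = 0.5),
    reconstruction = list(
      nIter = 4L, lowpassScheduleA = c(30, 20, 12, 8)),
    outputDir = outputDir)
}

#' Write / read a run configuration as JSON
#'
#' The on-disk JSON form round-trips losslessly (numbers written at full
#' precision).
#'
#' @param config nested list as produced by [runConfig()].
#' @param path JSON file.
#' @return `writeRunConfig`: `path` invisibly; `readRunConfig`: the list.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (blk in c("simulation", "metrics", "reconstruction"))
    for (nm in names(cfg[[blk]]))
      if (nm %in% c("boxPx", "nBlobs", "seed", "maskDilatePx", "nIter"))
        cfg[[blk]][[nm]] <- as.integer(cfg[[blk]][[nm]])
  cfg$enhance$reductionTimes <- as.integer(cfg$enhance$reductionTimes)
  cfg
}
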