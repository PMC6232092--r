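## 3D reconstruction: r-weighted back-projection about the y tilt axis and
## iterative projection-matching translational alignment, plus odd/even
## FSC resolution estimation.

## ramp (|f|) filter applied along x (columns) of one image
rampFilterImage <- function(p) {
  W <- ncol(p)
  f <- abs(freqIndex(W)) / W
  tp <- t(p)                                 # columns of tp are rows of p
  ft <- stats::mvfft(tp) * f
  t(Re(stats::mvfft(ft, inverse = TRUE)) / W)
}

#' Weighted back-projection
#'
#' r-weighted (ramp-filtered) real-space back-projection about the y tilt
#' axis: each image is filtered by |f| along x, smeared back through the
#' volume along its viewing direction, and the sum is scaled by the angular
#' increment. Deterministic and linear in the input series.
#'
#' @param series a [TiltSeries-class] of square, equally sized images with
#'   at least 3 members.
#' @return A [DensityVolume-class] cube whose side equals the image side.
#' @export
backProject <- function(series) {
  d <- dim(series@images)
  if (d[3L] < 3L) stop("backProject: need at least 3 images")
  if (d[1L] != d[2L]) stop("backProject: images must be square")
  filt <- series@images
  for (k in seq_len(d[3L])) filt[, , k] <- rampFilterImage(filt[, , k])
  v <- cpp_backproject_y(as.vector(filt), d[1L], d[2L], d[3L],
                         series@angles, d[2L])
  dTheta <- mean(diff(series@angles)) * pi / 180
  vox <- array(v * dTheta, dim = c(d[2L], d[1L], d[2L]))
  ps <- if (is.na(series@pixelSize)) 1 else series@pixelSize
  densityVolume(vox, voxelSize = ps)
}

## cross-correlation displacement of image a relative to image b, with
## 3-point parabolic subpixel interpolation per axis, search limited to
## |shift| <= maxShift
ccShift <- function(a, b, maxShift) {
  d <- dim(a)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  wrap <- function(i, n) ((i + n) %% n) + 1L       # displacement -> index
  sh <- -maxShift:maxShift
  win <- cc[wrap(sh, d[1L]), wrap(sh, d[2L])]
  pk <- which(win == max(win), arr.ind = TRUE)
  if (nrow(pk) > 1L) {                              # tie: smallest shift
    mag <- sh[pk[, 1L]]^2 + sh[pk[, 2L]]^2
    pk <- pk[which.min(mag), , drop = FALSE]
  }
  dy <- sh[pk[1L, 1L]]; dx <- sh[pk[1L, 2L]]
  para <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (m1 - p1) / den))
  }
  sy <- para(cc[wrap(dy - 1L, d[1L]), wrap(dx, d[2L])],
             cc[wrap(dy, d[1L]), wrap(dx, d[2L])],
             cc[wrap(dy + 1L, d[1L]), wrap(dx, d[2L])])
  sx <- para(cc[wrap(dy, d[1L]), wrap(dx - 1L, d[2L])],
             cc[wrap(dy, d[1L]), wrap(dx, d[2L])],
             cc[wrap(dy, d[1L]), wrap(dx + 1L, d[2L])])
  c(dx = dx + sx, dy = dy + sy)
}

## center of mass (voxel units, 1-based) of the positive part of a volume
volumeCoM <- function(v) {
  w <- pmax(v, 0)
  s <- sum(w)
  if (s <= 0) return((dim(v) + 1) / 2)
  d <- dim(v)
  g <- function(k) sum(w * array(rep(seq_len(d[k]),
                                     each = prod(d[seq_len(k - 1L)])),
                                 dim = d)) / s
  c(g(1L), g(2L), g(3L))
}

#' Iterative projection-matching alignment
#'
#' IPET-style translational refinement of a tilt series to a common center.
#' Per iteration: back-project the currently aligned series, re-project the
#' volume at each tilt angle, cross-correlate each (low-pass filtered)
#' measured image against its re-projection, and update the per-image
#' translation with subpixel (3-point parabolic) precision. Each image is
#' matched against the reconstruction computed without itself (leave-one-out
#' reprojection, done by subtracting the image's own back-projection from
#' the full linear sum), which removes the reference bias that would
#' otherwise let a noisy image lock onto its own back-projected noise. The
#' low-pass cutoff tightens over iterations following `lowpassScheduleA`. When
#' `enhParams` is given, every measured image is contrast-enhanced (after an
#' optional `preLowpassA` filter) once before the refinement, matching the
#' use of the enhancement as a preprocessing step. The reconstruction is
#' recentered on its center of mass each iteration so the recovered shifts
#' are absolute. If the mean shift update grows for 3 consecutive
#' iterations the refinement stops and reports divergence.
#'
#' @param series a [TiltSeries-class].
#' @param nIter number of refinement iterations (>= 1).
#' @param lowpassScheduleA per-iteration low-pass cutoffs in Angstrom
#'   (recycled at its last value), or `NULL` for no filtering.
#' @param enhParams optional [EnhanceParams-class] applied per image before
#'   alignment.
#' @param preLowpassA optional low-pass (Angstrom) applied before the
#'   enhancement (the combination preprocessing).
#' @param maxShiftPx cross-correlation search radius; default a quarter of
#'   the image side minus one.
#' @param initCenter start from a per-image center-of-mass pre-centering
#'   (computed on the low-pass filtered image above its upper-quartile
#'   level, refined by a windowed mean-shift) instead of zero shifts; a
#'   strong initializer for compact particles.
#' @param relax under-relaxation factor applied to shift updates after the
#'   second iteration, damping cross-correlation jitter on noisy data.
#' @return list with `series` (the aligned [TiltSeries-class]),
#'   `result` (an [AlignmentResult-class]; `alignmentShifts()` gives the
#'   applied corrections, approximately the negated true shifts) and
#'   `volume` (the final [DensityVolume-class]).
#' @export
iterativeAlign <- function(series, nIter = 6L,
                           lowpassScheduleA = c(30, 20, 12, 8),
                           enhParams = NULL, preLowpassA = NULL,
                           maxShiftPx = NULL, initCenter = TRUE,
                           relax = 0.7) {
  stopifnot(nIter >= 1L)
  d <- dim(series@images)
  n <- d[3L]
  ps <- series@pixelSize
  if (!is.null(lowpassScheduleA) && is.na(ps))
    stop("iterativeAlign: pixel size needed for the low-pass schedule")
  if (is.null(maxShiftPx))
    maxShiftPx <- as.integer(min(d[1L], d[2L]) / 4) - 1L

  meas <- series@images
  if (!is.null(enhParams))
    for (k in seq_len(n))
      meas[, , k] <- pixels(preprocessImage(getImage(series, k),
                                            lowpassA = preLowpassA,
                                            params = enhParams))
  work <- initialize(series, images = meas)

  lpMat <- function(p, cutoff) {
    if (is.null(cutoff)) p else lowpassArray(p, ps, cutoff)
  }
  corr <- matrix(0, n, 2L)
  if (initCenter) {
    cut0 <- if (is.null(lowpassScheduleA)) NULL else lowpassScheduleA[1L]
    winR <- min(d[1L], d[2L]) / 3
    for (k in seq_len(n)) {
      lp <- if (is.null(cut0)) meas[, , k]
        else lowpassArray(meas[, , k], ps, cut0)
      w0 <- pmax(lp - stats::quantile(lp, 0.75), 0)
      if (sum(w0) <= 0) next
      cy <- sum(w0 * row(w0)) / sum(w0)
      cx <- sum(w0 * col(w0)) / sum(w0)
      ## mean-shift: re-estimate inside a window so far-field noise cannot
      ## bias the centroid
      for (pass in 1:4) {
        w <- w0 * ((row(w0) - cy)^2 + (col(w0) - cx)^2 <= winR^2)
        if (sum(w) <= 0) break
        cy <- sum(w * row(w0)) / sum(w)
        cx <- sum(w * col(w0)) / sum(w)
      }
      corr[k, ] <- c((d[2L] + 1) / 2 - cx, (d[1L] + 1) / 2 - cy)
    }
    corr <- pmin(pmax(corr, -maxShiftPx), maxShiftPx)
  }
  residuals <- numeric(0)
  grown <- 0L
  for (it in seq_len(nIter)) {
    cutoff <- if (is.null(lowpassScheduleA)) NULL
      else lowpassScheduleA[min(it, length(lowpassScheduleA))]
    alig <- meas
    for (k in seq_len(n))
      if (any(corr[k, ] != 0))
        alig[, , k] <- fourierShiftArray(meas[, , k],
                                         c(corr[k, 2L], corr[k, 1L]))
    filt <- alig
    for (k in seq_len(n)) filt[, , k] <- rampFilterImage(filt[, , k])
    dTheta <- mean(diff(series@angles)) * pi / 180
    vFull <- array(cpp_backproject_y(as.vector(filt), d[1L], d[2L], n,
                                     series@angles, d[2L]) * dTheta,
                   dim = c(d[2L], d[1L], d[2L]))
    com <- volumeCoM(vFull)
    ctr <- (dim(vFull) + 1) / 2
    gauge <- ctr - com                      # recentering, applied per image
    ## deadband: the CoM anchor is only accurate to ~0.2 px, so do not chase
    ## offsets below that
    if (sqrt(sum(gauge^2)) <= 0.2) gauge <- c(0, 0, 0)
    th <- series@angles * pi / 180
    upd <- matrix(0, n, 2L)
    for (k in seq_len(n)) {
      vK <- array(cpp_backproject_y(as.vector(filt[, , k]), d[1L], d[2L], 1L,
                                    series@angles[k], d[2L]) * dTheta,
                  dim = c(d[2L], d[1L], d[2L]))
      vLoo <- vFull - vK
      reproj <- cpp_project_y(as.vector(vLoo), dim(vLoo)[1L], dim(vLoo)[2L],
                              dim(vLoo)[3L], series@angles[k])
      dshift <- ccShift(lpMat(alig[, , k], cutoff), lpMat(reproj, cutoff),
                        maxShiftPx)
      ## fold the volume recentering into the expected reprojection position
      g <- c(cos(th[k]) * gauge[1L] - sin(th[k]) * gauge[3L], gauge[2L])
      upd[k, ] <- dshift - g
    }
    if (it > 2L) upd <- upd * relax
    corr <- corr - upd
    res <- mean(sqrt(rowSums(upd^2)))
    grown <- if (length(residuals) && res > residuals[length(residuals)])
      grown + 1L else 0L
    residuals <- c(residuals, res)
    if (grown >= 3L) {
      warning(sprintf(
        "iterativeAlign: residual grew 3 consecutive iterations (%.3g px), stopping",
        res))
      break
    }
  }
  aligFinal <- meas
  for (k in seq_len(n))
    if (any(corr[k, ] != 0))
      aligFinal[, , k] <- fourierShiftArray(meas[, , k],
                                            c(corr[k, 2L], corr[k, 1L]))
  aligned <- initialize(work, images = aligFinal)
  list(series = aligned,
       result = new("AlignmentResult", shifts = corr, residuals = residuals,
                    nIter = length(residuals),
                    lowpassSchedule = if (is.null(lowpassScheduleA))
                      numeric(0) else as.numeric(lowpassScheduleA)),
       volume = backProject(aligned))
}

#' Odd/even split resolution
#'
#' Splits the (aligned) series by image-index parity, back-projects each
#' half, and returns the FSC 0.5 threshold-crossing resolution between the
#' two half reconstructions.
#'
#' @param series an aligned [TiltSeries-class] with at least 6 images.
#' @param pixelSizeA Angstrom per pixel; defaults to the series' own.
#' @return Resolution in Angstrom (attribute `nyquistLimited`), from
#'   [resolutionAt()].
#' @export
oddEvenResolution <- function(series, pixelSizeA = NULL) {
  n <- nImages(series)
  if (n < 6L) stop("oddEvenResolution: need at least 6 images")
  if (is.null(pixelSizeA)) pixelSizeA <- series@pixelSize
  odd <- seq(1L, n, by = 2L); even <- seq(2L, n, by = 2L)
  sub <- function(i) tiltSeries(series@images[, , i, drop = FALSE],
                                series@angles[i],
                                pixelSize = series@pixelSize)
  curve <- fsc(backProject(sub(odd)), backProject(sub(even)))
  resolutionAt(curve, threshold = 0.5, pixelSizeA = pixelSizeA)
}
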