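## Independent oracles, kept deliberately naive: dense linear algebra for the
## WLS system, per-pixel enumeration for ring/shell correlation and mask
## construction, direct Gaussian summation for the atom gridder.

## Dense assembly of (Id + lambda A) and direct solve, with explicit loops
## over grid edges; shares nothing with the sparse path but the definition.
denseWLSOracle <- function(p, lambda, alpha, eps, logDomain, logOffset) {
  H <- nrow(p); W <- ncol(p); n <- H * W
  l <- if (logDomain) log(p + logOffset) else p
  id <- function(i, j) (j - 1) * H + i
  A <- matrix(0, n, n)
  for (i in seq_len(H)) for (j in seq_len(W - 1)) {
    w <- 1 / (abs(l[i, j + 1] - l[i, j])^alpha + eps)
    a <- id(i, j); b <- id(i, j + 1)
    A[a, a] <- A[a, a] + w; A[b, b] <- A[b, b] + w
    A[a, b] <- A[a, b] - w; A[b, a] <- A[b, a] - w
  }
  for (i in seq_len(H - 1)) for (j in seq_len(W)) {
    w <- 1 / (abs(l[i + 1, j] - l[i, j])^alpha + eps)
    a <- id(i, j); b <- id(i + 1, j)
    A[a, a] <- A[a, a] + w; A[b, b] <- A[b, b] + w
    A[a, b] <- A[a, b] - w; A[b, a] <- A[b, a] - w
  }
  matrix(solve(diag(n) + lambda * A, as.vector(p)), H, W)
}

## Ring/shell correlation by explicit enumeration of every Fourier pixel.
bruteCorrCurve <- function(a, b, widthPx = 1) {
  d <- dim(a)
  F1 <- fft(a); F2 <- fft(b)
  n <- min(d)
  maxBin <- floor((n / 2) / widthPx)
  num <- p1 <- p2 <- numeric(maxBin)
  cnt <- integer(maxBin)
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    ks <- numeric(length(d))
    for (k in seq_along(d)) {
      kk <- idx[r, k] - 1
      if (kk > d[k] / 2) kk <- kk - d[k]
      ks[k] <- kk
    }
    bin <- round(sqrt(sum(ks^2)) / widthPx)
    if (bin < 1 || bin > maxBin) next
    z1 <- F1[r]; z2 <- F2[r]
    num[bin] <- num[bin] + Re(z1 * Conj(z2))
    p1[bin] <- p1[bin] + abs(z1)^2
    p2[bin] <- p2[bin] + abs(z2)^2
    cnt[bin] <- cnt[bin] + 1L
  }
  list(values = ifelse(sqrt(p1 * p2) > 0, num / sqrt(p1 * p2), NA_real_),
       counts = cnt, binCenters = seq_len(maxBin) * widthPx / n)
}

## threshold + chebyshev dilation by explicit voxel scan
bruteMask <- function(ref, thresholdFrac, dilatePx) {
  inside <- ref > thresholdFrac * max(ref)
  if (dilatePx == 0) return(inside)
  d <- dim(ref)
  idx <- which(inside, arr.ind = TRUE)
  out <- array(FALSE, d)
  all <- which(array(TRUE, d), arr.ind = TRUE)
  for (r in seq_len(nrow(all))) {
    cheb <- min(apply(abs(sweep(idx, 2, all[r, ])), 1, max))
    out[r] <- cheb <= dilatePx
  }
  out
}

## separable Gaussian blur matched later to a variance-reduction level
gaussBlur <- function(p, sigma) {
  r <- ceiling(4 * sigma)
  k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
  pad <- function(m, n) m[pmin(pmax(seq_len(nrow(m) + 2 * n) - n, 1),
                               nrow(m)), , drop = FALSE]
  conv1 <- function(m) {
    mp <- pad(m, r)
    out <- m
    for (i in seq_len(nrow(m)))
      out[i, ] <- colSums(mp[i:(i + 2 * r), , drop = FALSE] * k)
    out
  }
  t(conv1(t(conv1(p))))
}

## 10-90% rise distance of the horizontal edge profile of an image holding a
## vertical step
riseDistance <- function(p) {
  prof <- colMeans(p)
  prof <- (prof - min(prof)) / (max(prof) - min(prof))
  x10 <- which(prof >= 0.1)[1L]
  x90 <- which(prof >= 0.9)[1L]
  x90 - x10
}

## small compact phantom + clean 0-degree projection shared by several tests
testPhantom <- function(boxPx = 96, nBlobs = 12, seed = 11)
  makePhantom(nBlobs, boxPx = boxPx, blobSigmaRangeA = c(2, 4),
              envelopeRadiusFrac = 0.22, seed = seed)
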