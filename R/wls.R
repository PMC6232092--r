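## Weighted-least-squares edge-preserving smoothing.
##
## The filter returns u minimizing
##   sum (u - g)^2 + lambda * sum [ wx (du/dx)^2 + wy (du/dy)^2 ]
## with per-edge weights w = (|grad l|^alpha + eps)^-1 computed once from the
## (log-)intensity of the input, so the operator is linear and the system
## (Id + lambda A) u = g is sparse, symmetric positive definite. Forward
## differences, Neumann (replicate) boundaries.

#' Gradient-dependent smoothing weights
#'
#' Computes the per-edge weights w = (|grad l|^alpha + eps)^-1 used by
#' [wlsSmooth()], where l is the image intensity (optionally log
#' transformed). Forward differences; the last column of `wx` and last row
#' of `wy` are defined by replication (Neumann boundary). Larger gradients
#' give strictly smaller weights.
#'
#' @param img a [GrayImage-class] or numeric matrix.
#' @param alpha gradient-sensitivity exponent in (0, 4].
#' @param eps regularizer (> 0) bounding the weights by 1/eps.
#' @param logDomain compute gradients on log(img + logOffset).
#' @param logOffset offset added before the log (> 0).
#' @return list with matrices `wx` (horizontal edges) and `wy` (vertical
#'   edges), both strictly positive, full image size.
#' @examples
#' w <- edgeWeights(matrix(0, 4, 4), alpha = 1, eps = 1e-4)
#' stopifnot(all(w$wx == 1e4))
#' @export
edgeWeights <- function(img, alpha = 1.2, eps = 1e-4, logDomain = TRUE,
                        logOffset = 1) {
  p <- asPixelMatrix(img)
  if (!all(is.finite(p))) stop("edgeWeights: non-finite pixels in input")
  stopifnot(alpha > 0, alpha <= 4, eps > 0)
  l <- if (logDomain) {
    if (min(p) + logOffset <= 0)
      stop("edgeWeights: img + logOffset must be positive for logDomain")
    log(p + logOffset)
  } else p
  H <- nrow(l); W <- ncol(l)
  dx <- l[, -1L, drop = FALSE] - l[, -W, drop = FALSE]   # H x (W-1)
  dy <- l[-1L, , drop = FALSE] - l[-H, , drop = FALSE]   # (H-1) x W
  wx <- 1 / (abs(dx)^alpha + eps)
  wy <- 1 / (abs(dy)^alpha + eps)
  wx <- cbind(wx, wx[, W - 1L])                          # replicate last col
  wy <- rbind(wy, wy[H - 1L, ])                          # replicate last row
  list(wx = wx, wy = wy)
}

#' WLS edge-preserving smoothing
#'
#' Solves (Id + lambda A) u = g with A = Dx' Wx Dx + Dy' Wy Dy (forward
#' differences, Neumann boundaries) by a sparse Cholesky factorization.
#' Weights are computed once from the input, so the smoothing operator is
#' linear. A annihilates constants: the mean is preserved and constant
#' images are fixed points for any lambda; lambda = 0 returns the input
#' bit-for-bit.
#'
#' @param img a [GrayImage-class] or numeric matrix.
#' @param params a [WLSParams-class].
#' @return Same type as `img`, same shape.
#' @examples
#' p <- matrix(rnorm(64), 8, 8)
#' s <- wlsSmooth(p, wlsParams(lambda = 1, logDomain = FALSE))
#' stopifnot(abs(mean(s) - mean(p)) < 1e-8)
#' @export
wlsSmooth <- function(img, params = wlsParams()) {
  p <- asPixelMatrix(img)
  if (!all(is.finite(p))) stop("wlsSmooth: non-finite pixels in input")
  lam <- params@lambda
  if (lam == 0) return(img)
  u <- solveWLSSystem(p, lam,
                      edgeWeights(p, params@alpha, params@eps,
                                  params@logDomain, params@logOffset))
  if (is(img, "GrayImage")) grayImage(u, pixelSize = img@pixelSize) else u
}

## Assemble and solve (Id + lam A) u = g for one weight set.
solveWLSSystem <- function(p, lam, w) {
  H <- nrow(p); W <- ncol(p); n <- H * W
  idx <- matrix(seq_len(n), H, W)    # column-major grid indexing

  ## horizontal edges (i,j)-(i,j+1), weight wx[i,j], j < W
  pe <- as.vector(idx[, -W, drop = FALSE])
  qe <- as.vector(idx[, -1L, drop = FALSE])
  we <- as.vector(w$wx[, -W, drop = FALSE])
  ## vertical edges (i,j)-(i+1,j), weight wy[i,j], i < H
  pe <- c(pe, as.vector(idx[-H, , drop = FALSE]))
  qe <- c(qe, as.vector(idx[-1L, , drop = FALSE]))
  we <- c(we, as.vector(w$wy[-H, , drop = FALSE]))

  ## graph Laplacian A from the weighted edge list
  A <- Matrix::sparseMatrix(
    i = c(pe, qe, pe, qe), j = c(pe, qe, qe, pe),
    x = c(we, we, -we, -we), dims = c(n, n))
  M <- Matrix::Diagonal(n) + lam * A
  M <- methods::as(Matrix::forceSymmetric(M), "CsparseMatrix")
  g <- as.vector(p)
  u <- as.vector(Matrix::solve(M, g))
  rel <- sqrt(sum((as.vector(M %*% u) - g)^2)) / max(sqrt(sum(g^2)), 1e-300)
  if (!is.finite(rel) || rel > 1e-8)
    stop(sprintf("wlsSmooth: solver residual %.3g exceeds tolerance", rel))
  matrix(u, H, W)
}
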