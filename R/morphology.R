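# Grayscale and binary morphology helpers. Structuring elements and
# binary opening go through EBImage; Gaussian smoothing is a separable
# banded-matrix convolution with boundary-renormalized (replicate-like)
# edges, which conserves total intensity for interior structures.

# One-dimensional Gaussian band matrix of size n, rows renormalized so
# each output pixel averages only in-image weights.
gauss_band <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  B <- matrix(0, n, n)
  for (d in -r:r) {
    idx <- seq_len(n)
    j <- idx + d
    ok <- j >= 1L & j <= n
    B[cbind(idx[ok], j[ok])] <- B[cbind(idx[ok], j[ok])] + k[d + r + 1L]
  }
  B / rowSums(B)
}

#' Gaussian smoothing of an intensity matrix
#'
#' Separable Gaussian filter with kernel truncated at 4 sigma.
#' `boundary = "renorm"` renormalizes the truncated kernel at the image
#' edge (flat backgrounds stay flat); `boundary = "reflect"` mirrors the
#' image (Neumann condition), which conserves total intensity — the
#' right choice for diffusion propagation.
#'
#' @param m Numeric matrix.
#' @param sigma Standard deviation in pixels; `0` returns `m` unchanged.
#' @param boundary `"renorm"` (default) or `"reflect"`.
#' @return Smoothed matrix of the same shape.
#' @export
gaussian_smooth <- function(m, sigma, boundary = c("renorm", "reflect")) {
  stopifnot(is.matrix(m), is.numeric(sigma), sigma >= 0)
  boundary <- match.arg(boundary)
  if (sigma == 0) return(m)
  if (boundary == "reflect") {
    r <- max(1L, as.integer(ceiling(4 * sigma)))
    ry <- min(r, nrow(m) - 1L); rx <- min(r, ncol(m) - 1L)
    pad <- rbind(m[ry:1, , drop = FALSE], m,
                 m[nrow(m):(nrow(m) - ry + 1L), , drop = FALSE])
    pad <- cbind(pad[, rx:1, drop = FALSE], pad,
                 pad[, ncol(pad):(ncol(pad) - rx + 1L), drop = FALSE])
    out <- gauss_band(nrow(pad), sigma) %*% pad %*%
      t(gauss_band(ncol(pad), sigma))
    return(out[(ry + 1L):(ry + nrow(m)), (rx + 1L):(rx + ncol(m)),
               drop = FALSE])
  }
  By <- gauss_band(nrow(m), sigma)
  Bx <- gauss_band(ncol(m), sigma)
  By %*% m %*% t(Bx)
}

# Disc structuring element of integer radius r (odd side 2r + 1).
disc_brush <- function(r) {
  EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
}

# Binary opening with a disc of radius r; returns a logical matrix.
binary_opening <- function(mask, r) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  matrix(EBImage::opening(m, disc_brush(r)) > 0.5, nrow(m), ncol(m))
}

# Binary dilation with a disc of radius r; returns a logical matrix.
binary_dilation <- function(mask, r) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  matrix(EBImage::dilate(m, disc_brush(r)) > 0.5, nrow(m), ncol(m))
}
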