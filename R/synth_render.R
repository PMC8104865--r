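# Forward model for synthetic ER frames: edges drawn as 1-px Bresenham
# lines, optional bright cisterna discs, Gaussian PSF blur, and
# Poisson-Gaussian (shot + read) noise. The model is a deliberately
# simple stand-in for real ER micrographs; its purpose is ground-truthed
# testing of the segmentation and tracking stages.

# Integer Bresenham line between rounded endpoints; returns cbind(x, y),
# 0-based.
bresenham <- function(x0, y0, x1, y1) {
  x0 <- as.integer(round(x0)); y0 <- as.integer(round(y0))
  x1 <- as.integer(round(x1)); y1 <- as.integer(round(y1))
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  xs <- integer(0L); ys <- integer(0L)
  repeat {
    xs <- c(xs, x0); ys <- c(ys, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  cbind(x = xs, y = ys)
}

# Draw value v at 0-based (x, y) into matrix m (clipped), keeping the
# per-pixel maximum.
draw_pixels <- function(m, xy, v) {
  h <- nrow(m); w <- ncol(m)
  ok <- xy[, 1L] >= 0L & xy[, 1L] <= w - 1L & xy[, 2L] >= 0L & xy[, 2L] <= h - 1L
  idx <- cbind(xy[ok, 2L] + 1L, xy[ok, 1L] + 1L)
  m[idx] <- pmax(m[idx], v)
  m
}

disc_pixels <- function(cx, cy, r) {
  xr <- seq.int(floor(cx - r), ceiling(cx + r))
  yr <- seq.int(floor(cy - r), ceiling(cy + r))
  g <- expand.grid(x = xr, y = yr)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  cbind(x = as.integer(g$x[keep]), y = as.integer(g$y[keep]))
}

# Draw the network geometry (and discs) at given node positions into an
# intensity canvas. `positions` defaults to the network's own nodes.
draw_network <- function(net, positions = NULL, tubule_intensity, background,
                         cisterna_spec = NULL) {
  h <- net$height_px; w <- net$width_px
  m <- matrix(background, h, w)
  pos <- positions %||% net$node_positions
  if (nrow(net$edges) > 0L) {
    for (e in seq_len(nrow(net$edges))) {
      p <- pos[net$edges[e, 1L], ]
      q <- pos[net$edges[e, 2L], ]
      m <- draw_pixels(m, bresenham(p[1L], p[2L], q[1L], q[2L]),
                       tubule_intensity)
    }
  }
  if (!is.null(cisterna_spec) && nrow(cisterna_spec) > 0L) {
    ints <- cisterna_spec$intensity %||% rep(tubule_intensity, nrow(cisterna_spec))
    for (k in seq_len(nrow(cisterna_spec))) {
      m <- draw_pixels(m, disc_pixels(cisterna_spec$x[k], cisterna_spec$y[k],
                                      cisterna_spec$radius_px[k]), ints[k])
    }
  }
  m
}

# Poisson shot noise plus additive Gaussian read noise.
add_poisson_gauss <- function(m, read_noise_sd) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(rpois(h * w, lambda = as.vector(m)), h, w) +
    matrix(rnorm(h * w, sd = read_noise_sd), h, w)
  pmax(out, 0)
}

#' Render a synthetic network into a fluorescence frame
#'
#' Edges are drawn as 1-px lines at `tubule_intensity` over `background`,
#' optional cisterna discs added, the image convolved with a Gaussian
#' PSF, and noise applied.
#'
#' @param net A [generate_network()] result.
#' @param psf_sigma_px Gaussian PSF standard deviation in pixels (>= 0).
#' @param tubule_intensity Line intensity (counts); must exceed
#'   `background`.
#' @param cisterna_spec Optional data frame with columns `x`, `y`,
#'   `radius_px` and optionally `intensity` describing bright cisternal
#'   patches.
#' @param background Background level (counts, >= 0).
#' @param noise `"none"` or `"poisson_gauss"` (shot noise plus Gaussian
#'   read noise of SD `read_noise_sd`).
#' @param read_noise_sd Read-noise standard deviation (counts).
#' @param seed Integer seed for the noise draw.
#' @return An [image_frame()].
#' @export
render_network <- function(net, psf_sigma_px = 1.2, tubule_intensity = 100,
                           cisterna_spec = NULL, background = 5,
                           noise = c("none", "poisson_gauss"),
                           read_noise_sd = 2, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(psf_sigma_px >= 0, background >= 0)
  if (tubule_intensity <= background) {
    stop("`tubule_intensity` must exceed `background`", call. = FALSE)
  }
  if (nrow(net$edges) == 0L &&
      (is.null(cisterna_spec) || nrow(cisterna_spec) == 0L)) {
    warning("empty network and no cisternae: emitting background-only frame")
  }
  m <- draw_network(net, NULL, tubule_intensity, background, cisterna_spec)
  m <- gaussian_smooth(m, psf_sigma_px)
  if (noise == "poisson_gauss") {
    set.seed(child_seed(seed, "render_noise"))
    m <- add_poisson_gauss(m, read_noise_sd)
  }
  image_frame(m, net$pixel_size_um)
}
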