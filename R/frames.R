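#' Calibrated 2-D intensity frame
#'
#' The universal carrier for all imaging operations: a non-negative
#' intensity matrix plus its physical pixel size. Pixels are indexed with
#' 0-based coordinates, x to the right (columns), y down (rows), pixel
#' centers at integer coordinates. Internally `pixels[y + 1, x + 1]`.
#'
#' @param pixels Numeric matrix of intensities, all finite and `>= 0`,
#'   both dimensions at least 16.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @return An object of class `ImageFrame` with fields `pixels` and
#'   `pixel_size_um`.
#' @export
image_frame <- function(pixels, pixel_size_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  if (nrow(pixels) < 16L || ncol(pixels) < 16L) {
    stop("frame dimensions must both be >= 16 pixels", call. = FALSE)
  }
  stop_if_not_scalar_pos(pixel_size_um, "pixel_size_um")
  structure(list(pixels = pixels, pixel_size_um = as.double(pixel_size_um)),
            class = "ImageFrame")
}

#' @export
print.ImageFrame <- function(x, ...) {
  cat(sprintf("<ImageFrame> %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              ncol(x$pixels), nrow(x$pixels), x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.ImageFrame <- function(x) dim(x$pixels)

#' Calibrated time lapse
#'
#' An ordered list of identically shaped [image_frame()] objects with a
#' fixed frame interval.
#'
#' @param frames List of `ImageFrame` objects (at least 2) with identical
#'   dimensions and pixel size.
#' @param frame_interval_s Frame interval in seconds.
#' @return An object of class `TimeLapse`.
#' @export
time_lapse <- function(frames, frame_interval_s) {
  if (!is.list(frames) || length(frames) < 2L) {
    stop("a time lapse needs at least 2 frames", call. = FALSE)
  }
  if (!all(vapply(frames, inherits, logical(1L), "ImageFrame"))) {
    stop("all elements of `frames` must be ImageFrame objects", call. = FALSE)
  }
  d <- dim(frames[[1L]]$pixels)
  same <- vapply(frames, function(f) identical(dim(f$pixels), d), logical(1L))
  if (!all(same)) stop("all frames must share the same shape", call. = FALSE)
  stop_if_not_scalar_pos(frame_interval_s, "frame_interval_s")
  structure(list(frames = frames,
                 frame_interval_s = as.double(frame_interval_s)),
            class = "TimeLapse")
}

#' @export
print.TimeLapse <- function(x, ...) {
  d <- dim(x$frames[[1L]]$pixels)
  cat(sprintf("<TimeLapse> %d frames of %d x %d px, dt = %.4g s\n",
              length(x$frames), d[2L], d[1L], x$frame_interval_s))
  invisible(x)
}

#' @export
length.TimeLapse <- function(x) length(x$frames)

#' Read a single- or multi-page TIFF as a frame or time lapse
#'
#' Intensities are used as stored (for integer TIFFs the `tiff` package
#' returns values scaled to `[0, 1]`; an optional `scale` restores
#' physical counts).
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param frame_interval_s Frame interval in seconds; required when the
#'   file holds more than one page.
#' @param scale Multiplicative intensity scale applied after reading.
#' @return An `ImageFrame` (one page) or `TimeLapse` (several pages).
#' @export
read_frames <- function(path, pixel_size_um, frame_interval_s = NULL, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # first channel of RGB pages
    p * scale
  })
  if (length(pages) == 1L) {
    image_frame(pages[[1L]], pixel_size_um)
  } else {
    if (is.null(frame_interval_s)) {
      stop("`frame_interval_s` is required for a multi-page TIFF", call. = FALSE)
    }
    time_lapse(lapply(pages, image_frame, pixel_size_um = pixel_size_um),
               frame_interval_s)
  }
}

#' Write a frame or time lapse as a 32-bit float multi-page TIFF
#'
#' Intensities are divided by `scale` before writing so that stored
#' values lie in `[0, 1]` (the float TIFF convention of the `tiff`
#' package). The scale used is returned so callers can record it in a
#' sidecar file.
#'
#' @param x An `ImageFrame` or `TimeLapse`.
#' @param path Output path.
#' @param scale Intensity divisor; default the global maximum (or 1 for
#'   an all-zero image).
#' @return Invisibly, the scale used.
#' @export
write_frames <- function(x, path, scale = NULL) {
  mats <- if (inherits(x, "ImageFrame")) list(x$pixels)
          else if (inherits(x, "TimeLapse")) lapply(x$frames, `[[`, "pixels")
          else stop("`x` must be an ImageFrame or TimeLapse", call. = FALSE)
  if (is.null(scale)) {
    scale <- max(vapply(mats, max, numeric(1L)))
    if (scale <= 0) scale <- 1
  }
  mats <- lapply(mats, function(m) m / scale)
  tiff::writeTIFF(mats, path, bits.per.sample = 32L, reduce = FALSE,
                  compression = "none")
  invisible(scale)
}
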